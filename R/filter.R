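#' Normalize DYS439 allele nomenclature
#'
#' Raw exports from some testing companies report DYS439 four repeats above
#' the standard forensic nomenclature; published modal haplotypes use the
#' standard convention, so raw alleles must be reduced by 4 before motif
#' comparison. Idempotent once the convention is `"standard"`.
#'
#' @param db A [ystr_db()] with a DYS439 column.
#' @param source_convention `"ftdna_raw"` (subtract 4) or `"standard"`
#'   (leave unchanged).
#' @return The database with DYS439 in standard convention.
#' @export
#' @examples
#' db <- ystr_db(data.frame(kit_id = "k1", group = "jewish",
#'   haplogroup = "J1", hg_evidence = "snp_typed", DYS439 = 16))
#' normalize_dys439(db, "ftdna_raw")$DYS439  # 12
normalize_dys439 <- function(db, source_convention = c("standard", "ftdna_raw")) {
  source_convention <- match.arg(source_convention)
  if (!"DYS439" %in% names(db)) stop("DYS439 not present")
  if (source_convention == "ftdna_raw") {
    a <- db$DYS439 - 4L
    if (any(!is.na(a) & a < .ALLELE_MIN)) {
      stop("DYS439 correction yields an implausible repeat count (< ",
           .ALLELE_MIN, ")")
    }
    db$DYS439 <- a
  }
  db
}

#' Derive DYS389b from DYS389I/DYS389II
#'
#' DYS389II is reported as a compound allele containing DYS389I; for
#' mutational-distance work it is replaced by the difference
#' `DYS389b = DYS389II - DYS389I`, which must be strictly positive.
#'
#' @param db A [ystr_db()] (or any data frame) with DYS389I and DYS389II.
#' @return Integer vector of DYS389b values (NA where either input is
#'   missing).
#' @export
derive_dys389b <- function(db) {
  if (!all(c("DYS389I", "DYS389II") %in% names(db))) {
    stop("both DYS389I and DYS389II are required")
  }
  b <- db$DYS389II - db$DYS389I
  if (any(!is.na(b) & b <= 0L)) {
    stop("DYS389II must exceed DYS389I")
  }
  as.integer(b)
}

.empty_filter_report <- function() {
  structure(list(n_input = 0L, n_deduplicated = 0L, n_failed_loci = 0L,
                 n_failed_haplogroup = 0L, n_kept = 0L,
                 removed_kit_ids = character(0)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter report\n")
  cat("  input records:        ", x$n_input, "\n")
  cat("  after deduplication:  ", x$n_deduplicated, "\n")
  cat("  failed loci/coverage: ", x$n_failed_loci, "\n")
  cat("  failed hg evidence:   ", x$n_failed_haplogroup, "\n")
  cat("  kept:                 ", x$n_kept, "\n")
  invisible(x)
}

#' Filter database records
#'
#' Applies the double admission criterion, in a fixed rule order so every
#' removed record is counted once under its first failing rule:
#' deduplication by kit id (first occurrence by file order wins), then the
#' typing-density/coverage rule, then the haplogroup-evidence rule.
#'
#' Y records are kept iff typed at `min_y_loci` or more loci and the
#' haplogroup is supported by SNP typing or an STR-based prediction; mtDNA
#' records are kept iff their covered interval contains the whole HVS-I
#' window (16,024-16,569) and the haplogroup was confirmed by SNP typing.
#'
#' @param records A [ystr_db()] or [mtdna_db()].
#' @param kind `"y"` or `"mt"`.
#' @param min_y_loci Minimum typed Y-STR loci (default 12).
#' @return `list(kept = <database>, report = <filter_report>)`. The report
#'   satisfies `n_kept + (n_input - n_deduplicated) + n_failed_loci +
#'   n_failed_haplogroup = n_input`.
#' @export
filter_records <- function(records, kind = c("y", "mt"), min_y_loci = 12L) {
  kind <- match.arg(kind)
  n_input <- nrow(records)
  if (n_input == 0) {
    return(list(kept = records, report = .empty_filter_report()))
  }
  dup <- duplicated(records$kit_id)
  removed <- records$kit_id[dup]
  db <- records[!dup, , drop = FALSE]
  n_dedup <- nrow(db)

  if (kind == "y") {
    pass_loci <- n_loci_typed(db) >= min_y_loci
    pass_hg <- !is.na(db$hg_evidence) &
      db$hg_evidence %in% c("snp_typed", "str_predicted")
  } else {
    pass_loci <- !is.na(db$covered_start) & !is.na(db$covered_end) &
      db$covered_start <= .HVS1_START & db$covered_end >= .HVS1_END
    pass_hg <- !is.na(db$hg_evidence) & db$hg_evidence == "snp_typed"
  }
  fail_loci <- !pass_loci
  fail_hg <- pass_loci & !pass_hg
  keep <- pass_loci & pass_hg

  removed <- c(removed, db$kit_id[!keep])
  kept <- db[keep, , drop = FALSE]
  rownames(kept) <- NULL
  report <- structure(list(
    n_input = n_input,
    n_deduplicated = n_dedup,
    n_failed_loci = sum(fail_loci),
    n_failed_haplogroup = sum(fail_hg),
    n_kept = nrow(kept),
    removed_kit_ids = removed
  ), class = "filter_report")
  list(kept = kept, report = report)
}
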