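#' Column dialect for database files
#'
#' Tabular databases exported from genealogical-testing repositories differ
#' in column naming. A dialect maps file columns onto the package's data
#' model: which columns hold the kit id, ancestry-group label, haplogroup
#' and haplogroup-evidence flag, how group values are recoded, and which
#' columns to ignore. Locus columns are recognized by name (after
#' [normalize_locus_name()]); a combined `DYS385` column holding `"12-13"`
#' style pairs is split into `DYS385a`/`DYS385b`, stored sorted ascending
#' (DYS385 is an unordered duplicated locus).
#'
#' @param kit,group,haplogroup,evidence File column names.
#' @param group_map Named character vector recoding raw group values to
#'   labels such as `"jewish"`/`"non_jewish"` (`NULL` = use values as-is).
#' @param evidence_map Named character vector recoding evidence values.
#' @param subst,covered_start,covered_end mtDNA-specific column names.
#' @param ignore Columns to skip silently.
#' @return A list of class `db_dialect`.
#' @export
db_dialect <- function(kit = "kit_id", group = "group",
                       haplogroup = "haplogroup", evidence = "hg_evidence",
                       group_map = NULL, evidence_map = NULL,
                       subst = "substitutions",
                       covered_start = "covered_start",
                       covered_end = "covered_end",
                       ignore = character(0)) {
  structure(list(kit = kit, group = group, haplogroup = haplogroup,
                 evidence = evidence, group_map = group_map,
                 evidence_map = evidence_map, subst = subst,
                 covered_start = covered_start, covered_end = covered_end,
                 ignore = ignore),
            class = "db_dialect")
}

#' @rdname db_dialect
#' @param path YAML file whose top-level keys are `db_dialect()` arguments.
#' @export
read_dialect <- function(path) {
  do.call(db_dialect, yaml::read_yaml(path))
}

.recode <- function(x, map) {
  if (is.null(map)) return(x)
  hit <- x %in% names(map)
  x[hit] <- unname(map[x[hit]])
  x
}

#' Read a Y-STR database from TSV
#'
#' One row per record; metadata columns per the dialect; every remaining
#' column must be a recognizable Y-STR locus (hard error otherwise, naming
#' the column). Allele cells may be empty (missing), an integer, or for a
#' combined DYS385 column a pair `"12-13"`. Rows with unparseable alleles
#' are dropped and collected in the load report attached as
#' `attr(db, "load_report")`.
#'
#' @param path TSV file with a header row.
#' @param dialect A [db_dialect()].
#' @return A [ystr_db()] with a `load_report` attribute (data frame of
#'   dropped rows: `row`, `column`, `value`).
#' @export
read_y_database <- function(path, dialect = db_dialect()) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", na.strings = c("", "NA"))
  meta_cols <- c(dialect$kit, dialect$group, dialect$haplogroup,
                 dialect$evidence)
  missing_meta <- setdiff(meta_cols, names(raw))
  if (length(missing_meta)) {
    stop("file lacks declared column(s): ",
         paste(missing_meta, collapse = ", "))
  }
  locus_cols <- setdiff(names(raw), c(meta_cols, dialect$ignore))
  canon <- normalize_locus_name(locus_cols)
  known <- grepl("^DYS[0-9]+[ab]?$|^DYS389I{1,2}$", canon)
  if (any(!known)) {
    stop("unknown locus column(s): ", paste(locus_cols[!known], collapse = ", "))
  }

  n <- nrow(raw)
  out <- data.frame(
    kit_id = raw[[dialect$kit]],
    group = .recode(raw[[dialect$group]], dialect$group_map),
    haplogroup = raw[[dialect$haplogroup]],
    hg_evidence = .recode(raw[[dialect$evidence]], dialect$evidence_map),
    stringsAsFactors = FALSE
  )
  bad <- data.frame(row = integer(0), column = character(0),
                    value = character(0), stringsAsFactors = FALSE)
  drop_row <- logical(n)
  for (j in seq_along(locus_cols)) {
    col <- locus_cols[j]
    name <- canon[j]
    v <- raw[[col]]
    if (name == "DYS385") {
      # combined unordered pair "12-13"
      parts <- strsplit(ifelse(is.na(v), "-", v), "-", fixed = TRUE)
      a <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
      b <- suppressWarnings(as.integer(vapply(parts, function(p)
        if (length(p) >= 2) p[2] else NA_character_, "")))
      lo <- pmin(a, b); hi <- pmax(a, b)
      fail <- !is.na(v) & (is.na(lo) | is.na(hi))
      if (any(fail)) {
        bad <- rbind(bad, data.frame(row = which(fail), column = col,
                                     value = v[fail]))
        drop_row <- drop_row | fail
      }
      out$DYS385a <- lo
      out$DYS385b <- hi
    } else {
      a <- suppressWarnings(as.integer(v))
      fail <- !is.na(v) & is.na(a)
      if (any(fail)) {
        bad <- rbind(bad, data.frame(row = which(fail), column = col,
                                     value = v[fail]))
        drop_row <- drop_row | fail
      }
      out[[name]] <- a
    }
  }
  if (all(c("DYS385a", "DYS385b") %in% names(out))) {
    lo <- pmin(out$DYS385a, out$DYS385b)
    hi <- pmax(out$DYS385a, out$DYS385b)
    out$DYS385a <- lo
    out$DYS385b <- hi
  }
  db <- ystr_db(out[!drop_row, , drop = FALSE])
  rownames(db) <- NULL
  attr(db, "load_report") <- bad
  db
}

#' Write a Y-STR database to TSV
#'
#' Writes canonical column names (DYS385 as two columns); reading the file
#' back with the default dialect reproduces the records field-for-field.
#'
#' @param db A [ystr_db()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_y_database <- function(db, path) {
  utils::write.table(as.data.frame(db), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read an mtDNA HVS-I database from TSV
#'
#' @inheritParams read_y_database
#' @return An [mtdna_db()].
#' @export
read_mt_database <- function(path, dialect = db_dialect()) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", na.strings = c("", "NA"))
  need <- c(dialect$kit, dialect$group, dialect$haplogroup, dialect$evidence,
            dialect$subst, dialect$covered_start, dialect$covered_end)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("file lacks declared column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  mtdna_db(data.frame(
    kit_id = raw[[dialect$kit]],
    group = .recode(raw[[dialect$group]], dialect$group_map),
    haplogroup = raw[[dialect$haplogroup]],
    hg_evidence = .recode(raw[[dialect$evidence]], dialect$evidence_map),
    substitutions = ifelse(is.na(raw[[dialect$subst]]), "",
                           raw[[dialect$subst]]),
    covered_start = as.integer(raw[[dialect$covered_start]]),
    covered_end = as.integer(raw[[dialect$covered_end]]),
    stringsAsFactors = FALSE
  ))
}

#' Write an mtDNA database to TSV
#' @param db An [mtdna_db()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mt_database <- function(db, path) {
  utils::write.table(as.data.frame(db), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# Minimal FASTA reader (upper-case character vectors, one per record).
.read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  id <- sub("^>\\s*", "", lines[hdr])
  id <- sub("\\s.*$", "", id)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), function(s)
    toupper(paste(s, collapse = "")), character(1))
  names(seqs) <- id
  seqs
}

#' Import HVS-I haplotypes from FASTA
#'
#' Reads aligned sequences of the HVS-I window (positions 16,024-16,569,
#' rCRS numbering, 1-based) and scores each one as a substitution set by
#' diffing against a reference slice of the same window. Sites that are
#' `N` or `-` in a sample are treated as uncovered and excluded from its
#' covered interval bookkeeping (the record's covered interval is clipped to
#' the contiguous unambiguous core).
#'
#' The packaged default reference (`hvs1_reference_synthetic.fasta`) is a
#' synthetic stand-in with the correct coordinates, intended for simulated
#' data and tests; supply the real rCRS 16,024-16,569 slice via `reference`
#' when importing real data.
#'
#' @param path FASTA of sample sequences, each `end - start + 1` bases long.
#' @param reference FASTA containing a single reference sequence of the
#'   same window.
#' @param start 1-based coordinate of the first base (default 16024).
#' @param group,haplogroup,hg_evidence Metadata applied to every record.
#' @return An [mtdna_db()] with one record per FASTA entry.
#' @export
read_hvs1_fasta <- function(path,
                            reference = motifscan_file("hvs1_reference_synthetic.fasta"),
                            start = .HVS1_START,
                            group = NA_character_,
                            haplogroup = NA_character_,
                            hg_evidence = "snp_typed") {
  ref <- .read_fasta(reference)
  if (length(ref) != 1) stop("reference FASTA must hold exactly one sequence")
  ref <- strsplit(ref[[1]], "")[[1]]
  seqs <- .read_fasta(path)
  recs <- lapply(names(seqs), function(id) {
    s <- strsplit(seqs[[id]], "")[[1]]
    if (length(s) != length(ref)) {
      stop("sequence ", id, " length ", length(s),
           " does not match reference length ", length(ref))
    }
    callable <- s %in% c("A", "C", "G", "T")
    pos <- start + which(s != ref & callable) - 1L
    base <- s[s != ref & callable]
    cov <- if (all(callable)) c(start, start + length(ref) - 1L) else {
      idx <- which(callable)
      c(start + min(idx) - 1L, start + max(idx) - 1L)
    }
    data.frame(kit_id = id, group = group, haplogroup = haplogroup,
               hg_evidence = hg_evidence,
               substitutions = paste(sprintf("%d%s", pos, base), collapse = " "),
               covered_start = cov[1], covered_end = cov[2],
               stringsAsFactors = FALSE)
  })
  mtdna_db(do.call(rbind, recs))
}

#' Path to a packaged resource file
#' @param ... File name components under the package's `extdata` directory.
#' @return Absolute file path.
#' @export
motifscan_file <- function(...) {
  system.file("extdata", ..., package = "motifscan", mustWork = TRUE)
}
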