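#' Construct a Y-STR database
#'
#' A Y-STR database is a data frame with one row per record and columns
#' `kit_id`, `group`, `haplogroup`, `hg_evidence` plus one integer column per
#' locus (canonical names, see [ystr_panel()]; missing alleles are `NA`).
#'
#' @param df Data frame with the columns described above.
#' @param validate Check invariants (unique kit ids, allele bounds,
#'   DYS389II > DYS389I where both typed)?
#' @return An object of class `ystr_db` (a data frame).
#' @export
ystr_db <- function(df, validate = TRUE) {
  stopifnot(is.data.frame(df))
  meta <- c("kit_id", "group", "haplogroup", "hg_evidence")
  missing_meta <- setdiff(meta, names(df))
  if (length(missing_meta)) {
    stop("missing column(s): ", paste(missing_meta, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  loci <- setdiff(names(df), meta)
  for (l in loci) df[[l]] <- as.integer(df[[l]])
  df <- df[c(meta, loci)]
  # DYS385 is an unordered duplicated locus: store the pair sorted
  if (all(c("DYS385a", "DYS385b") %in% loci)) {
    lo <- pmin(df$DYS385a, df$DYS385b)
    hi <- pmax(df$DYS385a, df$DYS385b)
    df$DYS385a <- lo
    df$DYS385b <- hi
  }
  class(df) <- c("ystr_db", "data.frame")
  if (validate) validate_ystr_db(df)
  df
}

#' @rdname ystr_db
#' @param db A `ystr_db`.
#' @export
validate_ystr_db <- function(db) {
  loci <- y_loci(db)
  bad <- vapply(loci, function(l) {
    a <- db[[l]]
    any(!is.na(a) & (a < .ALLELE_MIN | a > .ALLELE_MAX))
  }, logical(1))
  if (any(bad)) {
    stop("allele out of [", .ALLELE_MIN, ", ", .ALLELE_MAX, "] at ",
         paste(loci[bad], collapse = ", "))
  }
  if (all(c("DYS389I", "DYS389II") %in% loci)) {
    both <- !is.na(db$DYS389I) & !is.na(db$DYS389II)
    if (any(both & db$DYS389II <= db$DYS389I)) {
      stop("DYS389II must exceed DYS389I where both are typed")
    }
  }
  ev <- db$hg_evidence
  ok <- is.na(ev) | ev %in% c("snp_typed", "str_predicted")
  if (!all(ok)) stop("hg_evidence must be snp_typed or str_predicted (or NA)")
  invisible(db)
}

#' Locus columns of a Y-STR database
#' @param db A `ystr_db`.
#' @return Character vector of locus column names.
#' @export
y_loci <- function(db) {
  setdiff(names(db), c("kit_id", "group", "haplogroup", "hg_evidence"))
}

#' Number of typed loci per record
#' @param db A `ystr_db`.
#' @return Integer vector: non-missing allele count per row.
#' @export
n_loci_typed <- function(db) {
  loci <- y_loci(db)
  if (!length(loci)) return(integer(nrow(db)))
  as.integer(rowSums(!is.na(as.matrix(db[loci]))))
}

#' Construct an mtDNA HVS-I database
#'
#' One row per record with columns `kit_id`, `group`, `haplogroup`,
#' `hg_evidence` (`snp_typed` or `unconfirmed`), `substitutions` (space
#' separated tokens such as `"16093C 16224C"`, relative to the rCRS), and the
#' covered interval `covered_start`, `covered_end` (1-based, inclusive).
#'
#' @param df Data frame with the columns described above.
#' @param validate Check invariants (unique positions per record, positions
#'   inside the covered interval)?
#' @return An object of class `mtdna_db` (a data frame).
#' @export
mtdna_db <- function(df, validate = TRUE) {
  stopifnot(is.data.frame(df))
  need <- c("kit_id", "group", "haplogroup", "hg_evidence",
            "substitutions", "covered_start", "covered_end")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)[need]
  df$covered_start <- as.integer(df$covered_start)
  df$covered_end <- as.integer(df$covered_end)
  df$substitutions <- vapply(df$substitutions, function(s) {
    paste(sort_hvs1(hvs1_set(s)), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  class(df) <- c("mtdna_db", "data.frame")
  if (validate) validate_mtdna_db(df)
  df
}

#' @rdname mtdna_db
#' @param db An `mtdna_db`.
#' @export
validate_mtdna_db <- function(db) {
  for (i in seq_len(nrow(db))) {
    s <- hvs1_set(db$substitutions[i])
    pos <- hvs1_positions(s)
    if (anyDuplicated(pos)) {
      stop("record ", db$kit_id[i], ": two substitutions share a position")
    }
    if (length(pos) &&
        (any(pos < db$covered_start[i]) || any(pos > db$covered_end[i]))) {
      stop("record ", db$kit_id[i],
           ": substitution outside the covered interval")
    }
  }
  ev <- db$hg_evidence
  if (!all(is.na(ev) | ev %in% c("snp_typed", "unconfirmed"))) {
    stop("hg_evidence must be snp_typed or unconfirmed (or NA)")
  }
  invisible(db)
}

#' Parse and render HVS-I substitution sets
#'
#' A substitution is written `"16093C"`: 1-based rCRS position followed by
#' the derived base. `hvs1_set()` splits a string on whitespace or commas
#' into a vector of tokens; heteroplasmic (IUPAC ambiguity) and indel tokens
#' (e.g. `"16188.1C"`, `"16166d"`) are dropped with a warning, so only clean
#' substitutions are compared downstream.
#'
#' @param x A single string (or already a character vector of tokens).
#' @param warn Warn when non-substitution tokens are dropped?
#' @return `hvs1_set()`: character vector of substitution tokens.
#' @export
hvs1_set <- function(x, warn = TRUE) {
  if (length(x) == 1 && (is.na(x) || !nzchar(trimws(x)))) return(character(0))
  tok <- unlist(strsplit(as.character(x), "[,;[:space:]]+"))
  tok <- tok[nzchar(tok)]
  ok <- grepl("^[0-9]{5}[ACGT]$", tok)
  if (any(!ok) && warn) {
    warning("dropping non-substitution token(s): ",
            paste(unique(tok[!ok]), collapse = ", "))
  }
  unique(tok[ok])
}

#' @rdname hvs1_set
#' @param set Character vector of substitution tokens.
#' @return `hvs1_positions()`: integer vector of positions.
#' @export
hvs1_positions <- function(set) {
  as.integer(substr(set, 1, nchar(set) - 1))
}

#' @rdname hvs1_set
#' @return `sort_hvs1()`: the set sorted by position.
#' @export
sort_hvs1 <- function(set) {
  set[order(hvs1_positions(set))]
}
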