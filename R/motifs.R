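#' Load the packaged haplotype motif definitions
#'
#' The package ships the ten published motifs as a versioned YAML resource:
#' six Y-STR modal haplotypes (LMH/eLMH, CMH/eCMH, GAL, IP) and four
#' Ashkenazi mtDNA HVS-I motifs (K1, K2, K3, N). Each motif carries its
#' haplogroup context tag; matching itself never enforces the haplogroup
#' (count tables stratify by haplogroup separately).
#'
#' @param path YAML file of motif definitions (default: packaged resource).
#' @return Named list of `motif` objects.
#' @export
#' @examples
#' motifs <- load_motifs()
#' motifs$CMH
load_motifs <- function(path = motifscan_file("motifs.yaml")) {
  raw <- yaml::read_yaml(path)
  out <- list()
  for (tag in names(raw$y_motifs)) {
    m <- raw$y_motifs[[tag]]
    out[[tag]] <- motif(tag, system = m$system, hg_context = m$hg_context,
                        y_alleles = unlist(m$alleles))
  }
  for (tag in names(raw$mt_motifs)) {
    m <- raw$mt_motifs[[tag]]
    out[[tag]] <- motif(tag, system = "hvs1", hg_context = m$hg_context,
                        mt_substitutions = unlist(m$substitutions))
  }
  out
}

#' Construct a haplotype motif
#'
#' @param tag Short name (e.g. `"CMH"`).
#' @param system `"ystr6"`, `"ystr12"` or `"hvs1"`.
#' @param hg_context Haplogroup the motif was described in.
#' @param y_alleles Named integer vector of alleles over the panel loci
#'   (Y motifs only).
#' @param mt_substitutions Character vector of HVS-I substitution tokens
#'   (mtDNA motifs only).
#' @return An object of class `motif`.
#' @export
motif <- function(tag, system, hg_context = NA_character_,
                  y_alleles = NULL, mt_substitutions = NULL) {
  system <- match.arg(system, c("ystr6", "ystr12", "hvs1"))
  if (is.null(y_alleles) == is.null(mt_substitutions)) {
    stop("exactly one of y_alleles / mt_substitutions must be given")
  }
  if (!is.null(y_alleles)) {
    panel <- ystr_panel(system)
    missing_loci <- setdiff(panel, names(y_alleles))
    if (length(missing_loci)) {
      stop("motif ", tag, " lacks panel locus ",
           paste(missing_loci, collapse = ", "))
    }
    y_alleles <- as.integer(y_alleles[panel])
    names(y_alleles) <- panel
  } else {
    mt_substitutions <- sort_hvs1(hvs1_set(mt_substitutions))
  }
  structure(list(tag = tag, system = system, hg_context = hg_context,
                 y_alleles = y_alleles, mt_substitutions = mt_substitutions),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat("<motif ", x$tag, "> system=", x$system, " hg=", x$hg_context, "\n",
      sep = "")
  if (!is.null(x$y_alleles)) {
    cat("  ", paste(names(x$y_alleles), x$y_alleles, sep = "=",
                    collapse = " "), "\n")
  } else {
    cat("  ", paste(x$mt_substitutions, collapse = " "), "\n")
  }
  invisible(x)
}

#' Match records against a Y-STR motif
#'
#' A record matches iff every panel locus is typed and equals the motif
#' allele; DYS385 is compared as an unordered pair. Records untyped at any
#' panel locus are flagged `NA` ("untyped") so they can be excluded from
#' the motif's denominator and reported separately.
#'
#' @param db A [ystr_db()] (DYS439 already in standard convention).
#' @param motif A Y-STR [motif()].
#' @return Logical vector: `TRUE` match, `FALSE` mismatch, `NA` untyped at
#'   one or more panel loci.
#' @export
match_y_motif <- function(db, motif) {
  stopifnot(inherits(motif, "motif"), !is.null(motif$y_alleles))
  panel <- names(motif$y_alleles)
  absent <- setdiff(panel, names(db))
  n <- nrow(db)
  if (length(absent)) return(rep(NA, n))
  # DYS385 pair is stored sorted ascending in the db; sort the motif pair
  # the same way so the comparison is order-free.
  target <- motif$y_alleles
  if (all(c("DYS385a", "DYS385b") %in% panel)) {
    pair <- sort(target[c("DYS385a", "DYS385b")])
    target["DYS385a"] <- pair[1]
    target["DYS385b"] <- pair[2]
  }
  m <- as.matrix(db[panel])
  typed <- rowSums(is.na(m)) == 0
  eq <- rowSums(m == rep(target, each = n)) == length(panel)
  out <- rep(NA, n)
  out[typed] <- eq[typed]
  out
}

#' Match records against an mtDNA HVS-I motif
#'
#' Under the default exact-set mode a record matches iff its substitution
#' set, restricted to the HVS-I window, equals the motif set; this keeps
#' the nested K motifs (K3's set is a subset of K1's and K2's) mutually
#' exclusive, as the published count tables report them. Subset-containment
#' mode (record contains the motif set) is available for sensitivity
#' analysis.
#'
#' @param db An [mtdna_db()] covering the HVS-I window.
#' @param motif An mtDNA [motif()].
#' @param mode `"exact"` (default) or `"subset"`.
#' @return Logical vector.
#' @export
match_mt_motif <- function(db, motif, mode = c("exact", "subset")) {
  mode <- match.arg(mode)
  stopifnot(inherits(motif, "motif"), !is.null(motif$mt_substitutions))
  target <- motif$mt_substitutions
  vapply(db$substitutions, function(s) {
    set <- hvs1_set(s, warn = FALSE)
    pos <- hvs1_positions(set)
    set <- set[pos >= .HVS1_START & pos <= .HVS1_END]
    if (mode == "exact") setequal(set, target) else all(target %in% set)
  }, logical(1), USE.NAMES = FALSE)
}

#' Match any motif against a database
#'
#' Dispatches on the motif system: Y motifs require a [ystr_db()], mtDNA
#' motifs an [mtdna_db()].
#'
#' @inheritParams match_mt_motif
#' @param db A database of the appropriate kind.
#' @return Logical vector (`NA` = untyped, Y motifs only).
#' @export
match_motif <- function(db, motif, mode = c("exact", "subset")) {
  if (motif$system == "hvs1") {
    match_mt_motif(db, motif, mode)
  } else {
    match_y_motif(db, motif)
  }
}

#' Motif count table stratified by haplogroup and group
#'
#' Counts motif matches per (haplogroup, ancestry group) cell, with group
#' totals, group sizes, untyped counts, and percentages (rounded half-up to
#' one decimal, as the published tables print them). Haplogroup labels can
#' be collapsed to coarser clades via a prefix hierarchy first.
#'
#' @param records A filtered database.
#' @param motif A [motif()].
#' @param hg_map Optional named character vector mapping fine haplogroup
#'   labels to coarser ones before stratification.
#' @param mode Passed to [match_mt_motif()] for mtDNA motifs.
#' @return An object of class `motif_count_table`: list with `tag`, `rows`
#'   (data frame haplogroup x group x count), `totals`, `n` (group sizes,
#'   excluding records untyped at a panel locus), `n_untyped`, `pct`.
#' @export
build_count_table <- function(records, motif, hg_map = NULL,
                              mode = c("exact", "subset")) {
  hit <- match_motif(records, motif, mode)
  groups <- sort(unique(records$group))
  hg <- records$haplogroup
  if (!is.null(hg_map)) hg <- .recode(hg, hg_map)
  matched <- !is.na(hit) & hit
  rows <- if (any(matched)) {
    tab <- table(haplogroup = hg[matched], group = records$group[matched])
    as.data.frame(tab, stringsAsFactors = FALSE, responseName = "count")
  } else {
    data.frame(haplogroup = character(0), group = character(0),
               count = integer(0))
  }
  n_untyped <- vapply(groups, function(g)
    sum(is.na(hit[records$group == g])), integer(1))
  n <- vapply(groups, function(g)
    sum(records$group == g), integer(1)) - n_untyped
  totals <- vapply(groups, function(g)
    sum(matched[records$group == g]), integer(1))
  count_table(motif$tag, rows, n, n_untyped = n_untyped)
}

#' Assemble a motif count table from explicit counts
#'
#' Used both by [build_count_table()] and to wrap published count tables
#' packaged as fixtures.
#'
#' @param tag Motif tag.
#' @param rows Data frame with columns `haplogroup`, `group`, `count`.
#' @param n Named integer vector of group sizes (the percentage
#'   denominators).
#' @param n_untyped Named integer vector (default all zero).
#' @return A `motif_count_table`.
#' @export
count_table <- function(tag, rows, n, n_untyped = NULL) {
  groups <- names(n)
  stopifnot(!is.null(groups))
  rows <- rows[rows$count > 0, , drop = FALSE]
  rownames(rows) <- NULL
  totals <- vapply(groups, function(g)
    sum(rows$count[rows$group == g]), numeric(1))
  if (is.null(n_untyped)) n_untyped <- stats::setNames(rep(0L, length(n)), groups)
  pct <- vapply(groups, function(g)
    if (n[[g]] > 0) percentage(totals[[g]], n[[g]]) else NA_real_, numeric(1))
  structure(list(tag = tag, rows = rows,
                 totals = stats::setNames(as.integer(totals), groups),
                 n = stats::setNames(as.integer(n), groups),
                 n_untyped = stats::setNames(as.integer(n_untyped), groups),
                 pct = pct),
            class = "motif_count_table")
}

#' @export
print.motif_count_table <- function(x, ...) {
  cat("<motif_count_table ", x$tag, ">\n", sep = "")
  for (g in names(x$n)) {
    cat(sprintf("  %-12s total %5d / %6d  (%.1f%%)\n", g, x$totals[[g]],
                x$n[[g]], x$pct[[g]]))
  }
  if (nrow(x$rows)) print(x$rows) else cat("  (no matches)\n")
  invisible(x)
}

#' Convert a count table to a k x 2 matrix for association testing
#'
#' With `include_noncarriers = TRUE` (the default) a final
#' `"non_carriers"` row holds `group size - carriers`, so the columns sum
#' to the group sizes and the test asks whether carrier status *and* its
#' haplogroup distribution differ between the groups — the construction
#' whose 2x2 special case reproduces the magnitude of the published
#' statistics. Carriers-only tables (`FALSE`) test only the haplogroup
#' distribution among carriers.
#'
#' @param x A `motif_count_table` with exactly two groups.
#' @param include_noncarriers Append the remainder row?
#' @return Integer matrix, one row per haplogroup (plus the optional
#'   remainder row), one column per group.
#' @export
as_contingency <- function(x, include_noncarriers = TRUE) {
  stopifnot(inherits(x, "motif_count_table"))
  groups <- names(x$n)
  if (length(groups) != 2) stop("need exactly two groups")
  hgs <- sort(unique(x$rows$haplogroup))
  m <- matrix(0L, length(hgs), 2, dimnames = list(hgs, groups))
  for (i in seq_len(nrow(x$rows))) {
    m[x$rows$haplogroup[i], x$rows$group[i]] <- x$rows$count[i]
  }
  if (include_noncarriers) {
    m <- rbind(m, non_carriers = x$n - x$totals)
  }
  m
}
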