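#' Y-STR locus panels
#'
#' The two marker panels used throughout the package. The 6-locus panel is
#' the classical modal-haplotype panel (DYS19, DYS388, DYS390, DYS391,
#' DYS392, DYS393); the 12-locus panel is the extended genealogical-testing
#' panel in its conventional reporting order (DYS393, DYS390, DYS19, DYS391,
#' DYS385a, DYS385b, DYS426, DYS388, DYS439, DYS389I, DYS392, DYS389II).
#'
#' @param panel One of `"ystr6"` or `"ystr12"`.
#' @return Character vector of locus names in panel order.
#' @export
#' @examples
#' ystr_panel("ystr6")
ystr_panel <- function(panel = c("ystr12", "ystr6")) {
  panel <- match.arg(panel)
  switch(panel,
    ystr6  = c("DYS19", "DYS388", "DYS390", "DYS391", "DYS392", "DYS393"),
    ystr12 = c("DYS393", "DYS390", "DYS19", "DYS391", "DYS385a", "DYS385b",
               "DYS426", "DYS388", "DYS439", "DYS389I", "DYS392", "DYS389II")
  )
}

# Allele plausibility bounds for repeat counts.
.ALLELE_MIN <- 5L
.ALLELE_MAX <- 50L

# HVS-I coordinate window (rCRS numbering, 1-based, inclusive).
.HVS1_START <- 16024L
.HVS1_END <- 16569L

#' Normalize a Y-STR locus name
#'
#' Maps common spelling variants (hyphenated DYS389-I/II, lower case,
#' embedded spaces, "DYS385a/b" vs "DYS385 a") onto the canonical names used
#' by [ystr_panel()]. Unknown names are returned unchanged by default so the
#' caller can decide whether that is an error.
#'
#' @param x Character vector of locus names as found in a file header.
#' @return Character vector of canonical locus names.
#' @export
normalize_locus_name <- function(x) {
  y <- toupper(gsub("[ _]", "", x))
  y <- sub("^DYS389-?I$", "DYS389I", y)
  y <- sub("^DYS389-?II$", "DYS389II", y)
  y <- sub("^DYS385-?A$", "DYS385a", y)
  y <- sub("^DYS385-?B$", "DYS385b", y)
  y <- sub("^DYS385A$", "DYS385a", y)
  y <- sub("^DYS385B$", "DYS385b", y)
  y
}

# Round half away from zero to `digits` decimals (the convention used by the
# printed percentage rows; base round() is half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
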