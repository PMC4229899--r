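#' Construct a mutation-rate model
#'
#' A rate model converts mutational distance into calendar time: it holds a
#' per-marker and a per-haplotype mutation rate (per generation), the
#' marker count, the generation interval in years, and whether TMRCA
#' conversion should undo back mutations via the stepwise-mutation-model
#' inversion. `per_haplotype_rate` defaults to
#' `per_marker_rate * n_markers`; published models may instead store the
#' printed (rounded) haplotype constant, flagged by `rounded_from_product`,
#' in which case downstream arithmetic uses the printed value exactly as
#' the source does.
#'
#' @param name Model name.
#' @param per_marker_rate Mutations per marker per generation.
#' @param n_markers Number of markers in the haplotype.
#' @param per_haplotype_rate Mutations per haplotype per generation
#'   (default: the product).
#' @param per_marker_sd Across-locus standard deviation of the per-marker
#'   rate, if known.
#' @param generation_years Years per generation (default 25).
#' @param back_correction `"none"` or `"smm_inversion"`.
#' @param rounded_from_product Is the stored haplotype rate a printed
#'   rounding of the product?
#' @param per_locus_rates Optional named per-locus rate vector.
#' @param extra List of additional metadata.
#' @return Object of class `rate_model`.
#' @export
rate_model <- function(name, per_marker_rate, n_markers,
                       per_haplotype_rate = per_marker_rate * n_markers,
                       per_marker_sd = NA_real_, generation_years = 25,
                       back_correction = c("none", "smm_inversion"),
                       rounded_from_product = FALSE,
                       per_locus_rates = NULL, extra = list()) {
  back_correction <- match.arg(back_correction)
  stopifnot(per_marker_rate >= 0, n_markers > 0, generation_years > 0,
            per_haplotype_rate >= 0)
  if (!rounded_from_product &&
      !isTRUE(all.equal(per_haplotype_rate, per_marker_rate * n_markers,
                        tolerance = 1e-6))) {
    stop("per_haplotype_rate must equal per_marker_rate * n_markers ",
         "(set rounded_from_product = TRUE for printed constants)")
  }
  structure(list(name = name, per_marker_rate = per_marker_rate,
                 per_marker_sd = per_marker_sd, n_markers = n_markers,
                 per_haplotype_rate = per_haplotype_rate,
                 generation_years = generation_years,
                 back_correction = back_correction,
                 rounded_from_product = rounded_from_product,
                 per_locus_rates = per_locus_rates, extra = extra),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model %s> %.4g mut/marker/gen x %d markers = %.4g mut/haplotype/gen\n",
              x$name, x$per_marker_rate, x$n_markers, x$per_haplotype_rate))
  cat(sprintf("  generation %g y, back correction: %s\n",
              x$generation_years, x$back_correction))
  invisible(x)
}

#' Load the packaged mutation-rate models
#'
#' Five models ship as a YAML resource: the genealogically calibrated
#' Y-STR constant (0.00166/marker/25-year generation, i.e. 0.020 per
#' 12-locus haplotype), the father-son germ-line aggregate
#' (2.113e-3 +/- 1.369e-3 per marker, 0.025 per haplotype, pooled over
#' 126,873 meioses), the pedigree and fossil-calibrated HVS-I rates
#' (1.06e-2 and 1.42e-3 per segment per generation), and a per-site NRY
#' SNP model used for mutation-interval arithmetic.
#'
#' @param path YAML resource (default: packaged).
#' @return Named list of [rate_model()]s.
#' @export
load_rate_models <- function(path = motifscan_file("rate_models.yaml")) {
  raw <- yaml::read_yaml(path)$models
  out <- lapply(names(raw), function(nm) {
    m <- raw[[nm]]
    known <- c("per_marker_rate", "per_marker_sd", "n_markers",
               "per_haplotype_rate", "generation_years", "back_correction",
               "rounded_from_product")
    rate_model(nm,
               per_marker_rate = m$per_marker_rate,
               per_marker_sd = if (is.null(m$per_marker_sd)) NA_real_
                               else m$per_marker_sd,
               n_markers = m$n_markers,
               per_haplotype_rate = m$per_haplotype_rate,
               generation_years = m$generation_years,
               back_correction = m$back_correction,
               rounded_from_product = isTRUE(m$rounded_from_product),
               extra = m[setdiff(names(m), known)])
  })
  names(out) <- names(raw)
  out
}

#' Write rate models back to YAML
#' @param models Named list of [rate_model()]s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rate_models <- function(models, path) {
  lst <- lapply(models, function(m) {
    c(list(per_marker_rate = m$per_marker_rate,
           per_marker_sd = if (is.na(m$per_marker_sd)) NULL else m$per_marker_sd,
           n_markers = m$n_markers,
           per_haplotype_rate = m$per_haplotype_rate,
           rounded_from_product = m$rounded_from_product,
           generation_years = m$generation_years,
           back_correction = m$back_correction),
      m$extra)
  })
  yaml::write_yaml(list(models = lst), path)
  invisible(path)
}

#' Pool father-son pedigree studies into a germ-line rate model
#'
#' Per-locus rates are pooled as total observed mutations over total
#' meioses across studies. Loci where no mutation was ever observed take a
#' supplied fallback rate (population-model regression estimates are the
#' usual source); a locus with zero meioses and no fallback is an error.
#' The per-marker rate is the unweighted mean of the per-locus rates (a
#' meioses-weighted mean is available), its standard deviation the
#' across-locus sd, and the per-haplotype rate the sum of per-locus rates.
#'
#' @param studies Data frame with columns `study`, `locus`, `meioses`,
#'   `mutations`.
#' @param panel Character vector of loci to include.
#' @param fallback_rates Named numeric vector of per-locus fallback rates.
#' @param weighted Use a meioses-weighted per-marker mean?
#' @param generation_years Years per generation.
#' @return A [rate_model()] named `"germline"` with `per_locus_rates`.
#' @export
aggregate_germline <- function(studies, panel,
                               fallback_rates = numeric(0),
                               weighted = FALSE, generation_years = 25) {
  stopifnot(all(c("study", "locus", "meioses", "mutations") %in%
                  names(studies)))
  if (any(studies$mutations > studies$meioses)) {
    stop("a study reports more mutations than meioses")
  }
  rates <- numeric(0)
  meioses <- numeric(0)
  for (l in panel) {
    rows <- studies[studies$locus == l, , drop = FALSE]
    tot_mei <- sum(rows$meioses)
    tot_mut <- sum(rows$mutations)
    if (tot_mei == 0 && !l %in% names(fallback_rates)) {
      stop("locus ", l, " has zero meioses and no fallback rate")
    }
    rates[l] <- if (tot_mut == 0) {
      if (!l %in% names(fallback_rates)) {
        stop("locus ", l, " has zero observed mutations and no fallback rate")
      }
      fallback_rates[[l]]
    } else {
      tot_mut / tot_mei
    }
    meioses[l] <- tot_mei
  }
  per_marker <- if (weighted) {
    stats::weighted.mean(rates, pmax(meioses, 1))
  } else {
    mean(rates)
  }
  rate_model("germline",
             per_marker_rate = per_marker,
             n_markers = length(panel),
             per_haplotype_rate = sum(rates),
             per_marker_sd = stats::sd(rates),
             generation_years = generation_years,
             rounded_from_product = TRUE,  # haplotype rate is the locus sum
             per_locus_rates = rates,
             extra = list(meioses = sum(meioses)))
}

#' Expected transmissions per observed mutation
#'
#' The reciprocal of the per-haplotype mutation rate, rounded to the
#' nearest integer: how many transmissions pass, on average, between
#' successive mutations anywhere in the haplotype. With
#' `n_markers_override` the interval is computed as
#' `1 / (per_marker_rate * n)` for a different marker count.
#'
#' @param model A [rate_model()].
#' @param n_markers_override Optional marker count.
#' @return Integer number of transmissions.
#' @export
#' @examples
#' mutation_interval(load_rate_models()$germline)  # 40
mutation_interval <- function(model, n_markers_override = NULL) {
  rate <- if (is.null(n_markers_override)) {
    model$per_haplotype_rate
  } else {
    model$per_marker_rate * n_markers_override
  }
  if (rate <= 0) stop("per-haplotype rate must be positive")
  as.integer(round(1 / rate))
}

#' Ratio of two per-haplotype rates
#' @param a,b [rate_model()]s on comparable units.
#' @return `a$per_haplotype_rate / b$per_haplotype_rate`.
#' @export
rate_ratio <- function(a, b) {
  if (b$per_haplotype_rate == 0) stop("zero denominator rate")
  a$per_haplotype_rate / b$per_haplotype_rate
}

#' Expected observed mutations under the symmetric stepwise model
#'
#' Under a symmetric single-step mutation model a marker that accumulates
#' `lambda_t` true mutation events performs a +/-1 random walk; the net
#' repeat displacement is the difference of two Poisson counts with mean
#' `lambda_t / 2` (a Skellam variable), and what distance-based estimators
#' observe is the expected absolute displacement `E|X|`. Back mutations
#' make `E|X| < lambda_t` for every positive `lambda_t`, with
#' `E|X| / lambda_t -> 1` as `lambda_t -> 0`.
#'
#' Computed from the exact transition distribution,
#' `P(X = k) = exp(-lambda_t) I_|k|(lambda_t)` (modified Bessel function),
#' truncated at `|k| <= kmax`.
#'
#' @param lambda_t Expected true mutation count(s) per marker, `>= 0`.
#' @param kmax Truncation bound for the displacement sum; `NULL` (default)
#'   chooses a bound well past the Skellam tail for each `lambda_t`.
#' @return `E|X|`, same length as `lambda_t`.
#' @export
smm_expected_observed <- function(lambda_t, kmax = NULL) {
  if (any(lambda_t < 0)) stop("lambda_t must be non-negative")
  vapply(lambda_t, function(l) {
    if (l == 0) return(0)
    kk <- if (is.null(kmax)) max(20L, ceiling(l + 12 * sqrt(l) + 10))
          else kmax
    k <- seq_len(kk)
    # exp(-l) * I_k(l), computed on the scaled form for stability;
    # far-tail orders underflow to 0, which is exactly what the sum needs
    2 * sum(k * suppressWarnings(besselI(l, k, expon.scaled = TRUE)))
  }, numeric(1))
}

#' Invert the stepwise-model expectation (back-mutation correction)
#'
#' Recovers the true per-marker mutation load `lambda_t` from an observed
#' mean absolute displacement by monotone bisection of
#' [smm_expected_observed()], so that
#' `back_correct(smm_expected_observed(x)) == x`. The corrected value is
#' always `>=` the observed one. Observations beyond the expectation
#' reachable within the search ceiling are rejected as saturated.
#'
#' @param observed_per_marker Observed mean absolute displacement(s),
#'   `>= 0`.
#' @param tol Bisection tolerance (default 1e-10).
#' @param lambda_max Search ceiling for `lambda_t` (default 100).
#' @param kmax Passed to [smm_expected_observed()].
#' @return Corrected `lambda_t`, same length as input.
#' @export
back_correct <- function(observed_per_marker, tol = 1e-10,
                         lambda_max = 100, kmax = NULL) {
  if (any(observed_per_marker < 0)) stop("observed must be non-negative")
  vapply(observed_per_marker, function(obs) {
    if (obs == 0) return(0)
    if (smm_expected_observed(lambda_max, kmax) < obs) {
      stop("saturated: observed displacement ", obs,
           " is beyond the model ceiling")
    }
    # E|X| <= lambda, so the root lies in [obs, lambda_max]
    lo <- obs
    hi <- obs * 2
    while (smm_expected_observed(hi, kmax) < obs && hi < lambda_max) {
      hi <- min(2 * hi, lambda_max)
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (smm_expected_observed(mid, kmax) < obs) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}
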