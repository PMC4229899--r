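#' Default prior proportion of the target population
#'
#' The worldwide Jewish fraction used for the posterior point estimate:
#' roughly 13 million people out of a global population of 7.2 billion.
#' Both numbers are configuration constants, not hard-coded into the
#' computation.
#'
#' @param population Size of the target population (default 13e6).
#' @param world Global population (default 7.2e9).
#' @return The prior proportion.
#' @export
default_prior <- function(population = 13e6, world = 7.2e9) {
  population / world
}

#' Posterior probability of group membership given a motif
#'
#' Bayes' rule with two populations: if a motif has frequency `p1` in the
#' target group and `p0` elsewhere, and the target group makes up a
#' proportion `prior` of the population, then a random motif carrier
#' belongs to the target group with probability
#' `p1 * prior / (p1 * prior + p0 * (1 - prior))`.
#'
#' @param p1 Motif frequency in the target group, in `[0, 1]`.
#' @param p0 Motif frequency in the rest of the population, in `[0, 1]`.
#' @param prior Prior proportion of the target group, in `[0, 1]`.
#' @return Posterior probability in `[0, 1]`. Vectorized.
#' @export
#' @examples
#' bayes_posterior(343 / 5281, 419 / 57639, default_prior())  # ~0.016
bayes_posterior <- function(p1, p0, prior) {
  if (any(c(p1, p0, prior) < 0 | c(p1, p0, prior) > 1)) {
    stop("p1, p0 and prior must lie in [0, 1]")
  }
  denom <- p1 * prior + p0 * (1 - prior)
  if (any(denom == 0)) stop("motif absent from population (zero denominator)")
  p1 * prior / denom
}

#' Posterior curve over a grid of prior proportions
#'
#' Estimates the two carrier frequencies from a motif count table
#' (plug-in maximum-likelihood ratios `total / N` per group; optionally
#' Jeffreys-adjusted by adding 1/2 to counts and 1 to denominators, for
#' motifs with a zero count in one group whose plug-in posterior would be
#' degenerate at 0 or 1) and evaluates the posterior on a log-spaced grid
#' of priors over `(1e-6, 1 - 1e-6)`, plus the point estimate at the
#' default worldwide prior.
#'
#' @param counts A [count_table()] with groups `jewish` and `non_jewish`.
#' @param grid_size Number of grid points (default 1000).
#' @param prior_star Prior for the point estimate (default
#'   [default_prior()]).
#' @param jeffreys Use the Jeffreys zero-count adjustment?
#' @return Object of class `posterior_curve`: `tag`, `p1`, `p0`, `grid`,
#'   `posterior`, `prior_star`, `point_estimate`, `jeffreys`.
#' @export
posterior_curve <- function(counts, grid_size = 1000,
                            prior_star = default_prior(), jeffreys = FALSE) {
  stopifnot(inherits(counts, "motif_count_table"))
  n <- counts$n
  if (any(n == 0)) stop("zero group size")
  k1 <- counts$totals[["jewish"]]
  k0 <- counts$totals[["non_jewish"]]
  if (jeffreys) {
    p1 <- (k1 + 0.5) / (n[["jewish"]] + 1)
    p0 <- (k0 + 0.5) / (n[["non_jewish"]] + 1)
  } else {
    p1 <- k1 / n[["jewish"]]
    p0 <- k0 / n[["non_jewish"]]
    if ((p0 == 0 && p1 > 0) || (p1 == 0 && p0 > 0)) {
      warning("zero carrier count in one group: plug-in posterior is ",
              "degenerate; consider jeffreys = TRUE")
    }
  }
  grid <- exp(seq(log(1e-6), log(1 - 1e-6), length.out = grid_size))
  post <- if (p1 == 0 && p0 == 0) rep(NA_real_, grid_size) else
    bayes_posterior(p1, p0, grid)
  point <- if (p1 == 0 && p0 == 0) NA_real_ else
    bayes_posterior(p1, p0, prior_star)
  structure(list(tag = counts$tag, p1 = p1, p0 = p0, grid = grid,
                 posterior = post, prior_star = prior_star,
                 point_estimate = point, jeffreys = jeffreys),
            class = "posterior_curve")
}

#' @export
print.posterior_curve <- function(x, ...) {
  cat(sprintf("<posterior_curve %s> p1 = %.4g, p0 = %.4g\n",
              x$tag, x$p1, x$p0))
  cat(sprintf("  posterior at prior %.4g: %.4g\n",
              x$prior_star, x$point_estimate))
  invisible(x)
}

#' @export
#' @rdname posterior_curve
#' @param x A `posterior_curve`.
#' @param ... Passed to [graphics::plot()].
plot.posterior_curve <- function(x, ...) {
  graphics::plot(x$grid, x$posterior, type = "l", log = "x",
                 xlab = "prior proportion of target group",
                 ylab = "posterior probability", main = x$tag, ...)
  graphics::points(x$prior_star, x$point_estimate, pch = 19, col = "red")
  invisible(x)
}

#' Write a posterior curve as TSV
#' @param x A `posterior_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_posterior_curve <- function(x, path) {
  utils::write.table(
    data.frame(prior = c(x$grid, x$prior_star),
               posterior = c(x$posterior, x$point_estimate),
               point = c(rep(FALSE, length(x$grid)), TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
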