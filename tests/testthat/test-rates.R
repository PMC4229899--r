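models <- load_rate_models()

test_that("packaged rate models carry the published constants and round-trip", {
  expect_equal(models$genealogical$per_marker_rate, 0.00166)
  expect_equal(models$genealogical$per_haplotype_rate, 0.020)
  expect_equal(models$germline$per_marker_rate, 2.113e-3)
  expect_equal(models$germline$per_marker_sd, 1.369e-3)
  expect_equal(models$germline$per_haplotype_rate, 0.025)
  expect_equal(models$germline$extra$meioses, 126873)
  expect_equal(models$hvs1_pedigree$per_haplotype_rate, 1.06e-2)
  expect_equal(models$hvs1_fossil$per_haplotype_rate, 1.42e-3)
  # haplotype rates are printed roundings of per-marker x 12
  expect_equal(models$genealogical$per_marker_rate * 12, 0.020,
               tolerance = 5e-3)
  expect_equal(models$germline$per_marker_rate * 12, 0.025,
               tolerance = 2e-2)

  tf <- tempfile(fileext = ".yaml")
  write_rate_models(models, tf)
  back <- load_rate_models(tf)
  for (nm in names(models)) {
    expect_equal(back[[nm]]$per_haplotype_rate,
                 models[[nm]]$per_haplotype_rate)
    expect_equal(back[[nm]]$per_marker_rate, models[[nm]]$per_marker_rate)
  }
})

test_that("pedigree pooling: per-locus rates, fallbacks, and invariances", {
  studies <- data.frame(
    study = c("s1", "s2", "s1"),
    locus = c("A", "A", "B"),
    meioses = c(1000, 1000, 2000),
    mutations = c(3, 1, 0)
  )
  m <- aggregate_germline(studies, panel = c("A", "B"),
                          fallback_rates = c(B = 0.5e-3))
  expect_equal(unname(m$per_locus_rates), c(2e-3, 0.5e-3))
  expect_equal(m$per_marker_rate, 1.25e-3)
  expect_equal(m$per_haplotype_rate, 2.5e-3)

  # single zero-mutation locus takes the fallback verbatim
  one <- aggregate_germline(
    data.frame(study = "s", locus = "A", meioses = 500, mutations = 0),
    panel = "A", fallback_rates = c(A = 0.458e-3))
  expect_equal(one$per_haplotype_rate, 0.458e-3)

  # pooling is invariant to splitting a study with the same totals
  split <- data.frame(study = c("x1", "x2"), locus = "A",
                      meioses = c(400, 600), mutations = c(1, 3))
  merged <- data.frame(study = "x", locus = "A", meioses = 1000,
                       mutations = 4)
  expect_equal(aggregate_germline(split, "A")$per_marker_rate,
               aggregate_germline(merged, "A")$per_marker_rate)

  expect_error(aggregate_germline(
    data.frame(study = "s", locus = "A", meioses = 0, mutations = 0),
    panel = "A"), "fallback")
})

test_that("mutation intervals reproduce the discussion arithmetic", {
  expect_equal(mutation_interval(models$germline), 40L)
  expect_equal(mutation_interval(models$nry_sites), 3L)
  expect_equal(mutation_interval(models$hvs1_pedigree), 94L)
  # the HVS-I interval also follows from the raw pedigree counts
  howell <- rate_model("howell", per_marker_rate = 28 / 2633, n_markers = 1)
  expect_equal(mutation_interval(howell), 94L)
  # override recomputes from the per-marker rate
  expect_equal(mutation_interval(models$germline, n_markers_override = 6),
               as.integer(round(1 / (2.113e-3 * 6))))
})

test_that("rate ratios: pedigree vs fossil HVS-I rate is about sevenfold", {
  r <- rate_ratio(models$hvs1_pedigree, models$hvs1_fossil)
  expect_equal(r, 1.06e-2 / 1.42e-3, tolerance = 1e-12)
  expect_equal(round(r), 7)
  expect_equal(rate_ratio(models$germline, models$germline), 1.0)
  expect_equal(rate_ratio(models$genealogical, models$germline), 0.8)
})

test_that("SMM expectation matches the Skellam convolution oracle", {
  expect_equal(smm_expected_observed(0), 0)
  for (l in c(0.05, 0.3, 1.0)) {
    expect_equal(smm_expected_observed(l),
                 oracle_expected_abs_displacement(l), tolerance = 1e-10)
  }
  x <- smm_expected_observed(0.05)
  expect_gt(x, 0.0487)
  expect_lt(x, 0.05)
  # observable fraction decreases with the true load
  grid <- c(1e-6, 0.01, 0.1, 0.5, 1, 2)
  frac <- smm_expected_observed(grid) / grid
  expect_true(all(diff(frac) < 0))
  expect_equal(frac[1], 1, tolerance = 1e-6)
  expect_lt(smm_expected_observed(0.5), smm_expected_observed(1.0))
})

test_that("back-correction inverts the expectation and never shrinks", {
  expect_equal(back_correct(0), 0)
  for (x in c(0.05, 0.3, 0.8)) {
    expect_equal(back_correct(smm_expected_observed(x)), x,
                 tolerance = 1e-8)
  }
  obs <- c(0.01, 0.2, 0.6)
  expect_true(all(back_correct(obs) >= obs))
  expect_error(back_correct(60), "saturated")
})
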