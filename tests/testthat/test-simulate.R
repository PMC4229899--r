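test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 21, n_jewish = 150, n_non_jewish = 300)
  a <- simulate_database(cfg)
  b <- simulate_database(cfg)
  expect_identical(a, b)
  c_ <- simulate_database(sim_config(seed = 22, n_jewish = 150,
                                     n_non_jewish = 300))
  expect_false(identical(a$y_db, c_$y_db))
})

test_that("planted truth ledger exactly matches motif counts without mutation", {
  cfg <- sim_config(seed = 9, n_jewish = 400, n_non_jewish = 800)
  sim <- simulate_database(cfg)
  motifs <- load_motifs()
  for (tag in unique(sim$expected_counts$motif)) {
    m <- motifs[[tag]]
    db <- if (m$system == "hvs1") sim$mt_db else sim$y_db
    ct <- build_count_table(db, m)
    for (g in c("jewish", "non_jewish")) {
      exp_n <- sim$expected_counts$count[
        sim$expected_counts$motif == tag & sim$expected_counts$group == g]
      expect_equal(unname(ct$totals[[g]]), exp_n,
                   label = paste(tag, g, "count"))
    }
  }
})

test_that("zero motif frequencies yield zero matches", {
  freqs <- lapply(default_motif_freqs(), function(f) f * 0)
  sim <- simulate_database(sim_config(seed = 4, n_jewish = 200,
                                      n_non_jewish = 200,
                                      motif_freqs = freqs))
  motifs <- load_motifs()
  expect_equal(nrow(sim$truth), 0)
  for (tag in names(motifs)) {
    db <- if (motifs[[tag]]$system == "hvs1") sim$mt_db else sim$y_db
    hit <- match_motif(db, motifs[[tag]])
    expect_equal(sum(hit, na.rm = TRUE), 0, label = tag)
  }
})

test_that("planted carrier fractions recover the configured frequencies", {
  # CMH planted at the published frequencies in a large database: the
  # carrier count falls inside the binomial 99% interval of expectation
  cfg <- sim_config(seed = 7)  # defaults: 5281 / 57,639, published freqs
  sim <- simulate_database(cfg)
  ct <- build_count_table(sim$y_db, load_motifs()$CMH)
  for (g in c("jewish", "non_jewish")) {
    n <- cfg[[if (g == "jewish") "n_jewish" else "n_non_jewish"]]
    p <- cfg$motif_freqs$CMH[[g]] + cfg$motif_freqs$eCMH[[g]]
    bounds <- qbinom(c(0.005, 0.995), n, p)
    expect_gte(ct$totals[[g]], bounds[1])
    expect_lte(ct$totals[[g]], bounds[2])
  }
})

test_that("star genealogy: exact at t = 0, displacement matches the SMM law", {
  rates <- stats::setNames(rep(0.025 / 12, 12), ystr_panel("ystr12"))
  founder <- stats::setNames(rep(14L, 12), names(rates))
  H0 <- simulate_star_genealogy(founder, 20, 0, rates, seed = 1)
  expect_true(all(t(H0) == founder))

  H <- simulate_star_genealogy(founder, 500, 40, rates, seed = 2)
  disp <- rowSums(abs(t(t(H) - founder)))
  expected <- sum(smm_expected_observed(unname(rates) * 40))
  se <- sd(disp) / sqrt(length(disp))
  expect_lt(abs(mean(disp) - expected), 3 * se)

  H2 <- simulate_star_genealogy(founder, 20, 40, rates, seed = 3)
  expect_false(identical(
    simulate_star_genealogy(founder, 20, 40, rates, seed = 4), H2))
})

test_that("HVS-I simulation: identity at t = 0 and hotspot recurrence excess", {
  # founder substitutions constructed against the packaged reference so
  # every token genuinely differs from the ancestral base
  ref <- strsplit(paste(readLines(
    motifscan_file("hvs1_reference_synthetic.fasta"))[-1], collapse = ""),
    "")[[1]]
  mk <- function(pos) {
    paste0(pos, setdiff(c("A", "C", "G", "T"), ref[pos - 16023])[1])
  }
  founder <- vapply(c(16224L, 16311L, 16391L), mk, character(1))
  db0 <- simulate_hvs1(founder, 10, 0, seed = 1)
  expect_true(all(vapply(db0$substitutions, function(s)
    setequal(hvs1_set(s), founder), logical(1))))

  # a 10x hotspot at 16519 accumulates more changes than a cold site
  db <- simulate_hvs1(character(0), 400, 60,
                      hotspots = c("16519" = 10), seed = 5)
  pos <- unlist(lapply(db$substitutions, function(s)
    hvs1_positions(hvs1_set(s, warn = FALSE))))
  hot_hits <- sum(pos == 16519)
  cold_hits <- tabulate(pos - 16023, nbins = 546)
  cold_median <- stats::median(cold_hits[-(16519 - 16023)])
  expect_gt(hot_hits, 3 * max(1, cold_median))
})

test_that("deliberately failing records are produced and then filtered out", {
  cfg <- sim_config(seed = 13, n_jewish = 300, n_non_jewish = 300,
                    fail_fraction = 0.1)
  sim <- simulate_database(cfg)
  fy <- filter_records(sim$y_db, "y")
  fmt <- filter_records(sim$mt_db, "mt")
  expect_lt(nrow(fy$kept), nrow(sim$y_db))
  expect_lt(nrow(fmt$kept), nrow(sim$mt_db))
  r <- fy$report
  expect_equal(r$n_kept + (r$n_input - r$n_deduplicated) +
                 r$n_failed_loci + r$n_failed_haplogroup, r$n_input)
})
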