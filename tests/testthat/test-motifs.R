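motifs <- load_motifs()

test_that("packaged motifs are internally consistent and round-trip YAML", {
  # the extended motifs restrict to their classical 6-locus versions
  six <- ystr_panel("ystr6")
  expect_equal(motifs$eCMH$y_alleles[six], motifs$CMH$y_alleles[six])
  expect_equal(motifs$eLMH$y_alleles[six], motifs$LMH$y_alleles[six])
  # classical CMH allele vector (DYS19, DYS388, DYS390, DYS391, DYS392,
  # DYS393 = 14 16 23 10 11 12)
  expect_equal(unname(motifs$CMH$y_alleles), c(14L, 16L, 23L, 10L, 11L, 12L))
  expect_equal(motifs$eCMH$y_alleles[["DYS439"]], 12L)
  expect_equal(motifs$K3$mt_substitutions, c("16224C", "16311C", "16519C"))
  # K3 is nested inside both K1 and K2 as a set
  expect_true(all(motifs$K3$mt_substitutions %in% motifs$K1$mt_substitutions))

  # serialization round trip through the YAML resource format
  tf <- tempfile(fileext = ".yaml")
  file.copy(motifscan_file("motifs.yaml"), tf)
  expect_equal(load_motifs(tf), motifs)
})

test_that("Y motif matching is exact, unordered at DYS385, NA when untyped", {
  cmh6 <- c(DYS19 = 14L, DYS388 = 16L, DYS390 = 23L, DYS391 = 10L,
            DYS392 = 11L, DYS393 = 12L)
  df <- make_y_df(3)
  for (l in names(cmh6)) df[1:2, l] <- cmh6[[l]]
  df[2, "DYS391"] <- 11L              # one-step mismatch
  db <- ystr_db(df, validate = FALSE)
  expect_equal(match_y_motif(db, motifs$CMH), c(TRUE, FALSE, FALSE))

  # DYS385 compared as an unordered pair
  df12 <- plant_y_motif(make_y_df(1), 1, motifs$eCMH)
  db12 <- ystr_db(df12, validate = FALSE)
  expect_true(match_y_motif(db12, motifs$eCMH))
  # swap the stored pair: still a match because both sides sort
  tmp <- db12$DYS385a; db12$DYS385a <- db12$DYS385b; db12$DYS385b <- tmp
  db12 <- ystr_db(as.data.frame(db12), validate = FALSE)
  expect_true(match_y_motif(db12, motifs$eCMH))

  df[3, "DYS388"] <- NA
  db <- ystr_db(df, validate = FALSE)
  expect_true(is.na(match_y_motif(db, motifs$CMH)[3]))
})

test_that("mtDNA matching: exact-set default keeps the K motifs disjoint", {
  db <- mtdna_db(make_mt_df(c(
    "16224C 16311C 16519C",                       # K3 exactly
    "16093C 16224C 16311C 16519C 16524G",         # K1 exactly (superset of K3)
    "",                                           # empty
    "16145A 16176A 16223T 16390A 16519C"          # N
  )))
  expect_equal(match_mt_motif(db, motifs$K3), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(match_mt_motif(db, motifs$K1), c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(match_mt_motif(db, motifs$N), c(FALSE, FALSE, FALSE, TRUE))
  # subset-containment mode sees K3 inside the K1 record
  expect_equal(match_mt_motif(db, motifs$K3, mode = "subset"),
               c(TRUE, TRUE, FALSE, FALSE))
})

test_that("exact-set matching makes K1/K2/K3 mutually exclusive (property)", {
  set.seed(7)
  sets <- replicate(60, {
    k <- sample(0:6, 1)
    pos <- sample(16024:16569, k)
    paste(sprintf("%d%s", sort(pos),
                  sample(c("A", "C", "G", "T"), k, replace = TRUE)),
          collapse = " ")
  })
  sets <- c(sets, "16224C 16311C 16519C",
            "16093C 16224C 16311C 16519C 16524G",
            "16224C 16234T 16311C 16519C")
  db <- mtdna_db(make_mt_df(sets))
  hits <- cbind(match_mt_motif(db, motifs$K1),
                match_mt_motif(db, motifs$K2),
                match_mt_motif(db, motifs$K3))
  expect_true(all(rowSums(hits) <= 1))
})

test_that("every extended-motif match is a match of its classical motif", {
  sim <- simulate_database(sim_config(seed = 11, n_jewish = 300,
                                      n_non_jewish = 600))
  y <- sim$y_db
  for (pair in list(c("eCMH", "CMH"), c("eLMH", "LMH"))) {
    ext <- match_y_motif(y, motifs[[pair[1]]])
    cls <- match_y_motif(y, motifs[[pair[2]]])
    idx <- !is.na(ext) & ext
    expect_true(all(cls[idx]))
  }
})

test_that("count tables stratify matches and reproduce published totals", {
  ct <- published_count_table("CMH")
  expect_equal(unname(ct$totals), c(343L, 419L))
  expect_equal(unname(ct$pct), c(6.5, 0.7))
  m <- as_contingency(ct)
  expect_equal(unname(colSums(m)), c(5281, 57639))
  expect_equal(unname(m["J1-M267", ]), c(196L, 236L))

  # empty record list -> all-zero table
  empty <- build_count_table(ystr_db(make_y_df(0)), motifs$CMH)
  expect_equal(sum(empty$totals), 0)
  expect_equal(nrow(empty$rows), 0)
})
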