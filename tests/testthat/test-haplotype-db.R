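test_that("TSV round trip preserves records, including combined DYS385", {
  tf <- tempfile(fileext = ".tsv")
  df <- make_y_df(3)
  db <- ystr_db(df)
  write_y_database(db, tf)
  back <- read_y_database(tf)
  attr(back, "load_report") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(db))
  expect_equal(n_loci_typed(back), rep(12L, 3))

  # combined DYS385 "a-b" column and hyphenated DYS389 headers
  tf2 <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("kit_id", "group", "haplogroup", "hg_evidence", "DYS393",
          "DYS390", "DYS19", "DYS391", "DYS385", "DYS426", "DYS388",
          "DYS439", "DYS389-I", "DYS392", "DYS389-II", sep = "\t"),
    paste("A1", "jewish", "J1", "snp_typed", 12, 23, 14, 10, "15-13",
          11, 16, 12, 13, 11, 30, sep = "\t")
  ), tf2)
  db2 <- read_y_database(tf2)
  expect_equal(db2$DYS385a, 13L)  # stored sorted ascending
  expect_equal(db2$DYS385b, 15L)
  expect_equal(db2$DYS389II, 30L)
  # round trip through canonical columns
  tf3 <- tempfile(fileext = ".tsv")
  write_y_database(db2, tf3)
  expect_equal(as.data.frame(read_y_database(tf3)), as.data.frame(db2))
})

test_that("unknown locus columns are a hard error; bad alleles go to the load report", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("kit_id\tgroup\thaplogroup\thg_evidence\tNOTALOCUS",
               "A1\tjewish\tJ1\tsnp_typed\t12"), tf)
  expect_error(read_y_database(tf), "NOTALOCUS")

  tf2 <- tempfile(fileext = ".tsv")
  writeLines(c("kit_id\tgroup\thaplogroup\thg_evidence\tDYS393\tDYS390",
               "A1\tjewish\tJ1\tsnp_typed\t12\t23",
               "A2\tjewish\tJ1\tsnp_typed\ttwelve\t23"), tf2)
  db <- read_y_database(tf2)
  expect_equal(nrow(db), 1)
  rep <- attr(db, "load_report")
  expect_equal(rep$column, "DYS393")
  expect_equal(rep$value, "twelve")
})

test_that("DYS439 normalization subtracts 4 from raw exports and is idempotent", {
  db <- ystr_db(make_y_df(1))
  db$DYS439 <- 16L
  std <- normalize_dys439(db, "ftdna_raw")
  expect_equal(std$DYS439, 12L)
  expect_equal(normalize_dys439(std, "standard")$DYS439, 12L)
  db$DYS439 <- 7L
  expect_error(normalize_dys439(db, "ftdna_raw"), "implausible")
})

test_that("DYS389b is the strictly positive difference of the compound allele", {
  db <- ystr_db(make_y_df(1))
  db$DYS389I <- 13L; db$DYS389II <- 30L
  expect_equal(derive_dys389b(db), 17L)
  db$DYS389II <- 13L
  expect_error(derive_dys389b(db), "exceed")
})

test_that("filtering applies dedup, typing/coverage and evidence rules in order", {
  df <- make_y_df(5)
  df[1, "DYS392"] <- NA; df[1, "DYS426"] <- NA  # 10 loci -> fails
  res <- filter_records(ystr_db(df), "y")
  expect_equal(res$report$n_failed_loci, 1)
  expect_equal(nrow(res$kept), 4)

  mt <- mtdna_db(make_mt_df(c("16224C 16311C 16519C", "", "16093C")))
  mt$covered_end[2] <- 16400L
  res_mt <- filter_records(mt, "mt")
  expect_equal(nrow(res_mt$kept), 2)
  expect_equal(res_mt$report$n_failed_loci, 1)

  dup <- make_y_df(4)
  dup$kit_id[3] <- dup$kit_id[1]
  res_dup <- filter_records(ystr_db(dup, validate = FALSE), "y")
  expect_equal(nrow(res_dup$kept), 3)
  expect_equal(res_dup$report$n_deduplicated, 3)

  empty <- filter_records(ystr_db(make_y_df(0)), "y")
  expect_equal(empty$report$n_input, 0)
  expect_equal(nrow(empty$kept), 0)
})

test_that("filter report counts conserve and filtering is idempotent (property)", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    df <- make_y_df(n)
    # random spoilage
    short <- sample(n, sample(0:3, 1))
    for (i in short) df[i, sample(ystr_panel("ystr12"), 3)] <- NA
    df$hg_evidence[sample(n, sample(0:3, 1))] <- NA
    df$kit_id[sample(n, sample(0:2, 1))] <- df$kit_id[1]
    res <- filter_records(ystr_db(df, validate = FALSE), "y")
    r <- res$report
    expect_equal(r$n_kept + (r$n_input - r$n_deduplicated) +
                   r$n_failed_loci + r$n_failed_haplogroup, r$n_input)
    res2 <- filter_records(res$kept, "y")
    expect_equal(as.data.frame(res2$kept), as.data.frame(res$kept))
    expect_equal(res2$report$n_kept, res2$report$n_input)
  }
})

test_that("HVS-I parsing keeps substitutions and drops indels/heteroplasmies", {
  expect_warning(s <- hvs1_set("16093C 16188.1C 16166d 16224C 16311Y"),
                 "dropping")
  expect_setequal(s, c("16093C", "16224C"))
  expect_equal(hvs1_positions(c("16093C", "16519C")), c(16093L, 16519L))
  expect_equal(sort_hvs1(c("16519C", "16093C")), c("16093C", "16519C"))
})

test_that("FASTA import recovers substitution sets by diff against the reference", {
  ref_path <- motifscan_file("hvs1_reference_synthetic.fasta")
  ref <- readLines(ref_path)
  seq <- paste(ref[-1], collapse = "")
  chars <- strsplit(seq, "")[[1]]
  # plant two substitutions at known coordinates
  p1 <- 16093 - 16024 + 1; p2 <- 16519 - 16024 + 1
  new1 <- setdiff(c("A", "C", "G", "T"), chars[p1])[1]
  new2 <- setdiff(c("A", "C", "G", "T"), chars[p2])[1]
  mut <- chars; mut[p1] <- new1; mut[p2] <- new2
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">S1", paste(mut, collapse = ""),
               ">S2", paste(chars, collapse = "")), tf)
  db <- read_hvs1_fasta(tf)
  expect_equal(hvs1_set(db$substitutions[1]),
               c(paste0(16093, new1), paste0(16519, new2)))
  expect_equal(db$substitutions[2], "")
  expect_equal(db$covered_start, c(16024L, 16024L))
  expect_equal(db$covered_end, c(16569L, 16569L))
})
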