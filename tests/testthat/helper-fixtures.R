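# Shared builders and independent oracles for the test suite.

# small Y database builder over the 12-locus panel
make_y_df <- function(n = 3, group = "jewish", haplogroup = "J1-M267",
                      hg_evidence = "snp_typed", alleles = NULL) {
  panel <- ystr_panel("ystr12")
  if (is.null(alleles)) {
    alleles <- stats::setNames(rep(12L, length(panel)), panel)
    alleles["DYS389II"] <- 29L
  }
  df <- data.frame(kit_id = sprintf("K%03d", seq_len(n)),
                   group = rep(group, n), haplogroup = rep(haplogroup, n),
                   hg_evidence = rep(hg_evidence, n),
                   stringsAsFactors = FALSE)
  for (l in panel) df[[l]] <- rep(alleles[[l]], n)
  df
}

make_mt_df <- function(substitutions, group = "jewish", haplogroup = "K",
                       hg_evidence = "snp_typed",
                       covered_start = 16024L, covered_end = 16569L) {
  n <- length(substitutions)
  data.frame(kit_id = sprintf("M%03d", seq_len(n)), group = group,
             haplogroup = haplogroup, hg_evidence = hg_evidence,
             substitutions = substitutions,
             covered_start = covered_start, covered_end = covered_end,
             stringsAsFactors = FALSE)
}

# set a record's alleles to a Y motif's state
plant_y_motif <- function(df, rows, motif) {
  for (l in names(motif$y_alleles)) df[rows, l] <- motif$y_alleles[[l]]
  df
}

# independent Skellam oracle: E|X| by direct convolution of two Poissons
oracle_expected_abs_displacement <- function(lambda, kmax = 60) {
  mu <- lambda / 2
  k <- -kmax:kmax
  pk <- vapply(k, function(kk) {
    j <- 0:kmax
    sum(stats::dpois(j + abs(kk), mu) * stats::dpois(j, mu))
  }, numeric(1))
  sum(abs(k) * pk)
}

# independent Pearson chi-square: brute-force double loop
oracle_pearson <- function(m) {
  rs <- rowSums(m); cs <- colSums(m); N <- sum(m)
  out <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- rs[i] * cs[j] / N
      out <- out + (m[i, j] - e)^2 / e
    }
  }
  out
}

# independent MST total cost over rows of a haplotype matrix (weighted L1)
oracle_mst_cost <- function(H, w = rep(1, ncol(H))) {
  D <- matrix(0, nrow(H), nrow(H))
  for (l in seq_len(ncol(H))) {
    D <- D + w[l] * abs(outer(H[, l], H[, l], "-"))
  }
  if (nrow(H) < 2) return(0)
  tr <- vegan::spantree(stats::as.dist(D))
  sum(tr$dist)
}

# brute-force optimal cost for a 3-haplotype instance allowing one Steiner
# point anywhere in the per-locus bounding box (unit weights)
oracle_three_point_cost <- function(H) {
  d <- function(a, b) sum(abs(a - b))
  mst <- min(d(H[1, ], H[2, ]) + d(H[1, ], H[3, ]),
             d(H[1, ], H[2, ]) + d(H[2, ], H[3, ]),
             d(H[1, ], H[3, ]) + d(H[2, ], H[3, ]))
  ranges <- lapply(seq_len(ncol(H)), function(l)
    seq(min(H[, l]), max(H[, l])))
  grid <- as.matrix(expand.grid(ranges))
  star <- min(apply(grid, 1, function(s)
    d(s, H[1, ]) + d(s, H[2, ]) + d(s, H[3, ])))
  min(mst, star)
}
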