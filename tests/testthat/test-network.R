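models <- load_rate_models()

test_that("locus weights follow the inverse-variance scoring rule", {
  # equal variance at both loci -> both weights 10
  H <- rbind(c(10, 20), c(11, 21), c(12, 22))
  expect_equal(locus_weights(H), c(10L, 10L))
  # one locus with 4x the mean of-the-two variance ratio: 10 * (mean/var)
  # where var2 = 4 * var1 gives weights round(10*2.5/1)=25, round(10*2.5/4)=6
  H2 <- rbind(c(10, 20), c(11, 22), c(12, 24))
  v <- apply(H2, 2, var)
  expect_equal(locus_weights(H2),
               as.integer(round(10 * mean(v) / v)))
  # a constant locus takes the cap
  H3 <- rbind(c(10, 7), c(11, 7), c(13, 7))
  expect_equal(locus_weights(H3)[2], 99L)
  expect_error(locus_weights(rbind(c(1, 1), c(1, 1))), "distinct")
})

test_that("median joining: simple instances and the star-able triple", {
  # two haplotypes one step apart: a single edge, no medians
  net2 <- median_joining(rbind(c(10, 10), c(11, 10)))
  expect_equal(nrow(net2$edges), 1)
  expect_equal(sum(!net2$observed), 0)
  expect_equal(net2$cost, 1)

  # three haplotypes pairwise 2 apart on distinct loci: one median node
  # joined to all three by unit edges
  H <- rbind(c(11, 10, 10, 10), c(10, 11, 10, 10), c(10, 10, 11, 10))
  net <- median_joining(H)
  expect_equal(sum(!net$observed), 1)
  expect_equal(nrow(net$edges), 3)
  expect_equal(sort(net$edges$length), c(1, 1, 1))
  expect_equal(net$cost, 3)
  # the inferred median is the cell-wise consensus
  expect_equal(unname(net$haplotypes[!net$observed, ]), c(10, 10, 10, 10))

  # the classic binary 3-taxon instance resolves through its median
  B <- rbind(c(1, 1, 0, 0), c(0, 1, 1, 0), c(1, 0, 1, 1))
  netb <- median_joining(B)
  expect_equal(netb$cost, oracle_three_point_cost(B))
})

test_that("median insertion never increases the spanning cost (SMM property)", {
  rates <- stats::setNames(rep(0.025 / 10, 10),
                           paste0("L", 1:10))
  founder <- stats::setNames(rep(14L, 10), names(rates))
  for (s in 1:5) {
    H <- simulate_star_genealogy(founder, 20, 60, rates, seed = 100 + s)
    net <- median_joining(H)
    expect_lte(net$cost, oracle_mst_cost(unique(H)) + 1e-9)
    # the network stays connected and keeps every observed haplotype
    g <- as_igraph(net)
    expect_equal(igraph::components(g)$no, 1)
    expect_equal(sum(net$observed), nrow(unique(H)))
  }
})

test_that("root selection: modal node with documented tie-breaks", {
  H <- rbind(A = c(10, 10), B = c(11, 10), C = c(12, 10))
  net <- median_joining(H, multiplicities = c(5L, 2L, 1L))
  expect_equal(choose_root(net), "A")
  net_tie <- median_joining(H[1:2, ], multiplicities = c(3L, 3L))
  # tie -> lexicographically smaller haplotype vector (10,10) < (11,10)
  expect_equal(net_tie$haplotypes[choose_root(net_tie), ],
               c(10, 10), ignore_attr = TRUE)
  one <- median_joining(H[1, , drop = FALSE])
  expect_equal(choose_root(one), rownames(one$haplotypes))
  expect_error(choose_root(net, "outgroup", "nope"), "not in the network")
})

test_that("rho and its error reproduce hand-computed star cases", {
  # all samples identical to the root: rho = 0, t = 0
  H0 <- matrix(rep(c(12, 12, 12), 4), 4, 3, byrow = TRUE)
  net0 <- median_joining(H0)
  est0 <- rho_tmrca(net0, choose_root(net0), models$genealogical,
                    correct = "none")
  expect_equal(est0$rho, 0)
  expect_equal(est0$t_years, 0)

  # star of 10 tips, each one step from the root, root itself sampled
  # heavily so it is modal
  root <- rep(12L, 10)
  tips <- t(vapply(1:10, function(i) {
    v <- root; v[i] <- v[i] + 1L; v
  }, integer(10)))
  H <- rbind(root, tips)
  net <- median_joining(H, multiplicities = c(20L, rep(1L, 10)))
  r <- choose_root(net)
  # rho over the 10 one-step tips plus 20 root copies = 10/30
  est <- rho_tmrca(net, r, models$genealogical, correct = "none")
  expect_equal(est$rho, 10 / 30)

  # tips only (root excluded from the sample): rho = 1, genealogical rate
  # 0.020/generation, 25-year generations -> 1250 years
  net_t <- median_joining(tips)
  # root the network at the founder state via a specified median/outgroup:
  # the founder is reconstructed as the central median vector
  centre <- rownames(net_t$haplotypes)[!net_t$observed]
  expect_length(centre, 1)
  est_t <- rho_tmrca(net_t, centre, models$genealogical, correct = "none")
  expect_equal(est_t$rho, 1.0)
  expect_equal(est_t$t_years, 1250)
  expect_equal(est_t$sigma, sqrt(10) / 10)

  # germ-line vs genealogical dating of the same network: 0.020/0.025
  est_g <- rho_tmrca(net_t, centre, models$germline, correct = "none")
  expect_equal(est_g$t_years / est_t$t_years, 0.8)

  # rho 0.94 at the genealogical rate dates to 1175 years (the clade-age
  # arithmetic: rho / 0.020 generations x 25 y)
  H94 <- rbind(root, tips)
  rownames(H94) <- c("anc", paste0("t", 1:10))
  mult <- c(3L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 4L, 3L)  # n = 50, sum d = 47
  net94 <- median_joining(H94, multiplicities = mult)
  est94 <- rho_tmrca(net94, choose_root(net94, "specified", "anc"),
                     models$genealogical, correct = "none")
  expect_equal(est94$rho, 47 / 50)
  expect_equal(est94$t_years, 1175)
})

test_that("network distances never undercut direct mutational distances", {
  rates <- stats::setNames(rep(0.003, 10), paste0("L", 1:10))
  founder <- stats::setNames(rep(14L, 10), names(rates))
  H <- simulate_star_genealogy(founder, 25, 50, rates, seed = 77)
  net <- median_joining(H)
  g <- as_igraph(net)
  root <- choose_root(net)
  obs <- rownames(net$haplotypes)[net$observed]
  d_net <- igraph::distances(g, v = root, to = obs,
                             weights = igraph::E(g)$steps)[1, ]
  d_direct <- colSums(abs(t(net$haplotypes[obs, , drop = FALSE]) -
                            net$haplotypes[root, ]))
  expect_true(all(d_net >= d_direct - 1e-9))
})

test_that("network exports are readable and carry multiplicities", {
  H <- rbind(A = c(10, 10), B = c(11, 10), C = c(11, 11))
  net <- median_joining(H, multiplicities = c(2L, 1L, 1L))
  tf <- tempfile()
  write_gml(net, paste0(tf, ".gml"))
  g <- igraph::read_graph(paste0(tf, ".gml"), format = "gml")
  expect_equal(igraph::vcount(g), 3)
  files <- write_fluxus(net, tf)
  nodes <- read.delim(paste0(tf, ".nodes.tsv"))
  expect_equal(sum(nodes$multiplicity), 4)
})
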