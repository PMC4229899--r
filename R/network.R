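# Weighted median-joining networks and rho-statistic dating.
#
# Nodes are haplotype vectors: integer repeat counts over a Y-STR panel, or
# 0/1 indicators over observed HVS-I substitutions. Distances are per-locus
# weighted L1 ("length"); mutational steps are the unweighted L1 distance.
# Weights guide topology only; rho always counts unweighted steps.

# weighted L1 distance matrix between rows of A (and B)
.wdist <- function(A, B = NULL, w = NULL) {
  if (is.null(B)) B <- A
  if (is.null(w)) w <- rep(1, ncol(A))
  d <- matrix(0, nrow(A), nrow(B))
  for (l in seq_len(ncol(A))) {
    d <- d + w[l] * abs(outer(A[, l], B[, l], "-"))
  }
  d
}

# Prim's algorithm on a dense distance matrix; deterministic tie-break by
# node index. Returns the edge list and total cost.
.mst_edges <- function(D) {
  n <- nrow(D)
  if (n <= 1) return(list(edges = matrix(0L, 0, 2), cost = 0))
  in_tree <- logical(n)
  in_tree[1] <- TRUE
  best <- D[1, ]
  parent <- rep(1L, n)
  edges <- matrix(0L, n - 1L, 2)
  cost <- 0
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    i <- cand[which.min(best[cand])]
    cost <- cost + best[i]
    edges[k, ] <- c(parent[i], i)
    in_tree[i] <- TRUE
    upd <- which(!in_tree & D[i, ] < best)
    parent[upd] <- i
    best[upd] <- D[i, upd]
  }
  list(edges = edges, cost = as.numeric(cost))
}

.mst_cost <- function(D) .mst_edges(D)$cost

# bottleneck (minimax-path) distances over the MST: for each pair, the
# largest edge on the unique tree path between them
.bottleneck <- function(mst, D) {
  n <- nrow(D)
  B <- matrix(0, n, n)
  if (n <= 1) return(B)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mst$edges))) {
    i <- mst$edges[k, 1]; j <- mst$edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  for (s in seq_len(n)) {
    seen <- logical(n)
    seen[s] <- TRUE
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (!seen[v]) {
          seen[v] <- TRUE
          B[s, v] <- max(B[s, u], D[u, v])
          queue <- c(queue, v)
        }
      }
    }
  }
  B
}

# minimum-spanning-network feasibility at tolerance epsilon: a link (u, v)
# is feasible iff d(u, v) <= bottleneck(u, v) + epsilon. epsilon = 0 keeps
# exactly the union of all minimum spanning trees.
.msn_links <- function(D, epsilon) {
  mst <- .mst_edges(D)
  B <- .bottleneck(mst, D)
  feas <- D <= B + epsilon + 1e-9
  diag(feas) <- FALSE
  feas
}

#' Variance-based locus weights for network construction
#'
#' Fast-mutating (high-variance) loci are down-weighted so that they do not
#' dominate the topology: the weight of a locus is
#' `round(10 * mean per-locus variance / variance at that locus)` (round
#' half-even, the base R rounding). Loci with zero variance get the cap
#' (they carry no topology information but must not create zero-length
#' edges); weights are clipped to `[1, cap]`. With equal variance at every
#' locus all weights are 10 — the same default weight given to HVS-I sites.
#'
#' @param haplotypes Integer matrix, one row per haplotype.
#' @param cap Weight assigned to constant loci and upper clip (default 99).
#' @return Integer vector of per-locus weights.
#' @export
locus_weights <- function(haplotypes, cap = 99L) {
  m <- as.matrix(haplotypes)
  if (nrow(unique(m)) < 2) stop("need at least 2 distinct haplotypes")
  v <- apply(m, 2, stats::var)
  if (all(v == 0)) stop("no variation at any locus")
  mv <- mean(v)
  w <- ifelse(v == 0, cap, round(10 * mv / v))
  as.integer(pmin(pmax(w, 1L), cap))
}

#' Median-joining haplotype network
#'
#' Builds the median-joining network of a set of haplotype vectors:
#' starting from the minimum spanning network at tolerance `epsilon`, every
#' connected triplet proposes its cell-wise median as a candidate node
#' (a hypothetical unsampled intermediate); the candidate whose insertion
#' most reduces the total spanning cost is added, and the loop repeats
#' until no candidate reduces cost. Median vectors that end up redundant
#' are pruned. The final network keeps all feasible minimum-spanning-
#' network links over observed plus retained median nodes, so it always
#' contains a minimum spanning tree of the input haplotypes.
#'
#' @param haplotypes Integer matrix (rows = haplotypes, columns = loci);
#'   duplicated rows are aggregated with summed multiplicities.
#' @param multiplicities Integer vector of sample counts per row
#'   (default 1 each).
#' @param weights Per-locus positive weights (default all 1); see
#'   [locus_weights()].
#' @param epsilon Non-negative spanning tolerance (default 0, the usual
#'   software default).
#' @return Object of class `haplo_network`: `haplotypes` (matrix incl.
#'   medians), `multiplicity` (0 for medians), `observed`, `edges` (data
#'   frame `from`, `to`, `length` (weighted), `steps` (unweighted)),
#'   `weights`, `epsilon`, `cost` (total spanning cost).
#' @export
median_joining <- function(haplotypes, multiplicities = NULL, weights = NULL,
                           epsilon = 0) {
  H <- as.matrix(haplotypes)
  storage.mode(H) <- "integer"
  if (any(is.na(H))) stop("haplotype vectors must be complete (no NA)")
  n0 <- nrow(H)
  if (n0 < 1) stop("need at least one haplotype")
  if (is.null(multiplicities)) multiplicities <- rep(1L, n0)
  stopifnot(length(multiplicities) == n0)
  if (is.null(weights)) weights <- rep(1, ncol(H))
  stopifnot(length(weights) == ncol(H), all(weights > 0), epsilon >= 0)

  # aggregate identical haplotypes
  key <- apply(H, 1, paste, collapse = ",")
  first <- !duplicated(key)
  mult <- as.integer(tapply(multiplicities, key, sum)[key[first]])
  H <- H[first, , drop = FALSE]
  labels <- rownames(H)
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels)) ||
      anyNA(labels)) {
    labels <- paste0("H", seq_len(nrow(H)))
  }
  rownames(H) <- NULL
  observed <- rep(TRUE, nrow(H))
  n_median <- 0L

  repeat {
    if (nrow(H) < 3) break
    D <- .wdist(H, w = weights)
    cur_cost <- .mst_cost(D)
    feas <- .msn_links(D, epsilon)
    # connected triplets: two feasible links sharing a node
    cand <- list()
    for (u in seq_len(nrow(H))) {
      nb <- which(feas[u, ])
      if (length(nb) < 2) next
      for (a in seq_len(length(nb) - 1)) {
        for (b in seq((a + 1), length(nb))) {
          trip <- c(u, nb[a], nb[b])
          med <- apply(H[trip, , drop = FALSE], 2, stats::median)
          med <- as.integer(round(med))
          k <- paste(med, collapse = ",")
          if (!k %in% names(cand)) cand[[k]] <- med
        }
      }
    }
    if (!length(cand)) break
    # drop candidates already present
    existing <- apply(H, 1, paste, collapse = ",")
    cand <- cand[setdiff(names(cand), existing)]
    if (!length(cand)) break
    # deterministic order: lexicographic key
    cand <- cand[order(names(cand))]
    best_gain <- 0
    best_med <- NULL
    for (k in names(cand)) {
      med <- cand[[k]]
      d_new <- as.numeric(.wdist(matrix(med, 1), H, weights))
      Daug <- rbind(cbind(D, d_new), c(d_new, 0))
      gain <- cur_cost - .mst_cost(Daug)
      if (gain > best_gain + 1e-9) {
        best_gain <- gain
        best_med <- med
      }
    }
    if (is.null(best_med)) break
    n_median <- n_median + 1L
    H <- rbind(H, best_med)
    rownames(H) <- NULL
    mult <- c(mult, 0L)
    observed <- c(observed, FALSE)
    labels <- c(labels, paste0("mv", n_median))
  }

  # prune median vectors whose removal leaves the spanning cost unchanged
  repeat {
    D <- .wdist(H, w = weights)
    cost <- .mst_cost(D)
    drop_idx <- NA_integer_
    for (i in which(!observed)) {
      if (.mst_cost(D[-i, -i, drop = FALSE]) <= cost + 1e-9) {
        drop_idx <- i
        break
      }
    }
    if (is.na(drop_idx)) break
    H <- H[-drop_idx, , drop = FALSE]
    mult <- mult[-drop_idx]
    observed <- observed[-drop_idx]
    labels <- labels[-drop_idx]
  }

  D <- .wdist(H, w = weights)
  feas <- if (nrow(H) > 1) .msn_links(D, epsilon) else
    matrix(FALSE, nrow(H), nrow(H))
  S <- .wdist(H)  # unweighted steps
  idx <- which(feas & upper.tri(feas), arr.ind = TRUE)
  edges <- data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]],
                      length = D[idx], steps = S[idx],
                      stringsAsFactors = FALSE)
  rownames(H) <- labels
  structure(list(haplotypes = H, multiplicity = mult, observed = observed,
                 edges = edges, weights = weights, epsilon = epsilon,
                 cost = .mst_cost(D)),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("<haplo_network> %d observed + %d median nodes, %d links, cost %g\n",
              sum(x$observed), sum(!x$observed), nrow(x$edges), x$cost))
  invisible(x)
}

#' Convert a haplotype network to an igraph graph
#'
#' Edge attributes: `weight` (weighted length) and `steps` (unweighted
#' mutational steps); vertex attributes: `multiplicity`, `observed`.
#'
#' @param net A `haplo_network`.
#' @return An igraph graph.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[c("from", "to", "length", "steps")],
    directed = FALSE,
    vertices = data.frame(name = rownames(net$haplotypes),
                          multiplicity = net$multiplicity,
                          observed = as.integer(net$observed)))
  igraph::E(g)$weight <- igraph::E(g)$length
  g
}

#' Choose the root node of a network
#'
#' Published rho-based clade datings rarely state their rooting rule, so
#' rooting is explicit here: `"modal"` picks the highest-multiplicity observed
#' node (ties broken by the lexicographically smallest haplotype vector);
#' `"specified"`/`"outgroup"` use the given node label.
#'
#' @param net A `haplo_network`.
#' @param strategy `"modal"`, `"specified"` or `"outgroup"`.
#' @param node Node label for the non-modal strategies.
#' @return Node label of the root.
#' @export
choose_root <- function(net, strategy = c("modal", "specified", "outgroup"),
                        node = NULL) {
  strategy <- match.arg(strategy)
  labels <- rownames(net$haplotypes)
  if (strategy == "modal") {
    obs <- which(net$observed)
    top <- obs[net$multiplicity[obs] == max(net$multiplicity[obs])]
    if (length(top) > 1) {
      keys <- apply(net$haplotypes[top, , drop = FALSE], 1,
                    function(v) paste(sprintf("%06d", v), collapse = ","))
      top <- top[order(keys)[1]]
    }
    labels[top]
  } else {
    if (is.null(node) || !node %in% labels) {
      stop("node ", if (is.null(node)) "<NULL>" else node,
           " is not in the network")
    }
    node
  }
}

#' Rho statistic and TMRCA from a rooted network
#'
#' `rho` is the multiplicity-weighted mean number of mutational steps
#' (unweighted L1 distance along shortest network paths) from the root to
#' every observed haplotype. Its standard error follows the classical
#' rho-statistic estimator (Saillard et al. 1997):
#' `sigma = sqrt(sum_b l_b * n_b^2) / n`, summing over the branches of the
#' shortest-path tree from the root, where `l_b` is the branch length in
#' steps and `n_b` the number of sampled individuals whose root path uses
#' that branch.
#'
#' Time conversion: `t_generations = rho / per_haplotype_rate`; with
#' `correct = "smm_inversion"` the per-marker displacement `rho /
#' n_markers` is first back-corrected for stepwise back mutations, so
#' `t_generations = back_correct(rho / n_markers) * n_markers /
#' per_haplotype_rate`. `t_years = t_generations * generation_years`; the
#' `ci_years` interval is `t_years +/- sigma` converted on the same
#' (uncorrected-slope) scale.
#'
#' @param net A `haplo_network`.
#' @param root Root node label (see [choose_root()]).
#' @param model A [rate_model()].
#' @param correct `"none"` or `"smm_inversion"` (default: the model's
#'   `back_correction` field).
#' @return Object of class `rho_estimate`: `rho`, `sigma`, `t_generations`,
#'   `t_years`, `ci_years` (length 2), plus bookkeeping fields.
#' @export
rho_tmrca <- function(net, root, model, correct = NULL) {
  if (is.null(correct)) correct <- model$back_correction
  correct <- match.arg(correct, c("none", "smm_inversion"))
  labels <- rownames(net$haplotypes)
  if (!root %in% labels) stop("root ", root, " is not a node of the network")
  g <- as_igraph(net)
  if (igraph::components(g)$no > 1) stop("network is disconnected")

  obs <- labels[net$observed]
  mult <- stats::setNames(net$multiplicity[net$observed], obs)
  n <- sum(mult)
  d <- igraph::distances(g, v = root, to = obs,
                         weights = igraph::E(g)$steps)[1, ]
  rho <- sum(d * mult) / n

  # shortest-path tree from the root; per-branch downstream sample counts
  paths <- igraph::shortest_paths(g, from = root, to = obs,
                                  weights = igraph::E(g)$steps,
                                  output = "epath")$epath
  n_b <- numeric(igraph::ecount(g))
  for (i in seq_along(paths)) {
    eid <- as.integer(paths[[i]])
    n_b[eid] <- n_b[eid] + mult[[obs[i]]]
  }
  used <- n_b > 0
  sigma <- sqrt(sum(igraph::E(g)$steps[used] * n_b[used]^2)) / n

  t_gen <- if (correct == "smm_inversion") {
    back_correct(rho / model$n_markers) * model$n_markers /
      model$per_haplotype_rate
  } else {
    rho / model$per_haplotype_rate
  }
  se_gen <- sigma / model$per_haplotype_rate
  t_years <- t_gen * model$generation_years
  se_years <- se_gen * model$generation_years
  structure(list(rho = rho, sigma = sigma,
                 t_generations = t_gen, t_years = t_years,
                 ci_years = c(t_years - se_years, t_years + se_years),
                 root = root, n = n, model = model$name,
                 correct = correct),
            class = "rho_estimate")
}

#' @export
print.rho_estimate <- function(x, ...) {
  cat(sprintf("rho = %.3f +/- %.3f  ->  %.0f +/- %.0f years (%s rate%s)\n",
              x$rho, x$sigma, x$t_years,
              (x$ci_years[2] - x$ci_years[1]) / 2, x$model,
              if (x$correct == "smm_inversion") ", back-corrected" else ""))
  invisible(x)
}

#' Prepare Y-STR haplotype vectors for network analysis
#'
#' Applies the conventions used for Y-STR networks: DYS385a/b is excluded
#' (alleles cannot be assigned to a specific copy of the duplicated
#' region) and DYS389II is replaced by `DYS389b = DYS389II - DYS389I`.
#' Records with any missing panel allele are dropped.
#'
#' @param db A [ystr_db()].
#' @param panel Locus panel (default `"ystr12"`).
#' @return Integer matrix of network-ready haplotype vectors (rownames =
#'   kit ids).
#' @export
ystr_network_input <- function(db, panel = "ystr12") {
  loci <- ystr_panel(panel)
  loci <- setdiff(loci, c("DYS385a", "DYS385b"))
  m <- as.matrix(as.data.frame(db)[intersect(loci, names(db))])
  if ("DYS389II" %in% colnames(m)) {
    m[, "DYS389II"] <- derive_dys389b(db)
    colnames(m)[colnames(m) == "DYS389II"] <- "DYS389b"
  }
  keep <- rowSums(is.na(m)) == 0
  m <- m[keep, , drop = FALSE]
  rownames(m) <- db$kit_id[keep]
  storage.mode(m) <- "integer"
  m
}

#' Prepare HVS-I haplotypes for network analysis
#'
#' Encodes each record as a 0/1 vector over the union of substitutions
#' observed in the input, so that the L1 machinery counts site
#' differences. The default per-site weight for networks is 10.
#'
#' @param db An [mtdna_db()].
#' @return Integer 0/1 matrix (rownames = kit ids, colnames = substitution
#'   tokens).
#' @export
mt_network_input <- function(db) {
  sets <- lapply(db$substitutions, hvs1_set, warn = FALSE)
  all_subs <- sort_hvs1(unique(unlist(sets)))
  m <- matrix(0L, nrow(db), length(all_subs),
              dimnames = list(db$kit_id, all_subs))
  for (i in seq_along(sets)) m[i, sets[[i]]] <- 1L
  m
}

#' Export a network as GML
#' @param net A `haplo_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "gml")
  invisible(path)
}

#' Export a network in pairwise text form
#'
#' Writes a node table (`<path>.nodes.tsv`: label, multiplicity, observed,
#' haplotype vector) and an edge table (`<path>.edges.tsv`: from, to,
#' weighted length, steps) in the style of the pairwise exports used by
#' desktop network software.
#'
#' @param net A `haplo_network`.
#' @param path Output path stem.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_fluxus <- function(net, path) {
  nodes <- data.frame(label = rownames(net$haplotypes),
                      multiplicity = net$multiplicity,
                      observed = net$observed,
                      haplotype = apply(net$haplotypes, 1, paste,
                                        collapse = " "))
  np <- paste0(path, ".nodes.tsv")
  ep <- paste0(path, ".edges.tsv")
  utils::write.table(nodes, np, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$edges, ep, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(np, ep))
}
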