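# Seeded synthetic-data generators: genealogical-repository-like databases
# with planted motif frequencies, and genealogies with known TMRCA under the
# stepwise mutation model. These provide ground truth for every downstream
# stage without any external data.

.default_y_hg_mix <- list(
  jewish = c("J1-M267" = 0.20, "J2-M172" = 0.15, "R1a-M198" = 0.12,
             "R1b-M269" = 0.13, "E1b-M35" = 0.12, "G-M201" = 0.08,
             "others" = 0.20),
  non_jewish = c("R1b-M269" = 0.40, "R1a-M198" = 0.15, "I1-M253" = 0.12,
                 "J1-M267" = 0.04, "J2-M172" = 0.06, "E1b-M35" = 0.08,
                 "others" = 0.15)
)

.default_mt_hg_mix <- list(
  jewish = c("K" = 0.20, "H" = 0.25, "N1b" = 0.08, "J1c" = 0.12,
             "T2" = 0.10, "U5" = 0.05, "others" = 0.20),
  non_jewish = c("H" = 0.40, "U5" = 0.12, "K" = 0.08, "T2" = 0.10,
                 "J1c" = 0.10, "others" = 0.20)
)

# neutral central 12-locus founder (allele space away from the motifs)
.default_y_founder <- c(DYS393 = 13L, DYS390 = 24L, DYS19 = 15L,
                        DYS391 = 10L, DYS385a = 12L, DYS385b = 14L,
                        DYS426 = 12L, DYS388 = 13L, DYS439 = 12L,
                        DYS389I = 13L, DYS392 = 12L, DYS389II = 29L)

#' Default planted motif frequencies
#'
#' Per-group carrier frequencies for the ten packaged motifs, taken from
#' the published count tables (total carriers / group size per group), so
#' the generator's default conditions reproduce the observed database
#' composition.
#'
#' @return Named list `tag -> c(jewish = f1, non_jewish = f0)`.
#' @export
default_motif_freqs <- function() {
  tabs <- load_published_tables()
  tot <- tabs$motif_totals
  gs <- tabs$group_sizes
  out <- list()
  for (tag in unique(tot$motif)) {
    rows <- tot[tot$motif == tag, ]
    sys <- rows$system[1]
    n <- stats::setNames(gs$n[gs$system == sys], gs$group[gs$system == sys])
    out[[tag]] <- c(
      jewish = rows$total[rows$group == "jewish"] / n[["jewish"]],
      non_jewish = rows$total[rows$group == "non_jewish"] / n[["non_jewish"]]
    )
  }
  out
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the database generator. Defaults
#' emulate the published study conditions: group sizes 5281 / 57,639 (Y)
#' scaled to the same databases for mtDNA via `mt_fraction`, planted motif
#' frequencies equal to the published carrier frequencies, germ-line
#' per-locus Y-STR rates, and HVS-I mutational hotspots at 16,311 and
#' 16,519 (rate multiplier 5).
#'
#' @param seed Integer RNG seed; all downstream randomness flows from it.
#' @param n_jewish,n_non_jewish Y database group sizes.
#' @param mt_fraction mtDNA database size as a fraction of the Y sizes
#'   (default ~ 2818/5281).
#' @param motif_freqs Named list `tag -> c(jewish=, non_jewish=)`;
#'   frequencies in `[0, 1]` and summing to `< 1` per system and group.
#' @param y_hg_mix,mt_hg_mix Per-group haplogroup label distributions
#'   (named probability vectors). Labels are assigned independently of
#'   haplotype content (motifs cross haplogroups), except that planted mt
#'   carriers keep their motif's context haplogroup.
#' @param y_panel Y-STR locus panel.
#' @param per_locus_rates Named per-locus mutation rates per generation.
#' @param hvs1_hotspots Named multipliers (position -> rate factor).
#' @param y_founder Named founder allele vector over `y_panel`.
#' @param tmrca_generations SMM mutation time applied to database
#'   haplotypes (0 = mutation disabled; planted counts then exact).
#' @param genealogy `"star"` (single founder burst) -- reserved for future
#'   shapes.
#' @param p_hg_typed Probability a Y record's haplogroup is SNP-typed
#'   rather than STR-predicted.
#' @param fail_fraction Fraction of deliberately filter-failing records
#'   (short typing/coverage, duplicate kit ids, unconfirmed haplogroups).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_jewish = 5281L, n_non_jewish = 57639L,
                       mt_fraction = 2818 / 5281,
                       motif_freqs = default_motif_freqs(),
                       y_hg_mix = .default_y_hg_mix,
                       mt_hg_mix = .default_mt_hg_mix,
                       y_panel = ystr_panel("ystr12"),
                       per_locus_rates = NULL,
                       hvs1_hotspots = c("16311" = 5, "16519" = 5),
                       y_founder = .default_y_founder,
                       tmrca_generations = 0L,
                       genealogy = "star",
                       p_hg_typed = 0.2,
                       fail_fraction = 0) {
  if (is.null(per_locus_rates)) {
    per_locus_rates <- stats::setNames(rep(2.113e-3, length(y_panel)), y_panel)
  }
  freqs <- unlist(motif_freqs)
  stopifnot(all(freqs >= 0), all(freqs <= 1),
            n_jewish >= 0, n_non_jewish >= 0,
            all(per_locus_rates > 0), fail_fraction >= 0, fail_fraction < 1,
            tmrca_generations >= 0)
  if (!all(y_panel %in% names(y_founder))) {
    stop("y_founder must cover every panel locus")
  }
  structure(list(seed = as.integer(seed), n_jewish = as.integer(n_jewish),
                 n_non_jewish = as.integer(n_non_jewish),
                 mt_fraction = mt_fraction, motif_freqs = motif_freqs,
                 y_hg_mix = y_hg_mix, mt_hg_mix = mt_hg_mix,
                 y_panel = y_panel, per_locus_rates = per_locus_rates,
                 hvs1_hotspots = hvs1_hotspots,
                 y_founder = y_founder[y_panel],
                 tmrca_generations = as.integer(tmrca_generations),
                 genealogy = match.arg(genealogy, "star"),
                 p_hg_typed = p_hg_typed,
                 fail_fraction = fail_fraction),
            class = "sim_config")
}

.sample_hg <- function(n, mix) {
  sample(names(mix), n, replace = TRUE, prob = mix)
}

# assign at most one motif tag per record: multinomial over tags + none
.assign_motifs <- function(n, tags, freqs, group) {
  if (n == 0 || !length(tags)) return(rep(NA_character_, n))
  p <- vapply(tags, function(t) freqs[[t]][[group]], numeric(1))
  if (sum(p) > 1) stop("planted motif frequencies exceed 1 for ", group)
  sample(c(tags, NA), n, replace = TRUE, prob = c(p, 1 - sum(p)))
}

#' Simulate a genealogical-repository-like database pair
#'
#' Generates a Y-STR database and an mtDNA HVS-I database with motif
#' carriers planted at configured per-group frequencies, plus a truth
#' ledger of every planted carrier and the exact expected match counts per
#' motif (extended-motif carriers also match their 6-locus sub-motif; the
#' ledger accounts for that). Background haplotypes are post-checked so
#' they never collide with a motif state, which makes the ledger exact
#' when `tmrca_generations = 0`. A configured fraction of deliberately
#' failing records (short typing, missing coverage, duplicated kit ids,
#' unconfirmed haplogroups) exercises the filtering rules.
#'
#' @param cfg A [sim_config()].
#' @return List: `y_db` ([ystr_db()]), `mt_db` ([mtdna_db()]), `truth`
#'   (data frame `kit_id`, `group`, `system`, `motif`), `expected_counts`
#'   (data frame `motif`, `group`, `count` -- exact match counts when
#'   mutation is disabled).
#' @export
simulate_database <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  motifs <- load_motifs()
  y_tags <- names(Filter(function(m) m$system != "hvs1", motifs))
  mt_tags <- names(Filter(function(m) m$system == "hvs1", motifs))
  y_tags <- intersect(y_tags, names(cfg$motif_freqs))
  mt_tags <- intersect(mt_tags, names(cfg$motif_freqs))

  ## ---- Y database ----
  groups <- c(jewish = cfg$n_jewish, non_jewish = cfg$n_non_jewish)
  y_parts <- lapply(names(groups), function(g) {
    n <- groups[[g]]
    if (n == 0) return(NULL)
    planted <- .assign_motifs(n, y_tags, cfg$motif_freqs, g)
    L <- length(cfg$y_panel)
    # background: founder plus small symmetric repeat noise
    noise <- matrix(sample(-2:2, n * L, replace = TRUE,
                           prob = c(.05, .2, .5, .2, .05)), n, L)
    H <- matrix(rep(cfg$y_founder, each = n), n, L) + noise
    colnames(H) <- cfg$y_panel
    for (tag in y_tags) {
      idx <- which(!is.na(planted) & planted == tag)
      if (!length(idx)) next
      al <- motifs[[tag]]$y_alleles
      H[idx, names(al)] <- matrix(rep(al, each = length(idx)),
                                  length(idx), length(al))
    }
    # keep DYS385 stored as an ordered pair
    if (all(c("DYS385a", "DYS385b") %in% colnames(H))) {
      lo <- pmin(H[, "DYS385a"], H[, "DYS385b"])
      hi <- pmax(H[, "DYS385a"], H[, "DYS385b"])
      H[, "DYS385a"] <- lo
      H[, "DYS385b"] <- hi
    }
    list(group = g, planted = planted, H = H)
  })
  y_parts <- Filter(Negate(is.null), y_parts)

  y_db_rows <- lapply(y_parts, function(p) {
    n <- nrow(p$H)
    prefix <- if (p$group == "jewish") "J" else "N"
    data.frame(kit_id = sprintf("%s%06d", prefix, seq_len(n)),
               group = p$group,
               haplogroup = .sample_hg(n, cfg$y_hg_mix[[p$group]]),
               hg_evidence = ifelse(stats::runif(n) < cfg$p_hg_typed,
                                    "snp_typed", "str_predicted"),
               as.data.frame(p$H), stringsAsFactors = FALSE)
  })
  y_df <- do.call(rbind, y_db_rows)
  y_planted <- unlist(lapply(y_parts, `[[`, "planted"))

  # Records must not accidentally realize a motif they were not planted
  # for. Bump one allele until no unintended exact match remains; the bump
  # locus depends on the clashing panel so planted states stay intact:
  # 6-locus clashes can only involve background records (DYS391 is free to
  # move), 12-locus clashes may involve carriers of the nested 6-locus
  # motif, so bump DYS426, which no 6-locus panel contains.
  repeat {
    clash6 <- rep(FALSE, nrow(y_df))
    clash12 <- rep(FALSE, nrow(y_df))
    for (tag in y_tags) {
      hit <- match_y_motif(y_df, motifs[[tag]])
      hit[is.na(hit)] <- FALSE
      intended <- !is.na(y_planted) &
        y_planted %in% .implied_by(tag, y_tags, motifs)
      if (motifs[[tag]]$system == "ystr6") {
        clash6 <- clash6 | (hit & !intended)
      } else {
        clash12 <- clash12 | (hit & !intended)
      }
    }
    if (!any(clash6 | clash12)) break
    y_df$DYS391[clash6] <- y_df$DYS391[clash6] + 3L
    y_df$DYS426[clash12 & !clash6] <- y_df$DYS426[clash12 & !clash6] + 3L
  }

  ## ---- mtDNA database ----
  n_mt <- c(jewish = as.integer(round(cfg$n_jewish * cfg$mt_fraction)),
            non_jewish = as.integer(round(cfg$n_non_jewish * cfg$mt_fraction)))
  positions <- .HVS1_START:.HVS1_END
  site_w <- rep(1, length(positions))
  hs_pos <- as.integer(names(cfg$hvs1_hotspots))
  site_w[match(hs_pos, positions)] <- cfg$hvs1_hotspots
  motif_sets <- lapply(mt_tags, function(t) motifs[[t]]$mt_substitutions)
  names(motif_sets) <- mt_tags

  mt_parts <- lapply(names(n_mt), function(g) {
    n <- n_mt[[g]]
    if (n == 0) return(NULL)
    planted <- .assign_motifs(n, mt_tags, cfg$motif_freqs, g)
    subs <- character(n)
    hg <- .sample_hg(n, cfg$mt_hg_mix[[g]])
    for (i in seq_len(n)) {
      if (!is.na(planted[i])) {
        subs[i] <- paste(motif_sets[[planted[i]]], collapse = " ")
        hg[i] <- motifs[[planted[i]]]$hg_context
      } else {
        k <- stats::rpois(1, 3)
        pos <- sample(positions, min(k, length(positions)), prob = site_w)
        set <- sprintf("%d%s", sort(pos),
                       sample(c("A", "C", "G", "T"), length(pos),
                              replace = TRUE))
        # background must not equal a motif set exactly
        while (any(vapply(motif_sets, function(ms) setequal(set, ms),
                          logical(1)))) {
          extra <- sample(setdiff(positions, pos), 1)
          set <- sort_hvs1(c(set, sprintf("%dA", extra)))
          pos <- c(pos, extra)
        }
        subs[i] <- paste(set, collapse = " ")
      }
    }
    prefix <- if (g == "jewish") "MJ" else "MN"
    data.frame(kit_id = sprintf("%s%06d", prefix, seq_len(n)), group = g,
               haplogroup = hg, hg_evidence = "snp_typed",
               substitutions = subs,
               covered_start = .HVS1_START, covered_end = .HVS1_END,
               stringsAsFactors = FALSE)
  })
  mt_parts <- Filter(Negate(is.null), mt_parts)
  mt_df <- do.call(rbind, mt_parts)
  mt_planted <- unlist(lapply(names(n_mt), function(g) {
    # re-derive planted tags from the constructed sets (exact by build)
    p <- mt_parts[[match(g, names(n_mt))]]
    if (is.null(p)) return(character(0))
    vapply(p$substitutions, function(s) {
      hit <- vapply(motif_sets, function(ms)
        setequal(hvs1_set(s, warn = FALSE), ms), logical(1))
      if (any(hit)) names(motif_sets)[which(hit)[1]] else NA_character_
    }, character(1), USE.NAMES = FALSE)
  }))

  ## ---- optional SMM mutation noise on Y haplotypes ----
  if (cfg$tmrca_generations > 0) {
    rates <- cfg$per_locus_rates[cfg$y_panel]
    for (l in cfg$y_panel) {
      k <- stats::rpois(nrow(y_df), rates[[l]] * cfg$tmrca_generations)
      net <- 2L * stats::rbinom(length(k), k, 0.5) - k
      y_df[[l]] <- y_df[[l]] + net
    }
  }

  ## ---- deliberately failing records ----
  if (cfg$fail_fraction > 0) {
    .spoil <- function(df, kind) {
      n_bad <- ceiling(nrow(df) * cfg$fail_fraction)
      idx <- sample(nrow(df), n_bad)
      mode <- sample(c("short", "dup", "evidence"), n_bad, replace = TRUE)
      if (kind == "y") {
        short <- idx[mode == "short"]
        df[short, sample(cfg$y_panel, 2)] <- NA
        ev <- idx[mode == "evidence"]
        df$hg_evidence[ev] <- NA
      } else {
        short <- idx[mode == "short"]
        df$covered_end[short] <- .HVS1_END - 100L
        ev <- idx[mode == "evidence"]
        df$hg_evidence[ev] <- "unconfirmed"
      }
      dup <- idx[mode == "dup"]
      if (length(dup)) df$kit_id[dup] <- df$kit_id[sample(nrow(df), length(dup))]
      df
    }
    y_df <- .spoil(y_df, "y")
    mt_df <- .spoil(mt_df, "mt")
  }

  truth <- rbind(
    data.frame(kit_id = y_df$kit_id, group = y_df$group, system = "y",
               motif = y_planted, stringsAsFactors = FALSE),
    data.frame(kit_id = mt_df$kit_id, group = mt_df$group, system = "mt",
               motif = mt_planted, stringsAsFactors = FALSE)
  )
  truth <- truth[!is.na(truth$motif), , drop = FALSE]
  rownames(truth) <- NULL

  # expected exact match counts (mutation disabled): planted carriers plus
  # extended-motif carriers matching their 6-locus parent motif
  expected <- do.call(rbind, lapply(c(y_tags, mt_tags), function(tag) {
    contributors <- .implied_by(tag, c(y_tags, mt_tags), motifs)
    do.call(rbind, lapply(c("jewish", "non_jewish"), function(g) {
      data.frame(motif = tag, group = g,
                 count = sum(truth$motif %in% contributors &
                               truth$group == g),
                 stringsAsFactors = FALSE)
    }))
  }))

  list(y_db = ystr_db(y_df, validate = FALSE),
       mt_db = mtdna_db(mt_df, validate = FALSE),
       truth = truth, expected_counts = expected)
}

# which planted tags produce a match for `tag`? a tag always implies
# itself; an extended Y motif implies its 6-locus version when the 6-locus
# alleles agree (they do for the packaged pairs)
.implied_by <- function(tag, all_tags, motifs) {
  out <- tag
  m <- motifs[[tag]]
  if (!is.null(m$y_alleles) && m$system == "ystr6") {
    for (t2 in all_tags) {
      m2 <- motifs[[t2]]
      if (is.null(m2$y_alleles) || m2$system != "ystr12") next
      if (all(m2$y_alleles[names(m$y_alleles)] == m$y_alleles)) {
        out <- c(out, t2)
      }
    }
  }
  out
}

#' Simulate a star genealogy under the stepwise mutation model
#'
#' Each of `n_tips` lineages descends independently from the founder for
#' `t` generations; a locus with rate `r` accumulates `Poisson(r * t)`
#' mutation events, each moving the repeat count by +/-1 with equal
#' probability. The expected number of true mutations per tip is
#' `t * sum(rates)`; the expected *observed* net displacement is smaller
#' (see [smm_expected_observed()]).
#'
#' @param founder Named integer allele vector.
#' @param n_tips Number of descendant lineages.
#' @param t Time in generations (`>= 0`).
#' @param per_locus_rates Named rates (mutations/locus/generation).
#' @param seed Integer seed.
#' @return Integer matrix `n_tips x loci` (rownames `tip1..`).
#' @export
simulate_star_genealogy <- function(founder, n_tips, t, per_locus_rates,
                                    seed = 1L) {
  stopifnot(t >= 0, n_tips >= 1)
  loci <- names(founder)
  stopifnot(!is.null(loci), all(loci %in% names(per_locus_rates)))
  set.seed(seed)
  H <- matrix(rep(as.integer(founder), each = n_tips), n_tips,
              length(loci), dimnames = list(paste0("tip", seq_len(n_tips)),
                                            loci))
  for (l in loci) {
    k <- stats::rpois(n_tips, per_locus_rates[[l]] * t)
    net <- 2L * stats::rbinom(n_tips, k, 0.5) - k
    H[, l] <- H[, l] + net
  }
  H
}

#' Simulate HVS-I haplotypes with mutational hotspots
#'
#' Finite-sites model over positions 16,024-16,569: each site mutates as a
#' Poisson process at `base_rate` per generation, multiplied at hotspot
#' sites; each event replaces the current base by one of the other three,
#' uniformly, so repeat hits can revert a derived site to the reference
#' state (back mutation) or exchange derived bases. The founder is given
#' as a substitution set relative to the packaged reference slice.
#'
#' @param founder_set Character vector of substitution tokens.
#' @param n_tips Number of descendant lineages.
#' @param t Time in generations.
#' @param base_rate Per-site mutation rate per generation (default: the
#'   pedigree segment rate 1.06e-2 spread over the 546 sites).
#' @param hotspots Named multipliers (position -> factor), default 5x at
#'   16,311 and 16,519.
#' @param seed Integer seed.
#' @param reference FASTA of the reference slice (defines ancestral
#'   bases).
#' @param group,haplogroup Metadata applied to every record.
#' @return An [mtdna_db()] with one record per tip.
#' @export
simulate_hvs1 <- function(founder_set, n_tips, t,
                          base_rate = 1.06e-2 / 546,
                          hotspots = c("16311" = 5, "16519" = 5),
                          seed = 1L,
                          reference = motifscan_file("hvs1_reference_synthetic.fasta"),
                          group = NA_character_, haplogroup = NA_character_) {
  stopifnot(t >= 0, n_tips >= 1)
  set.seed(seed)
  ref <- strsplit(.read_fasta(reference)[[1]], "")[[1]]
  positions <- .HVS1_START:.HVS1_END
  rates <- rep(base_rate, length(positions))
  idx <- match(as.integer(names(hotspots)), positions)
  rates[idx[!is.na(idx)]] <- base_rate * hotspots[!is.na(idx)]

  founder_set <- sort_hvs1(hvs1_set(founder_set))
  founder_seq <- ref
  fpos <- hvs1_positions(founder_set)
  fbase <- substr(founder_set, nchar(founder_set), nchar(founder_set))
  same <- fbase == ref[fpos - .HVS1_START + 1L]
  if (any(same)) {
    stop("founder substitution(s) equal the reference base at ",
         paste(founder_set[same], collapse = ", "),
         "; substitutions must differ from the reference")
  }
  founder_seq[fpos - .HVS1_START + 1L] <-
    substr(founder_set, nchar(founder_set), nchar(founder_set))

  bases <- c("A", "C", "G", "T")
  recs <- lapply(seq_len(n_tips), function(i) {
    s <- founder_seq
    k <- stats::rpois(length(positions), rates * t)
    for (j in which(k > 0)) {
      for (e in seq_len(k[j])) {
        s[j] <- sample(setdiff(bases, s[j]), 1)
      }
    }
    diff <- which(s != ref)
    data.frame(kit_id = sprintf("tip%04d", i), group = group,
               haplogroup = haplogroup, hg_evidence = "snp_typed",
               substitutions = paste(sprintf("%d%s",
                                             positions[diff], s[diff]),
                                     collapse = " "),
               covered_start = .HVS1_START, covered_end = .HVS1_END,
               stringsAsFactors = FALSE)
  })
  mtdna_db(do.call(rbind, recs))
}
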