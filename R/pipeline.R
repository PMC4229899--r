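#' Run the end-to-end motif analysis pipeline
#'
#' Orchestrates the full analysis on one configuration: obtain input
#' databases (simulated from a seed, or read from TSV), filter them, match
#' every configured motif, write count tables with percentages,
#' chi-square association statistics, Bayesian posterior curves, and
#' optionally a median-joining network with a rho TMRCA estimate for the
#' carriers of one motif. A run manifest (config hash, seed, per-stage row
#' counts, output checksums) makes reruns verifiable: the same config and
#' seed reproduce byte-identical outputs.
#'
#' The YAML config has sections `seed`, `simulate` (arguments of
#' [sim_config()]) *or* `inputs` (`y`, `mt` TSV paths), `filter`
#' (`min_y_loci`), `motifs` (tags, default: all packaged), `bayes`
#' (`grid_size`, `population`, `world`), and `network` (`motif`, `group`,
#' `rate`, `correct`, `root`).
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$seed)) cfg$seed <- 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message(sprintf("[%s] ", format(Sys.time(),
                                                           "%H:%M:%S")), ...)
  counts <- list()

  ## stage 1: inputs
  if (!is.null(cfg$inputs)) {
    if (is.null(cfg$inputs$y) || !file.exists(cfg$inputs$y)) {
      stop("missing input: ", cfg$inputs$y)
    }
    y_db <- read_y_database(cfg$inputs$y)
    mt_db <- if (!is.null(cfg$inputs$mt)) read_mt_database(cfg$inputs$mt)
             else NULL
    truth <- NULL
    log_msg("loaded ", nrow(y_db), " Y records")
  } else {
    sim_args <- cfg$simulate
    sim_args$seed <- cfg$seed
    if (!is.null(sim_args$motif_freqs)) {
      sim_args$motif_freqs <- lapply(sim_args$motif_freqs, unlist)
    }
    sc <- do.call(sim_config, sim_args)
    sim <- simulate_database(sc)
    y_db <- sim$y_db
    mt_db <- sim$mt_db
    truth <- sim
    utils::write.table(sim$expected_counts,
                       file.path(out_dir, "planted_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_msg("simulated ", nrow(y_db), " Y + ", nrow(mt_db), " mt records")
  }
  counts$y_input <- nrow(y_db)
  counts$mt_input <- if (is.null(mt_db)) 0L else nrow(mt_db)

  ## stage 2: filtering
  min_y <- if (!is.null(cfg$filter$min_y_loci)) cfg$filter$min_y_loci else 12L
  fy <- filter_records(y_db, "y", min_y_loci = min_y)
  y_kept <- fy$kept
  write_y_database(y_kept, file.path(out_dir, "y_kept.tsv"))
  reports <- list(y = unclass(fy$report))
  if (!is.null(mt_db)) {
    fmt <- filter_records(mt_db, "mt")
    mt_kept <- fmt$kept
    write_mt_database(mt_kept, file.path(out_dir, "mt_kept.tsv"))
    reports$mt <- unclass(fmt$report)
  } else {
    mt_kept <- NULL
  }
  jsonlite::write_json(reports, file.path(out_dir, "filter_report.json"),
                       auto_unbox = TRUE)
  counts$y_kept <- nrow(y_kept)
  counts$mt_kept <- if (is.null(mt_kept)) 0L else nrow(mt_kept)
  log_msg("filter kept ", counts$y_kept, " Y / ", counts$mt_kept, " mt")

  ## stage 3: motif matching and count tables
  motifs <- load_motifs()
  tags <- if (!is.null(cfg$motifs)) cfg$motifs else names(motifs)
  tables <- list()
  for (tag in tags) {
    m <- motifs[[tag]]
    if (is.null(m)) stop("unknown motif tag in config: ", tag)
    db <- if (m$system == "hvs1") mt_kept else y_kept
    if (is.null(db) || nrow(db) == 0) next
    ct <- build_count_table(db, m)
    tables[[tag]] <- ct
    out <- rbind(ct$rows,
                 data.frame(haplogroup = "Total", group = names(ct$totals),
                            count = as.integer(ct$totals)))
    utils::write.table(out,
                       file.path(out_dir, sprintf("counts_%s.tsv", tag)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  counts$motifs_tested <- length(tables)

  ## stage 4: association statistics
  stats_out <- lapply(tables, function(ct) {
    res <- tryCatch({
      cs <- chi_square_yates(as_contingency(ct))
      list(statistic = cs$statistic, df = cs$df, p_value = cs$p_value,
           collapsed = cs$collapsed_categories)
    }, error = function(e) list(error = conditionMessage(e)))
    c(list(totals = as.list(ct$totals), n = as.list(ct$n),
           pct = as.list(ct$pct)), res)
  })
  jsonlite::write_json(stats_out, file.path(out_dir, "association.json"),
                       auto_unbox = TRUE, digits = NA)

  ## stage 5: Bayesian posterior curves
  bayes_cfg <- cfg$bayes
  prior_star <- default_prior(
    population = if (!is.null(bayes_cfg$population)) bayes_cfg$population
                 else 13e6,
    world = if (!is.null(bayes_cfg$world)) bayes_cfg$world else 7.2e9)
  grid_size <- if (!is.null(bayes_cfg$grid_size)) bayes_cfg$grid_size else 1000
  for (tag in names(tables)) {
    ct <- tables[[tag]]
    if (ct$totals[["jewish"]] == 0 && ct$totals[["non_jewish"]] == 0) next
    pc <- suppressWarnings(
      posterior_curve(ct, grid_size = grid_size, prior_star = prior_star))
    write_posterior_curve(pc, file.path(out_dir,
                                        sprintf("posterior_%s.tsv", tag)))
  }

  ## stage 6: network + TMRCA (optional)
  if (!is.null(cfg$network)) {
    nc <- cfg$network
    tag <- nc$motif
    m <- motifs[[tag]]
    if (is.null(m)) stop("unknown network motif: ", tag)
    db <- if (m$system == "hvs1") mt_kept else y_kept
    sel <- match_motif(db, m)
    sel[is.na(sel)] <- FALSE
    if (!is.null(nc$group)) sel <- sel & db$group == nc$group
    sub <- db[sel, , drop = FALSE]
    if (nrow(sub) >= 2) {
      H <- if (m$system == "hvs1") mt_network_input(sub)
           else ystr_network_input(sub)
      w <- if (m$system == "hvs1") rep(10L, ncol(H)) else
        tryCatch(locus_weights(H), error = function(e) rep(10L, ncol(H)))
      net <- median_joining(H, weights = w,
                            epsilon = if (!is.null(nc$epsilon)) nc$epsilon
                                      else 0)
      root <- if (!is.null(nc$root) && nc$root != "modal") {
        choose_root(net, "specified", nc$root)
      } else choose_root(net, "modal")
      models <- load_rate_models()
      model <- models[[if (!is.null(nc$rate)) nc$rate else "genealogical"]]
      est <- rho_tmrca(net, root, model,
                       correct = if (!is.null(nc$correct)) nc$correct)
      write_gml(net, file.path(out_dir, sprintf("network_%s.gml", tag)))
      write_fluxus(net, file.path(out_dir, sprintf("network_%s", tag)))
      utils::write.table(
        data.frame(motif = tag, n = est$n, rho = est$rho,
                   sigma = est$sigma, t_generations = est$t_generations,
                   t_years = est$t_years, ci_low = est$ci_years[1],
                   ci_high = est$ci_years[2], model = est$model,
                   correct = est$correct),
        file.path(out_dir, "tmrca.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      counts$network_haplotypes <- nrow(sub)
      log_msg("network on ", nrow(sub), " ", tag, " carriers: rho = ",
              round(est$rho, 3))
    } else {
      log_msg("network skipped: fewer than 2 ", tag, " carriers")
    }
  }

  ## manifest
  cfg_norm <- yaml::as.yaml(cfg)
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("motifscan")),
    seed = cfg$seed,
    config_sha = unname(tools::md5sum(
      {tf <- tempfile(); writeLines(cfg_norm, tf); tf})),
    counts = counts,
    outputs = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
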