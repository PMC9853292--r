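# End-to-end pipeline: simulate/ingest -> preprocess -> per-kingdom networks
# -> interdomain network -> topology -> modules/roles/eigengenes -> trait
# correlations -> community statistics, with a run manifest.

#' Build a pipeline configuration
#'
#' All knobs of [run_pipeline()] in one validated list. Inputs are either a
#' synthetic-community spec (`synthetic = list(...)` passed to
#' [generate_truth()]/[simulate_counts()]/[simulate_metadata()]) or paths to
#' count tables and metadata (`input = list(counts = c(prokaryote = path,
#' ...), metadata = path)`).
#'
#' @param synthetic List of synthetic-community settings (`n_otus`,
#'   `n_modules`, `rho_within`, `n_samples`, `depth`, `group_sizes`, ...), or
#'   `NULL` when reading real tables.
#' @param input List with `counts` (named vector of per-kingdom TSV paths)
#'   and `metadata` (TSV path), or `NULL` when simulating.
#' @param rarefaction_depth Named per-kingdom rarefaction depths.
#' @param min_prevalence Prevalence cutoff for network OTUs.
#' @param thresholds Either a named numeric vector of fixed per-kingdom
#'   correlation thresholds, or `"rmt"` to select each by
#'   [rmt_select_threshold()].
#' @param interdomain_threshold Threshold for the pooled multi-kingdom
#'   network.
#' @param rmt_scan Scan settings (`s_min`, `s_max`, `step`, `alpha`) used
#'   when `thresholds = "rmt"`.
#' @param robustness_replicates,permutations Replication counts for the
#'   stochastic stages.
#' @param removal_fraction Node-removal fraction for robustness.
#' @param seed Master seed; every stochastic stage derives its own seed from
#'   it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = list(),
                            input = NULL,
                            rarefaction_depth = c(prokaryote = 1200,
                                                  fungus = 400,
                                                  cercozoa = 400),
                            min_prevalence = 0.8,
                            thresholds = c(prokaryote = 0.85, fungus = 0.85,
                                           cercozoa = 0.85),
                            interdomain_threshold = 0.85,
                            rmt_scan = list(s_min = 0.30, s_max = 0.99,
                                            step = 0.01, alpha = 0.05),
                            robustness_replicates = 100,
                            removal_fraction = 0.5,
                            permutations = 999,
                            seed = 1) {
  if (is.null(input) && is.null(synthetic)) {
    stop("either synthetic settings or input paths are required", call. = FALSE)
  }
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(
    synthetic = synthetic, input = input,
    rarefaction_depth = rarefaction_depth,
    min_prevalence = min_prevalence,
    thresholds = thresholds,
    interdomain_threshold = interdomain_threshold,
    rmt_scan = rmt_scan,
    robustness_replicates = robustness_replicates,
    removal_fraction = removal_fraction,
    permutations = permutations,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (key in c("rarefaction_depth", "thresholds")) {
    if (!is.null(y[[key]]) && is.list(y[[key]])) {
      y[[key]] <- unlist(y[[key]])
    }
  }
  if (!is.null(y$synthetic)) {
    for (key in c("n_otus", "depth", "group_sizes", "guild_fractions")) {
      if (!is.null(y$synthetic[[key]])) {
        y$synthetic[[key]] <- unlist(y$synthetic[[key]])
      }
    }
  }
  do.call(pipeline_config, y)
}

pipeline_log <- function(...) {
  message("[imena] ", ...)
}

#' Run the full interdomain network analysis
#'
#' Executes every stage from community tables (simulated or read from disk)
#' to the module-trait correlation table, writing all artifacts as TSV /
#' GraphML under `outdir` plus a YAML run manifest recording the package
#' version, seeds, and the thresholds actually used. Reruns with an identical
#' config produce byte-identical outputs.
#'
#' @param config A `pipeline_config` (or path to a YAML config).
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with every intermediate result (`truth`,
#'   `counts`, `metadata`, `alpha`, `networks`, `interdomain`, `topology`,
#'   `partition`, `roles`, `eigengenes`, `module_traits`, `mantel`,
#'   `dissimilarity`, `pca`, `anova`, `regressions`, `manifest`).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  out <- list()

  # --- stage 1: obtain tables -------------------------------------------
  if (!is.null(config$input)) {
    pipeline_log("reading count tables")
    tables <- purrr::imap(config$input$counts,
                          function(p, k) read_count_table(p, kingdom = k))
    counts <- dplyr::bind_rows(tables)
    metadata <- read_sample_metadata(config$input$metadata, counts)
    truth <- NULL
  } else {
    pipeline_log("simulating synthetic community (seed ", seed, ")")
    syn <- config$synthetic
    gt_args <- syn[intersect(names(syn),
                             names(formals(generate_truth)))]
    gt_args$seed <- seed
    truth <- do.call(generate_truth, gt_args)
    counts <- simulate_counts(truth,
                              n_samples = syn$n_samples %||% 27,
                              depth = syn$depth %||%
                                config$rarefaction_depth,
                              seed = seed + 1L)
    metadata <- simulate_metadata(truth, counts,
                                  group_sizes = syn$group_sizes %||%
                                    c(IL = 7, IM = 12, IH = 8),
                                  seed = seed + 2L)
    jsonlite::write_json(
      list(otus = truth$otus, rho_within = truth$rho_within,
           flux_link = truth$flux_link, seed = truth$seed),
      file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out$truth <- truth
  write_sample_metadata(metadata, file.path(outdir, "metadata.tsv"))

  # --- stage 2: preprocess ----------------------------------------------
  pipeline_log("preprocessing (rarefaction, guilds, groups)")
  metadata <- assign_groups(metadata)
  counts <- annotate_guilds(counts)
  rarefied <- rarefy(counts, config$rarefaction_depth, seed = seed + 3L)
  out$counts <- rarefied
  out$metadata <- metadata
  write_count_table(rarefied, file.path(outdir, "counts_rarefied.tsv"))
  out$alpha <- alpha_diversity(rarefied)
  readr::write_tsv(out$alpha, file.path(outdir, "alpha_diversity.tsv"),
                   progress = FALSE)

  kingdoms <- unique(rarefied$kingdom)
  filtered <- setNames(lapply(kingdoms, function(k) {
    prevalence_filter(rarefied[rarefied$kingdom == k, ],
                      config$min_prevalence)
  }), kingdoms)

  # --- stage 3: per-kingdom networks ------------------------------------
  thresholds_used <- list()
  out$networks <- list()
  for (k in kingdoms) {
    pipeline_log("building ", k, " network")
    corr <- spearman_matrix(filtered[[k]])
    if (identical(config$thresholds, "rmt")) {
      scan <- do.call(rmt_select_threshold,
                      c(list(corr = corr), config$rmt_scan))
      thr <- scan$selected
      readr::write_tsv(scan$scan,
                       file.path(outdir, paste0("rmt_scan_", k, ".tsv")),
                       progress = FALSE)
    } else {
      thr <- unname(config$thresholds[[k]])
    }
    thresholds_used[[k]] <- thr
    net <- build_network(corr, thr, filtered[[k]])
    out$networks[[k]] <- net
  }

  # --- stage 4: interdomain network -------------------------------------
  pipeline_log("building interdomain network")
  inter <- build_interdomain_network(unname(filtered),
                                     config$interdomain_threshold)
  thresholds_used$interdomain <- config$interdomain_threshold
  out$interdomain <- inter

  # --- stage 5: topology -------------------------------------------------
  pipeline_log("topology, vulnerability, robustness")
  nets <- c(out$networks, list(interdomain = inter))
  out$topology <- purrr::imap_dfr(nets, function(g, nm) {
    dplyr::bind_cols(tibble::tibble(network = nm), global_properties(g))
  })
  readr::write_tsv(out$topology, file.path(outdir, "topology.tsv"),
                   progress = FALSE)
  out$robustness <- purrr::imap_dfr(nets, function(g, nm) {
    dplyr::bind_cols(
      tibble::tibble(network = nm),
      dplyr::bind_rows(
        robustness(g, config$removal_fraction, "random",
                   config$robustness_replicates, seed = seed + 4L),
        robustness(g, config$removal_fraction, "target_hubs",
                   config$robustness_replicates, seed = seed + 5L))
    )
  })
  readr::write_tsv(out$robustness, file.path(outdir, "robustness.tsv"),
                   progress = FALSE)

  # --- stage 6: modules, roles, eigengenes ------------------------------
  pipeline_log("module detection and node roles")
  out$partition <- detect_modules(inter)
  out$roles <- zi_pi(inter, out$partition)
  readr::write_tsv(out$roles, file.path(outdir, "node_roles.tsv"),
                   progress = FALSE)
  inter <- set_node_roles(inter, out$roles)
  write_network(inter,
                edge_path = file.path(outdir, "interdomain_edges.tsv"),
                attr_path = file.path(outdir, "interdomain_nodes.tsv"),
                graphml_path = file.path(outdir, "interdomain.graphml"))
  combined <- dplyr::bind_rows(unname(filtered))
  out$eigengenes <- module_eigengenes(combined, out$partition)
  eg_tbl <- tibble::as_tibble(out$eigengenes$eigengenes)
  names(eg_tbl) <- paste0("module_", names(eg_tbl))
  eg_tbl <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(out$eigengenes$eigengenes)), eg_tbl)
  readr::write_tsv(eg_tbl, file.path(outdir, "eigengenes.tsv"),
                   progress = FALSE)

  # --- stage 7: module-trait correlations -------------------------------
  pipeline_log("eigengene-trait correlations")
  out$module_traits <- eigengene_trait_correlation(out$eigengenes, metadata)
  readr::write_tsv(out$module_traits,
                   file.path(outdir, "module_trait_correlations.tsv"),
                   progress = FALSE)

  # --- stage 8: community statistics ------------------------------------
  pipeline_log("community statistics")
  out$mantel <- purrr::map_dfr(kingdoms, function(k) {
    dm <- jaccard_distance(rarefied[rarefied$kingdom == k, ])
    dplyr::bind_cols(tibble::tibble(community = k),
                     mantel_table(dm, metadata,
                                  permutations = config$permutations,
                                  seed = seed + 6L))
  })
  readr::write_tsv(out$mantel, file.path(outdir, "mantel_tests.tsv"),
                   progress = FALSE)
  out$dissimilarity <- purrr::map_dfr(kingdoms, function(k) {
    dm <- jaccard_distance(rarefied[rarefied$kingdom == k, ])
    grp <- metadata$group[match(rownames(as.matrix(dm)),
                                metadata$sample_id)]
    dplyr::bind_cols(tibble::tibble(community = k),
                     dissimilarity_tests(dm, grp,
                                         permutations = config$permutations,
                                         seed = seed + 7L))
  })
  readr::write_tsv(out$dissimilarity,
                   file.path(outdir, "dissimilarity_tests.tsv"),
                   progress = FALSE)
  out$pca <- pca_ordination(rarefied)
  out$anova <- group_anova(metadata$ch4_flux, metadata$group)
  out$regressions <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(predictor = "mcrA_copies"),
                     flux_regression(metadata$mcrA_copies,
                                     metadata$ch4_flux)),
    dplyr::bind_cols(tibble::tibble(predictor = "pmoA_copies"),
                     flux_regression(metadata$pmoA_copies,
                                     metadata$ch4_flux))
  )
  readr::write_tsv(out$regressions,
                   file.path(outdir, "flux_regressions.tsv"),
                   progress = FALSE)

  # --- manifest ----------------------------------------------------------
  manifest <- list(
    package_version = as.character(packageVersion("imena")),
    seed = seed,
    stage_seeds = list(counts = seed + 1L, metadata = seed + 2L,
                       rarefaction = seed + 3L,
                       robustness_random = seed + 4L,
                       robustness_targeted = seed + 5L,
                       mantel = seed + 6L, dissimilarity = seed + 7L),
    rarefaction_depth = as.list(config$rarefaction_depth),
    min_prevalence = config$min_prevalence,
    thresholds_used = thresholds_used,
    permutations = config$permutations,
    robustness = list(replicates = config$robustness_replicates,
                      removal_fraction = config$removal_fraction)
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  out$manifest <- manifest
  pipeline_log("done: ", outdir)
  invisible(out)
}
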