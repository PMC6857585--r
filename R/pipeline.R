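#' Assemble a pipeline configuration
#'
#' Exactly one of `input` (paths to a band matrix and metadata on disk) or
#' `simulate` (a [sim_config()]) must be supplied. `seed` is mandatory: every
#' stochastic stage derives its own substream from it by a fixed stage
#' offset, so disabling one stage does not shift another's randomness.
#'
#' @param input `list(matrix =, metadata =, primer_map = NULL, primer_class
#'   = NULL)` of file paths.
#' @param simulate A `sim_config`.
#' @param seed Master integer seed.
#' @param stages Character vector of stages to run, a subset of
#'   `c("markers", "similarity", "pcoa", "partition", "admixture", "mantel")`.
#' @param gs_bands Band set for similarity/ordination/Mantel (`"all"` or
#'   `"polymorphic"`).
#' @param bootstrap_replicates UPGMA bootstrap replicates.
#' @param permutations AMOVA / pairwise PhiPT permutations.
#' @param k_range,runs,burnin,sweeps,thin,alpha Admixture scan settings.
#' @param mantel_permutations Mantel permutations.
#' @param merge_groups Passed to [mantel_suite()].
#' @param clade_threshold `"mean"` (cut at the mean pairwise similarity) or a
#'   numeric similarity.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL, seed,
                            stages = c("markers", "similarity", "pcoa",
                                       "partition", "admixture", "mantel"),
                            gs_bands = "all",
                            bootstrap_replicates = 1000,
                            permutations = 9999,
                            k_range = 2:10, runs = 4,
                            burnin = 2000, sweeps = 10000, thin = 10,
                            alpha = 1,
                            mantel_permutations = 999,
                            merge_groups = NULL,
                            clade_threshold = "mean") {
  if (is.null(input) == is.null(simulate)) {
    stop("supply exactly one of `input` or `simulate`", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  structure(
    list(input = input, simulate = simulate, seed = as.integer(seed),
         stages = stages, gs_bands = gs_bands,
         bootstrap_replicates = bootstrap_replicates,
         permutations = permutations, k_range = k_range, runs = runs,
         burnin = burnin, sweeps = sweeps, thin = thin, alpha = alpha,
         mantel_permutations = mantel_permutations,
         merge_groups = merge_groups, clade_threshold = clade_threshold),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML keys mirror the [pipeline_config()] arguments; a `simulate`
#' block holds [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  if (!is.null(y$k_range) && length(y$k_range) == 2L) {
    y$k_range <- seq(y$k_range[1], y$k_range[2])
  }
  do.call(pipeline_config, y)
}

stage_offsets <- c(simulate = 11L, bootstrap = 101L, partition = 211L,
                   admixture = 307L, mantel = 401L)

config_hash <- function(config) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(deparse(config[order(names(config))]), tf)
  unname(tools::md5sum(tf))
}

write_report_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bandpop %s config_hash=%s",
                     as.character(utils::packageVersion("bandpop")), hash), con)
  utils::write.csv(df, con, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Reproduces the standard dominant-marker analysis order: per-primer marker
#' statistics and panel summary; Dice similarity, UPGMA with bootstrap
#' supports, clade cut and PCoA; per-group diversity, AMOVA with PhiPT,
#' pairwise PhiPT and Nei group distances; multi-run Bayesian admixture with
#' Evanno delta-K and purity calls; and the Mantel suite against geographic
#' and environmental distances. Each enabled stage writes its tables (CSV
#' with a provenance header), the tree as Newick, and a run manifest.
#'
#' @param config A `pipeline_config` or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all stage results plus `manifest` (tibble
#'   of stage, status, elapsed seconds, outputs).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(config))
  seed <- config$seed
  results <- list()
  manifest <- tibble::tibble(stage = character(), status = character(),
                             elapsed = numeric(), outputs = character())
  note <- function(stage, status, elapsed, outputs = "") {
    manifest <<- dplyr::add_row(manifest, stage = stage, status = status,
                                elapsed = round(elapsed, 3),
                                outputs = paste(outputs, collapse = ";"))
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% c(config$stages, "load")) {
      note(stage, "skipped", 0); return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    el <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      note(stage, paste("failed:", conditionMessage(res)), el)
      write_manifest(manifest, out_dir, config, hash)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    res
  }

  # load or simulate
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(config$simulate)) {
    sim <- simulate_bands(config$simulate, seed = seed + stage_offsets[["simulate"]])
    bm <- sim$matrix; meta <- sim$meta
    results$sim <- sim
  } else {
    bm <- read_band_matrix(config$input$matrix,
                           primer_map = config$input$primer_map,
                           primer_class = config$input$primer_class)
    meta <- read_accession_meta(config$input$metadata)
  }
  note("load", "ok", proc.time()[["elapsed"]] - t0,
       if (!is.null(config$simulate)) "simulated" else config$input$matrix)
  results$matrix <- bm
  results$meta <- meta

  if ("markers" %in% config$stages) {
    t0 <- proc.time()[["elapsed"]]
    ms <- marker_stats(bm)
    ps <- panel_summary(ms)
    write_report_csv(ms, file.path(out_dir, "marker_stats.csv"), hash)
    write_report_csv(tidy(ps), file.path(out_dir, "panel_summary.csv"), hash)
    results$marker_stats <- ms
    results$panel_summary <- ps
    note("markers", "ok", proc.time()[["elapsed"]] - t0,
         c("marker_stats.csv", "panel_summary.csv"))
  } else note("markers", "skipped", 0)

  gs <- NULL
  if (any(c("similarity", "pcoa", "mantel") %in% config$stages)) {
    gs <- genetic_similarity(bm, bands = config$gs_bands)
    results$similarity <- gs
  }

  if ("similarity" %in% config$stages) {
    t0 <- proc.time()[["elapsed"]]
    tree <- bootstrap_upgma(bm, replicates = config$bootstrap_replicates,
                            seed = seed + stage_offsets[["bootstrap"]],
                            bands = config$gs_bands)
    thr <- if (identical(config$clade_threshold, "mean")) {
      mean(tidy(gs)$gs)
    } else config$clade_threshold
    clades <- cut_clades(tree, thr)
    utils::write.csv(as.data.frame(gs$gs),
                     file.path(out_dir, "gs_matrix.csv"))
    write_newick(tree, file.path(out_dir, "upgma_tree.nwk"))
    write_report_csv(tree$support, file.path(out_dir, "bootstrap_support.csv"), hash)
    write_report_csv(clades, file.path(out_dir, "clades.csv"), hash)
    results$tree <- tree
    results$clades <- clades
    results$clade_threshold <- thr
    note("similarity", "ok", proc.time()[["elapsed"]] - t0,
         c("gs_matrix.csv", "upgma_tree.nwk", "bootstrap_support.csv", "clades.csv"))
  } else note("similarity", "skipped", 0)

  if ("pcoa" %in% config$stages) {
    t0 <- proc.time()[["elapsed"]]
    ord <- pcoa(gs$dist)
    write_report_csv(tidy(ord), file.path(out_dir, "pcoa_coordinates.csv"), hash)
    write_report_csv(ord$percent, file.path(out_dir, "pcoa_eigenvalues.csv"), hash)
    results$pcoa <- ord
    note("pcoa", "ok", proc.time()[["elapsed"]] - t0,
         c("pcoa_coordinates.csv", "pcoa_eigenvalues.csv"))
  } else note("pcoa", "skipped", 0)

  if ("partition" %in% config$stages) {
    t0 <- proc.time()[["elapsed"]]
    gd <- group_diversity(keep_polymorphic(bm), meta)
    am <- amova(bm, meta, permutations = config$permutations,
                seed = seed + stage_offsets[["partition"]])
    pp <- pairwise_phipt(bm, meta, permutations = min(config$permutations, 999),
                         seed = seed + stage_offsets[["partition"]])
    nd <- nei_group_distance(keep_polymorphic(bm), meta)
    write_report_csv(gd, file.path(out_dir, "group_diversity.csv"), hash)
    write_report_csv(tidy(am), file.path(out_dir, "amova.csv"), hash)
    write_report_csv(glance(am), file.path(out_dir, "amova_summary.csv"), hash)
    write_report_csv(pp, file.path(out_dir, "pairwise_phipt.csv"), hash)
    write_report_csv(nd, file.path(out_dir, "nei_distance.csv"), hash)
    results$group_diversity <- gd
    results$amova <- am
    results$pairwise_phipt <- pp
    results$nei_distance <- nd
    note("partition", "ok", proc.time()[["elapsed"]] - t0,
         c("group_diversity.csv", "amova.csv", "amova_summary.csv",
           "pairwise_phipt.csv", "nei_distance.csv"))
  } else note("partition", "skipped", 0)

  if ("admixture" %in% config$stages) {
    t0 <- proc.time()[["elapsed"]]
    scan <- admixture_scan(bm, k_range = config$k_range, runs = config$runs,
                           seed = seed + stage_offsets[["admixture"]],
                           burnin = config$burnin, sweeps = config$sweeps,
                           thin = config$thin, alpha = config$alpha)
    ev <- evanno_delta_k(scan)
    best_k <- attr(ev, "best_k")
    best_fit <- if (!is.na(best_k)) {
      fits <- align_runs(scan$fit[scan$k == best_k])
      fits[[which.max(scan$ln_pd[scan$k == best_k])]]
    } else scan$fit[[which.max(scan$ln_pd)]]
    pc <- purity_calls(best_fit, meta)
    write_report_csv(as.data.frame(ev), file.path(out_dir, "delta_k.csv"), hash)
    write_report_csv(dplyr::left_join(tidy(best_fit),
                                      meta[, c("accession_id", "geo_group")],
                                      by = "accession_id"),
                     file.path(out_dir, "q_matrix.csv"), hash)
    write_report_csv(pc, file.path(out_dir, "purity.csv"), hash)
    results$admixture_scan <- scan[, c("k", "run", "seed", "ln_pd")]
    results$evanno <- ev
    results$best_fit <- best_fit
    results$purity <- pc
    note("admixture", "ok", proc.time()[["elapsed"]] - t0,
         c("delta_k.csv", "q_matrix.csv", "purity.csv"))
  } else note("admixture", "skipped", 0)

  if ("mantel" %in% config$stages) {
    t0 <- proc.time()[["elapsed"]]
    mt <- mantel_suite(gs$dist, meta,
                       merge_groups = config$merge_groups,
                       n_perm = config$mantel_permutations,
                       seed = seed + stage_offsets[["mantel"]])
    write_report_csv(mt, file.path(out_dir, "mantel_suite.csv"), hash)
    results$mantel <- mt
    note("mantel", "ok", proc.time()[["elapsed"]] - t0, "mantel_suite.csv")
  } else note("mantel", "skipped", 0)

  write_manifest(manifest, out_dir, config, hash)
  results$manifest <- manifest
  invisible(results)
}

write_manifest <- function(manifest, out_dir, config, hash) {
  lines <- c(
    sprintf("bandpop %s", as.character(utils::packageVersion("bandpop"))),
    sprintf("seed: %d", config$seed),
    sprintf("config_hash: %s", hash),
    sprintf("stages: %s", paste(config$stages, collapse = ",")),
    "",
    sprintf("%-12s %-40s %8s  %s", "stage", "status", "elapsed", "outputs"),
    sprintf("%-12s %-40s %8.3f  %s", manifest$stage, manifest$status,
            manifest$elapsed, manifest$outputs)
  )
  writeLines(lines, file.path(out_dir, "manifest.txt"))
}
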