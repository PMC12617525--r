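# End-to-end orchestration: a single declarative config drives the stage
# order simulate -> preprocess -> features -> predict -> cluster -> diff,
# with an independent spatial arm, and a run manifest (config snapshot,
# derived seeds, file digests) makes runs reproducible and diffable.

#' Default pipeline configuration
#'
#' A nested list that is the single source of truth for a run. Any subset of
#' keys can be overridden; unknown keys are rejected by [run_pipeline()].
#' The `sim` entry is a [sim_config()] and defines the synthetic study
#' conditions; `stages` gates each stage (a spatial-only run disables the
#' CF-MS stages).
#'
#' @param ... named overrides merged over the defaults (nested lists merged
#'   recursively).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    stages = list(simulate = TRUE, preprocess = TRUE, features = TRUE,
                  predict = TRUE, cluster = TRUE, diff = TRUE,
                  spatial = TRUE),
    sim = sim_config(),
    rewiring = list(HET = c(deleted = 0.15, split = 0.05, apex_shifted = 0.05),
                    HOM = c(deleted = 0.3, split = 0.1, apex_shifted = 0.1)),
    extract = "Mt",
    preprocess = list(mode = "both", log2_transform = FALSE),
    features = list(metrics = similarity_metrics(), prefilter_floor = NULL),
    predict = list(models = c("rf", "glm", "svm"), k_folds = 5L,
                   negative_ratio = 1, threshold_rule = "youden",
                   reference_gmt = NULL, compartments_tsv = NULL),
    cluster = list(d_grid = seq(0.2, 0.45, by = 0.05),
                   o_grid = seq(0.5, 0.8, by = 0.1),
                   penalty = 2, min_size = 3L),
    diff = list(reference_genotype = "WT", n_perm = 200L,
                weight_exponent = 1, gsea_mode = "total"),
    spatial = list(n_per_group = 20L, n_genes = 1000L, deg_frac = 0.1,
                   effect_size = 2, region = "SN", marker_floor = 1,
                   groups = c("HOM", "WT"), p_cut = 0.05, top_frac = 0.2,
                   test = "welch"))
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (k in names(overrides)) {
    # `rewiring` is replaced wholesale (its genotypes define the design);
    # other nested lists are merged key-wise over the defaults
    cfg[[k]] <- if (k != "rewiring" && is.list(cfg[[k]]) &&
                    is.list(overrides[[k]]) &&
                    !inherits(overrides[[k]], "sim_config"))
      utils::modifyList(cfg[[k]], overrides[[k]]) else overrides[[k]]
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose top-level keys match [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  do.call(pipeline_config, raw)
}

pipeline_log <- function(verbose, ...) if (verbose) message(sprintf(...))

#' Run the full pipeline under one config
#'
#' Executes the enabled stages in the fixed order simulate -> preprocess ->
#' features -> predict -> cluster -> diff, plus the independent spatial arm,
#' writing every artifact under `outdir` and finishing with a run manifest
#' (`manifest.json`: config snapshot, derived per-stage seeds, stage order,
#' md5 digest of every output, package version, timestamp). Every stochastic
#' stage consumes a named sub-seed derived from the master seed, so a rerun
#' with the same config and seed reproduces byte-identical stage outputs.
#' A stage failure aborts with the stage name; prior outputs are left
#' intact.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param verbose log stage progress and row counts.
#' @return invisibly, a list with the manifest and the key in-memory results
#'   (truth, networks, catalogs, reports).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  if (isTRUE(st$predict) && !isTRUE(st$simulate) &&
      is.null(config$predict$reference_gmt))
    stop("config key predict$reference_gmt is required when the simulate ",
         "stage is disabled")
  results <- list()
  outputs <- character()
  seeds <- list()
  add_out <- function(path) outputs <<- c(outputs, path)
  stage <- function(name, enabled, body) {
    if (!isTRUE(enabled)) return(invisible(NULL))
    pipeline_log(verbose, "stage %s ...", name)
    tryCatch(body(), error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }
  genotypes <- NULL

  stage("simulate", st$simulate, function() {
    seeds$simulate <<- derive_seed(config$seed, "truth")
    cfg <- config$sim
    cfg$seed <- as.integer(config$seed)
    truth <- generate_truth(cfg, config$rewiring)
    results$truth <<- truth
    genotypes <<- truth$genotypes
    for (g in truth$genotypes) {
      add_out(write_gmt(truth$catalogs[[g]],
                        file.path(outdir, paste0("planted_", g, ".gmt"))))
      mats <- simulate_elution(truth, cfg, g, extract = config$extract)
      results$engine_matrices[[g]] <<- mats
      for (m in mats)
        add_out(write_matrix(m, file.path(
          outdir, sprintf("elution_%s_%s.tsv", g, attr(m, "engine")))))
    }
    add_out(write_compartments(truth$compartments,
                               file.path(outdir, "compartments.tsv")))
    add_out(write_report(list(rewiring_log = truth$rewiring_log),
                         file.path(outdir, "rewiring_log.json"),
                         schema = "rewiring-log"))
  })

  stage("preprocess", st$preprocess, function() {
    for (g in genotypes) {
      pp <- preprocess_condition(results$engine_matrices[[g]],
                                 mode = config$preprocess$mode,
                                 log2_transform = config$preprocess$log2_transform)
      results$matrices[[g]] <<- pp$matrix
      add_out(write_matrix(pp$matrix,
                           file.path(outdir, sprintf("combined_%s.tsv", g))))
      add_out(write_report(pp$report,
                           file.path(outdir, sprintf("preprocess_%s.json", g)),
                           schema = "preprocess-report"))
      pipeline_log(verbose, "  %s: %d proteins kept", g, nrow(pp$matrix))
    }
  })

  stage("features", st$features, function() {
    for (g in genotypes) {
      ft <- compute_features(results$matrices[[g]],
                             metrics = config$features$metrics,
                             prefilter_floor = config$features$prefilter_floor)
      results$features[[g]] <<- ft
      path <- file.path(outdir, sprintf("features_%s.tsv", g))
      tab <- ft
      for (m in attr(ft, "metrics")) tab[[m]] <- format_num(tab[[m]])
      utils::write.table(tab, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add_out(path)
      pipeline_log(verbose, "  %s: %d candidate pairs", g, nrow(ft))
    }
  })

  stage("predict", st$predict, function() {
    reference <- if (!is.null(config$predict$reference_gmt))
      read_gmt(config$predict$reference_gmt) else results$truth$catalogs$WT
    compartments <- if (!is.null(config$predict$compartments_tsv))
      read_compartments(config$predict$compartments_tsv) else
        results$truth$compartments
    results$reference <<- reference
    for (g in genotypes) {
      seeds[[paste0("predict_", g)]] <<- derive_seed(config$seed,
                                                     paste0("predict:", g))
      training <- build_training(reference, rownames(results$matrices[[g]]),
                                 negative_ratio = config$predict$negative_ratio,
                                 seed = seeds[[paste0("predict_", g)]])
      ts <- train_and_score(results$features[[g]], training,
                            models = config$predict$models,
                            k_folds = config$predict$k_folds,
                            seed = seeds[[paste0("predict_", g)]])
      thr <- select_threshold(ts$report, rule = config$predict$threshold_rule)
      net <- threshold_network(ts$scores, thr, genotype = g,
                               extract = config$extract)
      flt <- filter_implausible(net, compartments)
      results$networks[[g]] <<- flt$network
      add_out(write_edges(flt$network,
                          file.path(outdir, sprintf("network_%s.tsv", g)),
                          removed = flt$removed))
      add_out(write_report(
        list(genotype = g, threshold = thr,
             threshold_rule = config$predict$threshold_rule,
             pooled_auroc = as.list(ts$report$pooled_auroc),
             n_positive = ts$report$n_positive,
             n_negative = ts$report$n_negative,
             n_edges = nrow(flt$network),
             n_implausible_removed = nrow(flt$removed),
             n_unannotated_passed = flt$n_unannotated_passed),
        file.path(outdir, sprintf("cv_report_%s.json", g)),
        schema = "cv-report"))
      pipeline_log(verbose, "  %s: auROC=%.3f threshold=%.3f edges=%d", g,
                   ts$report$pooled_auroc[["ensemble"]], thr,
                   nrow(flt$network))
    }
  })

  stage("cluster", st$cluster, function() {
    for (g in genotypes) {
      opt <- optimize_params(results$networks[[g]], results$reference,
                             d_grid = config$cluster$d_grid,
                             o_grid = config$cluster$o_grid,
                             penalty = config$cluster$penalty,
                             min_size = config$cluster$min_size)
      results$complexes[[g]] <<- opt$best$catalog
      results$cluster_grid[[g]] <<- opt$grid
      if (length(opt$best$catalog))
        add_out(write_gmt(opt$best$catalog,
                          file.path(outdir, sprintf("complexes_%s.gmt", g))))
      add_out(write_report(list(genotype = g, best_d = opt$best$d,
                                best_o = opt$best$o, grid = opt$grid),
                           file.path(outdir, sprintf("cluster_grid_%s.json", g)),
                           schema = "cluster-grid"))
    }
  })

  stage("diff", st$diff, function() {
    ref_g <- config$diff$reference_genotype
    others <- setdiff(genotypes, ref_g)
    inter <- intersect_networks(results$networks[genotypes])
    results$intersections <<- inter
    add_out(write_report(list(genotypes = inter$genotypes,
                              n_union = inter$n_union, cells = inter$cells),
                         file.path(outdir, "intersections.json"),
                         schema = "intersection-report"))
    lost <- lost_interactions(results$networks[[ref_g]],
                              results$networks[others])
    results$lost <<- lost
    add_out(write_report(list(reference = ref_g, others = others,
                              n_lost = lost$n_lost,
                              n_involved = length(lost$involved_proteins),
                              hub_percent = as.list(lost$hub_percent)),
                         file.path(outdir, "lost_ppis.json"),
                         schema = "lost-ppi-report"))
    # complexes identified across the genotypes, consolidated as gene sets
    sets <- list()
    for (g in genotypes) for (id in names(results$complexes[[g]]))
      sets[[paste0(g, ":", id)]] <- results$complexes[[g]][[id]]
    if (length(sets)) {
      gene_sets <- complex_catalog(sets, source = "predicted")
      for (g in others) {
        seeds[[paste0("gsea_", g)]] <<- derive_seed(config$seed,
                                                    paste0("gsea:", g))
        ranking <- rank_proteins(results$matrices[[ref_g]],
                                 results$matrices[[g]],
                                 mode = config$diff$gsea_mode)
        enr <- complex_gsea(ranking, gene_sets, n_perm = config$diff$n_perm,
                            weight_exponent = config$diff$weight_exponent,
                            seed = seeds[[paste0("gsea_", g)]])
        results$gsea[[g]] <<- enr
        path <- file.path(outdir, sprintf("gsea_%s_vs_%s.tsv", g, ref_g))
        tab <- as.data.frame(enr)
        for (cc in c("es", "nes", "p", "q")) tab[[cc]] <- format_num(tab[[cc]])
        utils::write.table(tab, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        add_out(path)
      }
    }
    excl <- exclusive_assemblies(results$complexes[genotypes])
    for (g in genotypes)
      if (length(excl[[g]]))
        add_out(write_gmt(excl[[g]],
                          file.path(outdir, sprintf("exclusive_%s.gmt", g))))
  })

  stage("spatial", st$spatial, function() {
    sp <- config$spatial
    seeds$spatial <<- derive_seed(config$seed, "spots")
    sim <- simulate_spots(n_per_group = sp$n_per_group, n_genes = sp$n_genes,
                          deg_frac = sp$deg_frac,
                          effect_size = sp$effect_size,
                          seed = seeds$spatial, groups = sp$groups,
                          region = sp$region)
    selected <- select_spots(sim$spots, sp$region,
                             marker_floor = sp$marker_floor)
    stats <- gene_stats(selected, sp$groups[1L], sp$groups[2L],
                        test = sp$test)
    table <- call_degs(score_genes(stats), p_cut = sp$p_cut,
                       top_frac = sp$top_frac)
    results$deg_table <<- table
    results$deg_truth <<- sim$deg_truth
    path <- file.path(outdir, "spatial_degs.tsv")
    tab <- table
    for (cc in c("mu_test", "mu_ref", "sd_test", "sd_ref", "p", "fcs", "sns"))
      tab[[cc]] <- format_num(tab[[cc]])
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_out(path)
    called <- table$gene[table$deg_flag]
    recall <- if (length(sim$deg_truth))
      mean(names(sim$deg_truth) %in% called) else NA_real_
    add_out(write_report(list(n_spots_selected = nrow(selected$counts),
                              n_genes = nrow(table),
                              n_deg_called = length(called),
                              n_deg_planted = length(sim$deg_truth),
                              planted_recall = recall),
                         file.path(outdir, "spatial_summary.json"),
                         schema = "spatial-summary"))
  })

  manifest <- list(
    package = "cofracnet",
    version = as.character(utils::packageVersion("cofracnet")),
    timestamp = format(Sys.time(), tz = "UTC"),
    master_seed = config$seed,
    stage_order = c("simulate", "preprocess", "features", "predict",
                    "cluster", "diff", "spatial"),
    stages_enabled = st,
    derived_seeds = seeds,
    config = config_snapshot(config),
    outputs = {
      paths <- sort(unique(outputs))
      as.list(stats::setNames(unname(tools::md5sum(paths)), basename(paths)))
    })
  write_report(manifest, file.path(outdir, "manifest.json"),
               schema = "run-manifest")
  results$manifest <- manifest
  invisible(results)
}

# JSON-serializable snapshot of the effective config
config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$sim <- unclass(snap$sim)
  snap
}
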