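#' Analysis configuration
#'
#' Collects every tunable of the pipeline in one validated list. All
#' thresholds are in the units of the data (intensities in non-log units,
#' rates in 1/hour); the seed is recorded in every output manifest.
#'
#' @param seed Integer seed driving all randomness.
#' @param k Number of principal activity clusters (default 5).
#' @param census_fold Fold threshold of the expression census (default 2).
#' @param decay_fold Fold threshold of the decay census (default 1.5).
#' @param range_min,up_fold,floor_frac Up-regulation filter thresholds
#'   (see [select_upregulated()]).
#' @param down_fold Down-regulation filter threshold.
#' @param r_threshold,min_wave_size Wave clustering settings (see
#'   [pearson_cluster_downregulated()]).
#' @param top_n Genes in the differential-expression gradient (default
#'   2000).
#' @param cca_top_m Size of the exported top-contributor list (default
#'   1000).
#' @param max_genes Optional deterministic subsample of the modelling set
#'   before pair fitting (full all-pairs fitting grows quadratically).
#' @param fit A [fit_config()] for the pair fitting.
#' @param synth A [synth_config()] used when simulating.
#' @param sd_a,sd_b Intensity error-model coefficients.
#' @param log_input If `TRUE`, input matrices are log2 scale and are
#'   exponentiated on load (the kinetic model is linear in concentration).
#' @return List of class `gwtm_config`.
#' @export
gwtm_config <- function(seed = 1L, k = 5L, census_fold = 2,
                        decay_fold = 1.5, range_min = 1.5, up_fold = 1.5,
                        floor_frac = 0.1, down_fold = 1.5,
                        r_threshold = 0.8, min_wave_size = 5L,
                        top_n = 2000L, cca_top_m = 1000L,
                        max_genes = NULL, fit = NULL, synth = NULL,
                        sd_a = 1, sd_b = 0.1, log_input = FALSE) {
  if (k < 2L) stop("k must be at least 2")
  for (nm in c("census_fold", "decay_fold", "range_min", "up_fold",
               "down_fold", "r_threshold")) {
    if (get(nm) <= 0) stop(nm, " must be > 0")
  }
  seed <- as.integer(seed)
  if (is.null(fit)) fit <- fit_config(seed = seed)
  if (is.null(synth)) synth <- synth_config(sd_a = sd_a, sd_b = sd_b)
  structure(list(seed = seed, k = as.integer(k),
                 census_fold = census_fold, decay_fold = decay_fold,
                 range_min = range_min, up_fold = up_fold,
                 floor_frac = floor_frac, down_fold = down_fold,
                 r_threshold = r_threshold,
                 min_wave_size = as.integer(min_wave_size),
                 top_n = as.integer(top_n),
                 cca_top_m = as.integer(cca_top_m), max_genes = max_genes,
                 fit = fit, synth = synth, sd_a = sd_a, sd_b = sd_b,
                 log_input = log_input),
            class = "gwtm_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML map onto [gwtm_config()] arguments; `fit:`
#' and `synth:` sub-maps onto [fit_config()] and [synth_config()].
#'
#' @param path YAML file path.
#' @return A `gwtm_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  fit <- if (!is.null(y$fit)) do.call(fit_config, y$fit) else NULL
  synth <- if (!is.null(y$synth)) do.call(synth_config, y$synth) else NULL
  y$fit <- NULL; y$synth <- NULL
  do.call(gwtm_config, c(y, list(fit = fit, synth = synth)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order on a simulated dataset (or on matrices
#' read from `inputs`): fold-change censuses, up/down filters,
#' degradation-array normalization and decay census, all-pairs kinetic
#' fitting on the modelling set, Ward clustering into principal
#' activities with mean G profiles, wave clustering of the down-regulated
#' genes, and CCA staging of a differentiating trajectory against
#' simulated reference populations. Writes TSV artifacts plus a JSON run
#' manifest (config hash, seed, per-stage outputs) into `outdir`.
#'
#' @param config A [gwtm_config()].
#' @param outdir Output directory (created if needed).
#' @param inputs Optional list with `expression` and `degradation` file
#'   paths (TSV, read with [read_time_course()]); when `NULL` the
#'   synthetic generator is used.
#' @param resume Reuse the pair-fitting checkpoint in `outdir` if present.
#' @param progress Progress messaging interval for pair fitting.
#' @return List of class `gwtm_run` with all stage results and `manifest`.
#' @export
run_pipeline <- function(config = gwtm_config(), outdir = tempfile("gwtm_"),
                         inputs = NULL, resume = FALSE, progress = 0L) {
  stopifnot(inherits(config, "gwtm_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- config_hash(config)
  manifest <- list(package = "gwtm",
                   version = as.character(utils::packageVersion("gwtm")),
                   seed = config$seed, config_hash = cfg_hash,
                   stages = list())
  stage_done <- function(name, files) {
    manifest$stages[[name]] <<- list(completed = TRUE, outputs = files)
  }
  egrid <- expression_grid()
  dgrid <- degradation_grid()
  op <- build_derivative_operator(egrid)

  # --- data ---------------------------------------------------------------
  if (is.null(inputs)) {
    sim <- simulate_dataset(config$synth, seed = config$seed)
    expr <- sim$expression
    deg <- sim$degradation
    truth <- sim$truth
    utils::write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    for (p in unlist(inputs)) {
      if (!file.exists(p)) stop("input file not found: ", p)
    }
    expr <- read_time_course(inputs$expression, egrid,
                             sd_a = config$sd_a, sd_b = config$sd_b)
    deg <- read_time_course(inputs$degradation, dgrid,
                            sd_a = config$sd_a, sd_b = config$sd_b)
    if (config$log_input) {
      expr <- time_course_matrix(2^expr$values, egrid,
                                 gene_ids = expr$gene_ids,
                                 sd_a = config$sd_a, sd_b = config$sd_b)
      deg <- time_course_matrix(2^deg$values, dgrid,
                                gene_ids = deg$gene_ids,
                                sd_a = config$sd_a, sd_b = config$sd_b)
    }
    truth <- NULL
  }
  write_time_course(expr, file.path(outdir, "expression.tsv"))
  write_time_course(deg, file.path(outdir, "degradation_raw.tsv"))
  stage_done("data", c("expression.tsv", "degradation_raw.tsv"))

  # --- censuses and filters ----------------------------------------------
  census <- fold_change_census(expr, fold = config$census_fold)
  utils::write.table(census, file.path(outdir, "expression_census.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  up <- select_upregulated(expr, range_min = config$range_min,
                           up_fold = config$up_fold,
                           floor_frac = config$floor_frac)
  down <- select_downregulated(expr, down_fold = config$down_fold)
  writeLines(up$selected, file.path(outdir, "upregulated_genes.txt"))
  writeLines(down$selected, file.path(outdir, "downregulated_genes.txt"))
  stage_done("filters", c("expression_census.tsv", "upregulated_genes.txt",
                          "downregulated_genes.txt"))

  # --- degradation normalization ------------------------------------------
  norm <- normalize_degradation_arrays(deg)
  write_time_course(norm$normalized,
                    file.path(outdir, "degradation_normalized.tsv"))
  dcensus <- decay_census(norm$normalized, fold = config$decay_fold)
  utils::write.table(dcensus, file.path(outdir, "decay_census.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_done("degradation",
             c("degradation_normalized.tsv", "decay_census.tsv"))

  # --- pair fitting on the modelling set ----------------------------------
  model_genes <- intersect(up$selected, norm$normalized$gene_ids)
  if (!is.null(config$max_genes) &&
      length(model_genes) > config$max_genes) {
    model_genes <- withr_seed(derive_seed(config$seed, 7L), function() {
      sort(sample(model_genes, config$max_genes))
    })
    warning("modelling set subsampled to ", config$max_genes,
            " genes; cluster-level results differ from a full-set run")
  }
  if (length(model_genes) < 2L) stop("fewer than 2 genes to model")
  ckpt <- file.path(outdir, "rss_checkpoint.tsv")
  if (!resume && file.exists(ckpt)) unlink(ckpt)
  rss <- rss_matrix(expr, norm$normalized, genes = model_genes, op = op,
                    cfg = config$fit, checkpoint = ckpt,
                    progress = progress)
  write_rss_matrix(rss, file.path(outdir, "rss_matrix.tsv"))
  stage_done("pairfit", "rss_matrix.tsv")

  # --- clustering into principal activities -------------------------------
  clust <- ward_cluster(rss, k = config$k)
  d_hat <- vapply(model_genes, function(g) {
    estimate_decay_rate(norm$normalized$values[
      match(g, norm$normalized$gene_ids), ], dgrid)$D_hat
  }, numeric(1L))
  gprof <- cluster_g_profiles(clust, expr, d_hat, op)
  write_cluster_table(gprof$labels,
                      file.path(outdir, "activity_clusters.tsv"),
                      quiet = TRUE)
  utils::write.table(gprof$profiles,
                     file.path(outdir, "cluster_g_profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = format_grid_times(egrid))
  write_dendrogram_newick(clust$hclust,
                          file.path(outdir, "activity_dendrogram.nwk"))
  stage_done("clustering", c("activity_clusters.tsv",
                             "cluster_g_profiles.tsv",
                             "activity_dendrogram.nwk"))

  # --- down-regulation waves ----------------------------------------------
  waves <- NULL
  if (length(down$selected) >= 2L) {
    waves <- pearson_cluster_downregulated(
      subset_genes(expr, down$selected),
      r_threshold = config$r_threshold,
      min_size = config$min_wave_size)
    wl <- waves$labels[!is.na(waves$labels)]
    write_cluster_table(wl, file.path(outdir, "wave_clusters.tsv"),
                        quiet = TRUE)
    stage_done("waves", "wave_clusters.tsv")
  }

  # --- CCA staging ---------------------------------------------------------
  refs <- simulate_reference_populations(seed = config$seed)
  traj <- simulate_trajectory(refs$ref, egrid, seed = config$seed)
  grad <- build_gradient(refs$ref, top_n = config$top_n)
  cca <- cca_scores(traj, grad)
  utils::write.table(
    data.frame(sample = names(cca$scores), time = as.numeric(egrid),
               score = as.numeric(cca$scores)),
    file.path(outdir, "cca_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(top_cca_contributors(cca, config$cca_top_m),
             file.path(outdir, "cca_top_contributors.txt"))
  stage_done("cca", c("cca_scores.tsv", "cca_top_contributors.txt"))

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(expression = expr, degradation = norm$normalized,
                 truth = truth, census = census, up = up, down = down,
                 normalization = norm, rss = rss, clusters = clust,
                 g_profiles = gprof, waves = waves, gradient = grad,
                 cca = cca, manifest = manifest, outdir = outdir),
            class = "gwtm_run")
}

#' @export
print.gwtm_run <- function(x, ...) {
  cat("<gwtm_run>\n")
  cat("  outdir:", x$outdir, "\n")
  cat("  stages:", paste(names(x$manifest$stages), collapse = ", "), "\n")
  invisible(x)
}
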