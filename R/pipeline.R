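#' Pipeline run configuration
#'
#' Collects every stage parameter and seed of the end-to-end synthetic
#' workflow.  Defaults reproduce the field design at desk scale: a
#' 150 x 150 km landscape of 1,000 m cells (so the 1/100 pseudo-absence
#' ratio with 183 presences — 18,300 absences — fits on the lattice),
#' 1,000 trees, threshold step 0.01, HII safety cut-off 10.  Each
#' stochastic stage derives its own sub-seed from `seed` so stages can be
#' re-run independently.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param shape grid shape c(rows, cols).
#' @param cell_size cell size, metres.
#' @param n_presence,n_test occurrence counts (defaults 183 and 102).
#' @param ratio pseudo-absences per presence (default 100).
#' @param n_trees forest size (default 1000).
#' @param threshold_step threshold-table step (default 0.01).
#' @param idw_power,idw_k IDW interpolation parameters.
#' @param hii_cutoff,hii_interval gap-analysis parameters.
#' @param settlement_count settlements in the synthetic HII raster.
#' @param pa_coverage protected-area coverage fraction of the landscape.
#' @param buffer_distance potential-area exclusion buffer, metres
#'   (default 3,000 on the 150-km synthetic landscape; the real-world
#'   dispersal buffer of 67,000 m is the [buffer_exclude()] default).
#' @param min_pixels,density_radius cluster aggregation parameters.
#' @param autocorr_range covariate smoothing range, cells.
#' @param stages character vector of stages to run.
#' @param out_dir optional directory for file outputs.
#' @return list of class `sdm_config`.
#' @export
sdm_config <- function(seed = 1, shape = c(150, 150), cell_size = 1000,
                       n_presence = 183, n_test = 102, ratio = 100,
                       n_trees = 1000, threshold_step = 0.01,
                       idw_power = 2, idw_k = 12,
                       hii_cutoff = 10, hii_interval = 5,
                       settlement_count = 30, pa_coverage = 0.25,
                       buffer_distance = 3000, min_pixels = 10,
                       density_radius = 5000, autocorr_range = 6,
                       stages = c("simulate", "sample", "fit", "evaluate",
                                  "surface", "gaps", "potential"),
                       out_dir = NULL) {
  cfg <- as.list(environment())
  # independent sub-seeds, kept below 2^31
  cfg$seeds <- list(covariates = (seed * 7 + 1) %% 2147483647,
                    occurrences = (seed * 7 + 2) %% 2147483647,
                    hii = (seed * 7 + 3) %% 2147483647,
                    protected = (seed * 7 + 4) %% 2147483647,
                    pseudo_absence = (seed * 7 + 5) %% 2147483647,
                    forest = (seed * 7 + 6) %% 2147483647,
                    bootstrap = (seed * 7 + 7) %% 2147483647)
  class(cfg) <- "sdm_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' The file form round-trips losslessly through [sdm_config()].
#'
#' @param path YAML path.
#' @return `sdm_config` (for the reader); `path` invisibly (writer).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$seeds <- NULL
  raw$shape <- as.integer(raw$shape)
  do.call(sdm_config, raw)
}

#' @rdname read_config
#' @param config `sdm_config`.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$seeds <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full synthetic workflow
#'
#' Executes the stages in order — simulate covariates and truth, sample
#' occurrences, build the training design, fit the forest, evaluate
#' (OOB AUC, threshold table, TSS, testing-point validation), build the
#' RIO and binary surfaces, run the conservation-gap overlay, and
#' delineate potential areas.  Re-running an identical configuration
#' reproduces every output exactly.
#'
#' @param config `sdm_config`.
#' @param verbose print stage progress (default TRUE).
#' @return a run manifest: list with `metrics` (auc, tss_at_threshold,
#'   tss_max, threshold, test medians/CIs, gap fractions, cluster
#'   shares), the fitted `model`, surfaces, tables and the echoed
#'   `config`.  When `config$out_dir` is set, rasters / tables /
#'   metrics.json are also written there.
#' @export
run_sdm_pipeline <- function(config = sdm_config(), verbose = TRUE) {
  stopifnot(inherits(config, "sdm_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  st <- config$stages
  if ("gaps" %in% st && !("simulate" %in% st) && is.null(config$hii_path))
    stop("gaps requires hii: enable the simulate stage or provide hii_path")
  res <- list(config = config)

  say("simulate: %d x %d landscape, seed %d", config$shape[1], config$shape[2],
      config$seed)
  stack <- generate_covariates(config$shape, config$cell_size,
                               seed = config$seeds$covariates,
                               autocorr_range = config$autocorr_range)
  spec <- default_response_spec()
  truth <- true_suitability(stack, spec)
  occ <- sample_occurrences(truth, config$n_presence, config$n_test,
                            seed = config$seeds$occurrences)
  hii <- generate_hii(config$shape, config$cell_size,
                      seed = config$seeds$hii,
                      settlement_count = config$settlement_count)
  pa <- generate_protected_areas(config$shape, config$cell_size,
                                 coverage_fraction = config$pa_coverage,
                                 seed = config$seeds$protected)
  res$stack <- stack; res$truth <- truth; res$occurrences <- occ
  res$hii <- hii; res$protected_areas <- pa

  say("sample: lattice + %d pseudo-absences per presence", config$ratio)
  tmpl <- stack[[1]]
  bounds <- c(tmpl$origin_x, tmpl$origin_y - nrow(tmpl$values) * tmpl$cell_size,
              tmpl$origin_x + ncol(tmpl$values) * tmpl$cell_size, tmpl$origin_y)
  lattice <- make_lattice(bounds, config$cell_size)
  presence <- extract_covariates(occ$presence, stack)
  absences <- sample_pseudo_absences(lattice, occ$presence, config$ratio,
                                     seed = config$seeds$pseudo_absence,
                                     grid = tmpl)
  absences <- extract_covariates(absences, stack)
  design <- assemble_design(presence, absences, stack)
  res$design <- design

  say("fit: %d trees on %d rows", config$n_trees, length(design$labels))
  model <- fit_suitability(design, n_trees = config$n_trees,
                           seed = config$seeds$forest)
  res$model <- model

  say("evaluate: OOB metrics and testing points")
  auc <- roc_auc(model$labels, model$oob)
  tab <- threshold_table(model$labels, model$oob, step = config$threshold_step)
  thr <- select_threshold(tab)
  row_at <- tab[which.min(abs(tab$threshold - thr)), ]
  test_scored <- score_points(model, extract_covariates(occ$test, stack))
  val <- validate_on_test(test_scored, seed = config$seeds$bootstrap)
  res$threshold_table <- tab; res$validation <- val
  res$importance <- variable_importance(model)

  say("surface: score lattice, IDW, binarize at %.2f", thr)
  lattice_scored <- score_points(model, extract_covariates(lattice, stack))
  rio <- idw_interpolate(lattice_scored, tmpl, power = config$idw_power,
                         k_neighbors = config$idw_k)
  binary <- binarize(rio, thr)
  res$rio <- rio; res$binary <- binary

  say("gaps: HII cutoff %g over protected areas", config$hii_cutoff)
  pa_mask <- if (length(pa$polygons)) rasterize_polygons(pa, tmpl) else
    raster_grid(matrix(0, nrow(tmpl$values), ncol(tmpl$values)),
                origin_x = tmpl$origin_x, origin_y = tmpl$origin_y,
                cell_size = tmpl$cell_size, name = "protected_mask")
  gaps <- conservation_gaps(binary, hii, pa_mask,
                            hii_cutoff = config$hii_cutoff,
                            hii_interval = config$hii_interval)
  res$protected_mask <- pa_mask; res$gaps <- gaps

  say("potential: %g m buffers, clusters >= %d pixels", config$buffer_distance,
      config$min_pixels)
  records <- rbind(as.data.frame(occ$presence)[c("x", "y")],
                   as.data.frame(occ$test)[c("x", "y")])
  records <- point_table(records$x, records$y, "presence")
  potential <- buffer_exclude(binary, known_ranges = NULL, records = records,
                              distance = config$buffer_distance)
  clusters <- aggregate_clusters(potential, min_pixels = config$min_pixels)
  res$potential_mask <- potential; res$clusters <- clusters
  if (nrow(clusters) > 0) {
    dens <- point_density(potential, radius = config$density_radius)
    res$density <- dens
    res$focal_regions <- rank_focal_regions(clusters, dens)
  }

  res$metrics <- list(
    auc = auc,
    threshold = thr,
    tss_at_threshold = row_at$tss,
    tss_max = max(tab$tss),
    sensitivity_at_threshold = row_at$sensitivity,
    specificity_at_threshold = row_at$specificity,
    test_rio_median = val$median,
    test_rio_ci_lower = val$ci_lower,
    test_rio_ci_upper = val$ci_upper,
    n_presence = config$n_presence,
    n_test = config$n_test,
    n_pseudo_absence = sum(design$labels == 0),
    n_presence_cells = gaps$n_presence_cells,
    protected_fraction = gaps$protected_fraction,
    hii_ge_cutoff_fraction = gaps$hii_ge_cutoff_fraction,
    protected_of_pressured_fraction = gaps$protected_of_pressured_fraction,
    gap_fraction = gaps$gap_fraction,
    n_clusters = nrow(clusters),
    top_cluster_share_pct = if (nrow(clusters)) max(clusters$share_pct) else 0)

  if (!is.null(config$out_dir)) write_outputs(res, config$out_dir)
  res
}

write_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_raster(res$rio, file.path(out_dir, "rio.asc"))
  write_raster(res$binary, file.path(out_dir, "binary.asc"))
  write_raster(res$gaps$gap_mask, file.path(out_dir, "gap_mask.asc"))
  write_raster(res$potential_mask, file.path(out_dir, "potential_mask.asc"))
  if (!is.null(res$density))
    write_raster(res$density, file.path(out_dir, "density.asc"))
  utils::write.csv(res$threshold_table,
                   file.path(out_dir, "threshold_table.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$clusters),
                   file.path(out_dir, "clusters.csv"), row.names = FALSE)
  utils::write.csv(res$importance, file.path(out_dir, "importance.csv"),
                   row.names = FALSE)
  if (length(res$protected_areas$polygons))
    write_polygons(res$protected_areas,
                   file.path(out_dir, "protected_areas.geojson"))
  jsonlite::write_json(res$metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  write_config(res$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
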