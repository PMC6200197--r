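#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with the conventional
#' defaults: 0.1 m cells, 1 m TPI neighbourhood, the six-class landform
#' thresholds (TPI cuts -0.3 / -0.05 / 0.15 / 0.4 SD, slope cut 7 degrees),
#' an AUC selection gate of 0.9, suitability thresholds 0.5 / 0.75, and
#' alpha 0.05 for the field statistics.
#'
#' Two input modes: `simulate = TRUE` generates the site from
#' [terrain_spec()] / [response_spec()]; otherwise `points_csv`,
#' `patches_geojson` and `samples_csv` must point to survey files.
#'
#' @param out_dir run directory (created if missing).
#' @param simulate generate a synthetic site instead of reading files.
#' @param points_csv,patches_geojson,samples_csv,trenches_geojson input
#'   paths (ignored when `simulate = TRUE`).
#' @param terrain a [terrain_spec] for the synthetic site.
#' @param response a [response_spec] for the synthetic presence.
#' @param factor_config factor-field table; see [default_factor_config()].
#' @param cell_size,tpi_radius grid resolution and TPI neighbourhood radius
#'   (metres).
#' @param tpi_breaks,slope_cut landform classification thresholds.
#' @param l2 ridge penalty for the GLM (0 = plain maximum likelihood).
#' @param auc_gate AUC threshold for model selection.
#' @param t_low,t_high suitability reclassification thresholds.
#' @param importance_k permutations per factor for importance scores
#'   (0 skips the importance stage).
#' @param krige_factors run the kriging stage (ordinary kriging + LOO
#'   validation of every sampled factor).
#' @param n_trenches trench count; `NULL` = density default.
#' @param seed master seed; stage seeds are derived from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("microsdm_run_"),
                            simulate = TRUE,
                            points_csv = NULL, patches_geojson = NULL,
                            samples_csv = NULL, trenches_geojson = NULL,
                            terrain = terrain_spec(),
                            response = response_spec(),
                            factor_config = default_factor_config(),
                            cell_size = 0.1, tpi_radius = 1.0,
                            tpi_breaks = c(-0.3, -0.05, 0.15, 0.4),
                            slope_cut = 7,
                            l2 = 0, auc_gate = 0.9,
                            t_low = 0.5, t_high = 0.75,
                            importance_k = 3, krige_factors = TRUE,
                            n_trenches = NULL,
                            seed = 1) {
  if (!simulate && (is.null(points_csv) || is.null(samples_csv)))
    stop("file mode needs points_csv and samples_csv")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes terrain gridding, landform classification, factor
#' interpolation, SDM calibration, the restoration scenario and area
#' accounting, writing every intermediate layer and a machine-readable
#' summary into the run directory. Deterministic given the configuration
#' and its seed. Stages:
#'
#' 1. simulate (optional): synthetic survey points, factor fields, presence
#'    and sampling design;
#' 2. terrain: DEM, slope, aspect (+ reclassified codes), TPI, six-class
#'    microtopography, patch overlay areas;
#' 3. interpolate: ordinary kriging of every sampled factor with
#'    leave-one-out validation;
#' 4. fit: per-cell training table, GLM calibration, AUC gate, permutation
#'    importance;
#' 5. scenario: level-trench factor replacement, scenario prediction,
#'    suitability reclassification, stratified area report.
#'
#' In simulate mode the model is calibrated on the generated factor fields
#' (kriged layers are still produced and validated); in file mode the
#' kriged layers are the predictors.
#'
#' @param config a [pipeline_config].
#' @return the run summary (also written as `summary.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "log.txt")
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  stage <- "setup"
  on.exit(if (!identical(stage, "done"))
    log_line("pipeline aborted during stage '%s'; partial artifacts kept in %s",
             stage, config$out_dir))
  log_line("microsdm %s, seed %d, out_dir %s",
           as.character(utils::packageVersion("microsdm")), config$seed,
           config$out_dir)
  seed <- config$seed

  ## -- stage: simulate / read inputs ----------------------------------
  stage <- "simulate"
  if (config$simulate) {
    ts <- config$terrain
    ts$seed <- seed
    points <- generate_terrain(ts)
    write_points_csv(points, file.path(config$out_dir, "points.csv"))
    log_line("simulated %d survey points over %g x %g m", nrow(points),
             ts$extent_x, ts$extent_y)
  } else {
    points <- read_points_csv(config$points_csv)
    log_line("read %d survey points from %s", nrow(points), config$points_csv)
  }

  ## -- stage: terrain --------------------------------------------------
  stage <- "terrain"
  dem <- grid_dem(points, config$cell_size)
  slope <- compute_slope(dem)
  aspect <- compute_aspect(dem)
  aspect_class <- reclassify_aspect(aspect)
  tpi <- compute_tpi(dem, config$tpi_radius)
  microtopo <- classify_microtopography(tpi, slope, config$tpi_breaks,
                                        config$slope_cut)
  for (nm in c("dem", "slope", "aspect", "aspect_class", "tpi", "microtopo"))
    write_ascii_grid(get(nm), file.path(config$out_dir, paste0(nm, ".asc")))
  log_line("terrain: %d x %d grid at %g m", nrow(dem$values), ncol(dem$values),
           config$cell_size)

  topo_stack <- list(altitude = dem, slope = slope, aspect_class = aspect_class)

  ## -- factor fields / presence / samples ------------------------------
  if (config$simulate) {
    fields <- generate_factor_fields(dem, tpi, config$factor_config,
                                     seed = seed + 1L)
    resp <- config$response
    resp$seed <- seed + 2L
    presence <- generate_presence(fields, resp)
    patches <- presence_to_patches(presence)
    write_geojson(patches, file.path(config$out_dir, "patches.geojson"))
    design <- generate_sampling_design(microtopo, seed = seed + 3L)
    samples <- sample_factor_table(design, fields,
                                   physiology = default_physiology_config(),
                                   seed = seed + 4L)
    utils::write.csv(samples, file.path(config$out_dir, "samples.csv"),
                     row.names = FALSE)
    factor_names <- config$factor_config$name
  } else {
    patches <- read_geojson(config$patches_geojson)
    presence <- rasterize_polygons(patches, dem)
    samples <- read_factor_samples_csv(config$samples_csv)
    factor_names <- setdiff(names(samples),
                            c("x", "y", "gully_type", "microtopo",
                              default_physiology_config()$name))
    fields <- NULL
  }
  class_areas <- overlay_class_areas(microtopo, presence)
  utils::write.csv(class_areas, file.path(config$out_dir, "class_areas.csv"),
                   row.names = FALSE)
  write_ascii_grid(presence, file.path(config$out_dir, "presence.asc"))

  ## -- stage: interpolate ----------------------------------------------
  stage <- "interpolate"
  kriged <- list()
  cv_rows <- list()
  if (config$krige_factors) {
    for (f in factor_names) {
      emp <- empirical_semivariogram(samples$x, samples$y, samples[[f]])
      vg <- fit_variogram(emp, "spherical")
      kriged[[f]] <- krige(samples$x, samples$y, samples[[f]], vg, dem)
      cv <- cross_validate(samples$x, samples$y, samples[[f]], vg)
      cv_rows[[f]] <- data.frame(factor = f, nugget = vg$nugget,
                                 psill = vg$psill, range = vg$range,
                                 mpe = cv$mpe, rmsse = cv$rmsse)
    }
    cv_report <- do.call(rbind, cv_rows)
    rownames(cv_report) <- NULL
    utils::write.csv(cv_report, file.path(config$out_dir, "cv_report.csv"),
                     row.names = FALSE)
    log_line("interpolate: kriged %d factors; mean |MPE| %.4g, mean RMSSE %.3f",
             length(factor_names), mean(abs(cv_report$mpe)),
             mean(cv_report$rmsse, na.rm = TRUE))
  } else {
    cv_report <- NULL
  }

  ## -- stage: fit -------------------------------------------------------
  stage <- "fit"
  predictor_layers <- if (config$simulate) fields$layers else kriged
  stack <- factor_stack(c(topo_stack, predictor_layers))
  train <- build_training(presence, stack)
  model <- fit_sdm(train, l2 = config$l2)
  selected <- select_model(list(model), threshold = config$auc_gate)
  write_sdm_json(selected, file.path(config$out_dir, "model.json"))
  prob_current <- predict(selected, stack)
  write_ascii_grid(prob_current,
                   file.path(config$out_dir, "probability_current.asc"))
  log_line("fit: GLM on %d cells (prevalence %.3f), AUC %.3f (%s)",
           model$n, model$prevalence, model$auc, accuracy_band(model$auc))
  if (config$importance_k > 0) {
    importance <- factor_importance(selected, train, k = config$importance_k,
                                    seed = seed + 5L)
    utils::write.csv(importance, file.path(config$out_dir, "importance.csv"),
                     row.names = FALSE)
  } else importance <- NULL

  ## -- stage: scenario ---------------------------------------------------
  stage <- "scenario"
  trenches <- generate_trenches(dem, n = config$n_trenches, seed = seed + 6L)
  write_geojson(trenches, file.path(config$out_dir, "trenches.geojson"))
  valley_rows <- samples$microtopo == "valley"
  replacements <- vapply(factor_names,
                         function(f) mean(samples[[f]][valley_rows]), 0)
  scen <- scenario_spec(trenches, replacements)
  stack_scen <- apply_scenario(stack, scen)
  prob_scen <- predict(selected, stack_scen)
  write_ascii_grid(prob_scen,
                   file.path(config$out_dir, "probability_scenario.asc"))
  suit <- reclassify_suitability(prob_scen, config$t_low, config$t_high)
  write_ascii_grid(suit$grid, file.path(config$out_dir, "suitability.asc"))
  report <- suitability_report(suit, microtopo, trenches)
  utils::write.csv(report, file.path(config$out_dir, "suitability_report.csv"),
                   row.names = FALSE)
  log_line("scenario: %d trenches; suitable %.2f m^2 (%.2f%%)",
           length(trenches), suit$areas$area_m2[3L], suit$areas$percentage[3L])

  ## -- stage: report -----------------------------------------------------
  stage <- "report"
  summary <- list(
    seed = seed,
    grid = list(n_rows = nrow(dem$values), n_cols = ncol(dem$values),
                cell_size = config$cell_size),
    class_areas = class_areas,
    patch_area_m2 = sum(class_areas$area_m2),
    n_presence = sum(train$label == 1),
    n_absence = sum(train$label == 0),
    model = list(kind = selected$kind, auc = selected$auc,
                 band = accuracy_band(selected$auc),
                 coefficients = as.list(selected$coefficients)),
    importance = if (!is.null(importance)) importance else NULL,
    kriging_cv = if (!is.null(cv_report)) cv_report else NULL,
    n_trenches = length(trenches),
    suitability = list(thresholds = c(config$t_low, config$t_high),
                       areas = suit$areas),
    suitability_report = report
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  stage <- "done"
  log_line("pipeline complete")
  invisible(summary)
}
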