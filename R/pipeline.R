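#' Pipeline configuration
#'
#' Collects the options of an end-to-end run. With no external inputs the
#' pipeline runs entirely on the synthetic generators, which is the
#' packaged demonstration mode.
#'
#' @param seed integer seed propagated to every stochastic stage.
#' @param output_dir directory for outputs (created if absent).
#' @param stages subset of
#'   `c("synth", "cardfit", "depthsim", "gamut", "survey", "scalebar")`.
#' @param optics a [water_optics()] for the synthetic card series.
#' @param layout a [card_layout()].
#' @param depths card-series depth grid in meters.
#' @param effort an [effort_spec()] for the dive-log simulation (its seed
#'   is overridden by `seed`).
#' @param sun optional [sun_table()]; defaults to the one in `effort`.
#'   Required by the survey stage.
#' @param interpolation_mode attenuation prediction mode, `"exponential"`
#'   or `"piecewise"`.
#' @param alternative tail of the exact Poisson rate test.
#' @param renormalize exposure renormalization in [simulate_at_depth()].
#' @param sim_depth depth (m) at which the demonstration flash image is
#'   re-rendered under ambient light.
#' @param mm_per_px,dot_separation_mm truth for the synthetic laser scene.
#' @param timezone_label nominal local-time label recorded in the
#'   manifest (timestamps themselves carry no offset).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, output_dir = "cuttleoptics-out",
                            stages = c("synth", "cardfit", "depthsim",
                                       "gamut", "survey", "scalebar"),
                            optics = water_optics(noise_sd = 0.005),
                            layout = default_card_layout(),
                            depths = card_series_depths(),
                            effort = effort_spec(),
                            sun = NULL,
                            interpolation_mode = c("exponential", "piecewise"),
                            alternative = c("deficit", "excess", "two.sided"),
                            renormalize = FALSE,
                            sim_depth = 10,
                            mm_per_px = 0.2, dot_separation_mm = 100,
                            timezone_label = "local") {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(
    seed = as.integer(seed), output_dir = output_dir, stages = stages,
    optics = optics, layout = layout, depths = depths, effort = effort,
    sun = sun, interpolation_mode = match.arg(interpolation_mode),
    alternative = match.arg(alternative), renormalize = renormalize,
    sim_depth = sim_depth, mm_per_px = mm_per_px,
    dot_separation_mm = dot_separation_mm,
    timezone_label = timezone_label),
    class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Accepts a JSON object whose fields mirror the [pipeline_config()]
#' arguments (scalars and the `optics` sub-object with `k`,
#' `surface_illuminant`, `noise_sd`); unspecified fields keep their
#' defaults.
#'
#' @param path JSON file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (f in c("seed", "output_dir", "stages", "interpolation_mode",
              "alternative", "renormalize", "sim_depth", "mm_per_px",
              "dot_separation_mm", "timezone_label"))
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  if (!is.null(cfg$optics))
    args$optics <- do.call(water_optics, cfg$optics)
  if (!is.null(cfg$depths)) args$depths <- cfg$depths
  do.call(pipeline_config, args)
}

write_csv_out <- function(df, dir, name) {
  p <- file.path(dir, name)
  utils::write.csv(df, p, row.names = FALSE)
  p
}

#' Run the full pipeline on synthetic inputs
#'
#' Executes the requested stages in order — synthesize inputs, fit the
#' attenuation model, simulate a flash image at depth, build the
#' depth-gamut profile, aggregate survey effort and run the encounter-rate
#' tests, calibrate the laser scale — writing CSV/JSON outputs and a run
#' manifest (seed, package version, per-file MD5 hashes). Identical
#' config and seed reproduce byte-identical tabular outputs.
#'
#' @param config a [pipeline_config()] (or path to a JSON config).
#' @return the manifest, invisibly, as a list; outputs are written under
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(); results <- list()
  stage_on <- function(s) s %in% config$stages

  # --- synthesize ---------------------------------------------------------
  series <- render_card_series(config$optics, config$layout, config$depths,
                               seed = config$seed)
  flash_series <- render_card_series(config$optics, config$layout,
                                     config$depths, flash = TRUE,
                                     seed = config$seed + 1L)
  eff <- config$effort; eff$seed <- config$seed
  sim <- simulate_dive_logs(eff)
  sun <- if (!is.null(config$sun)) config$sun else sim$sun
  laser_img <- render_laser_scene(mm_per_px = config$mm_per_px,
                                  dot_separation_mm = config$dot_separation_mm,
                                  noise_sd = 0.01, seed = config$seed + 2L)
  if (stage_on("synth")) {
    files <- c(files, write_csv_out(series, dir, "card_series.csv"),
               write_dive_logs(sim, dir))
  }

  # --- card fit -----------------------------------------------------------
  model <- NULL
  if (any(c("cardfit", "depthsim", "gamut") %in% config$stages)) {
    model <- fit_attenuation(series, mode = config$interpolation_mode)
    fit_out <- list(k = as.list(model$k),
                    rmse_log = as.list(model$diagnostics$rmse_log),
                    n_excluded = as.list(model$diagnostics$n_excluded),
                    mode = model$mode)
    p <- file.path(dir, "attenuation_model.json")
    jsonlite::write_json(fit_out, p, auto_unbox = TRUE, digits = NA)
    files <- c(files, p)
    results$k <- model$k
  }

  # --- depth simulation ---------------------------------------------------
  if (stage_on("depthsim")) {
    img <- render_card_image(config$optics, config$layout, flash = TRUE,
                             seed = config$seed + 3L)
    simimg <- simulate_at_depth(img, model, depth = config$sim_depth,
                                renormalize = config$renormalize)
    amb <- render_card_image(config$optics, config$layout,
                             depth = config$sim_depth, seed = config$seed + 3L)
    cmp <- compare_simulation(simimg, amb)
    cmp_df <- data.frame(channel = c("R", "G", "B"),
                         mae = cmp$mae, rmse = cmp$rmse)
    files <- c(files, write_csv_out(cmp_df, dir, "depthsim_errors.csv"))
    results$depthsim <- cmp
  }

  # --- gamut --------------------------------------------------------------
  if (stage_on("gamut")) {
    prof <- depth_gamut_profile(series, sim$sightings)
    files <- c(files, write_csv_out(prof, dir, "gamut_profile.csv"))
    results$gamut <- prof
  }

  # --- survey statistics --------------------------------------------------
  if (stage_on("survey")) {
    if (is.null(sun))
      stop("pipeline config error: field 'sun' (sunrise/sunset table) is ",
           "required by the survey stage")
    et <- aggregate_effort(sim$logs, sun)
    files <- c(files, write_csv_out(et$cells, dir, "effort_cells.csv"),
               write_csv_out(et$time_histogram, dir, "time_histogram.csv"),
               write_csv_out(et$depth_histogram, dir, "depth_histogram.csv"))
    hrs <- function(hab = NULL, diel = NULL) {
      sel <- rep(TRUE, nrow(et$cells))
      if (!is.null(hab)) sel <- sel & et$cells$habitat == hab
      if (!is.null(diel)) sel <- sel & et$cells$diel == diel
      sum(et$cells$hours[sel])
    }
    sg <- sim$sightings
    n_day <- sum(sg$diel == "day"); n_night <- sum(sg$diel == "night")
    n_reef <- sum(sg$habitat == "reef"); n_muck <- sum(sg$habitat == "muck")
    t_day <- hrs(diel = "day"); t_night <- hrs(diel = "night")
    t_reef <- hrs(hab = "reef"); t_muck <- hrs(hab = "muck")
    tests <- data.frame(
      contrast = c("day_vs_night", "muck_vs_reef"),
      x1 = c(n_day, n_muck), T1 = c(t_day, t_muck),
      x2 = c(n_night, n_reef), T2 = c(t_night, t_reef),
      expected = c(
        expected_count(n_night, t_night, t_day),
        expected_count(n_reef, t_reef, t_muck)),
      p_value = c(
        exact_poisson_rate_test(n_day, t_day, n_night, t_night,
                                config$alternative)$p.value,
        exact_poisson_rate_test(n_muck, t_muck, n_reef, t_reef,
                                config$alternative)$p.value))
    files <- c(files, write_csv_out(tests, dir, "survey_tests.csv"))
    results$survey <- list(effort = et, tests = tests)
  }

  # --- scale calibration --------------------------------------------------
  if (stage_on("scalebar")) {
    calib <- calibrate_scale(laser_img,
                             separation_mm = config$dot_separation_mm)
    bar <- scalebar_pixels(mm_per_pixel(calib))
    p <- file.path(dir, "scale_calibration.json")
    jsonlite::write_json(
      list(mm_per_px = calib$mm_per_px, distance_px = calib$distance_px,
           separation_mm = calib$separation_mm, method = calib$method,
           scalebar_mm = bar$length_mm, scalebar_px = bar$length_px),
      p, auto_unbox = TRUE, digits = NA)
    files <- c(files, p)
    results$scalebar <- calib
  }

  manifest <- list(
    package = "cuttleoptics",
    version = as.character(utils::packageVersion("cuttleoptics")),
    seed = config$seed,
    stages = config$stages,
    timezone = config$timezone_label,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$results <- results
  invisible(manifest)
}
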