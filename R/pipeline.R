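#' Default pipeline configuration
#'
#' Returns the fully resolved default configuration for [run_pipeline()]:
#' a zero-stress reference phantom (for the cohort SBR reference), a short
#' longitudinal tumor series for tracking, and a two-region registration
#' study for region-wise stress statistics. All stage parameters are
#' explicit so the resolved copy written next to the outputs fully
#' determines the run together with the seed.
#'
#' @return nested config list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    output_dir = "mechanomr_out",
    noise = list(model = "rician", sigma = NULL, background_mean = 100,
                 spot_depth = 10, psf_fwhm_mm = 0.3),
    calibration = list(a1 = 0.1344, b1 = 0.926, a2 = 0.864, b2 = 0.0405),
    phantom = list(n_particles = 30L),
    timeseries = list(enabled = TRUE, n_particles = 20L,
                      sessions = c(0, 1, 2), growth_rate = 0.05,
                      aggregate_fraction = 0.1, stress_profile = "gradual"),
    region_study = list(enabled = TRUE, n_sensors = 50L,
                        vimentin_fraction = 0.5,
                        stress_positive = c(3.5, 2.8),
                        stress_negative = c(7.4, 2.8)),
    detection = list(min_contrast = 0.04, min_separation = 0.7, gap = 5L),
    filter = list(sbr_max = 2.5, area_max_px = 9L, logic = "and"),
    tracking = list(max_displacement = 1, growth_correction = TRUE),
    cpd = list(mode = "nonrigid", w = 0.1, beta = 2, lambda = 3,
               max_iter = 100L, tol = 1e-5),
    regions = list(sampling_radius = 0.3)
  )
}

#' Validate and resolve a pipeline configuration
#'
#' Unknown keys (top level or within a block) are rejected; missing keys are
#' filled from [default_pipeline_config()].
#'
#' @param config partial config list.
#' @return resolved config list.
#' @export
validate_pipeline_config <- function(config) {
  def <- default_pipeline_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  for (k in names(config)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      bad <- setdiff(names(config[[k]]), names(def[[k]]))
      if (length(bad))
        stop(sprintf("unknown key(s) in '%s': %s", k,
                     paste(bad, collapse = ", ")))
      def[[k]][names(config[[k]])] <- config[[k]]
    } else {
      def[[k]] <- config[[k]]
    }
  }
  def
}

pipeline_stage <- function(name, log, expr) {
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  log(sprintf("stage %-10s complete", name))
  res
}

#' Run the full synthetic-to-statistics pipeline
#'
#' Executes simulate, detect, calibrate/invert, track, register and
#' region-statistics stages according to the configuration, writing CSV
#' tables, the fitted/declared calibration model (JSON), a resolved config
#' copy (YAML) and a plain-text report with per-stage record counts and
#' every threshold applied. Identical config and seed give identical
#' outputs.
#'
#' @param config configuration list (see [default_pipeline_config()]);
#'   partial configs are resolved against the defaults.
#' @return (invisibly) a report list: per-stage record counts, region
#'   statistics, trajectory summaries and output paths.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  lines <- character(0)
  log <- function(msg) lines <<- c(lines, msg)
  log(sprintf("mechanomr pipeline, seed %d", cfg$seed))
  noise <- do.call(noise_spec, cfg$noise[!vapply(cfg$noise, is.null,
                                                 logical(1))])
  model <- calibration_model(a1 = cfg$calibration$a1, b1 = cfg$calibration$b1,
                             a2 = cfg$calibration$a2, b2 = cfg$calibration$b2)
  report <- list(seed = cfg$seed, stages = character(0))
  out <- function(f) file.path(cfg$output_dir, f)

  # reference phantom: cohort zero-stress SBR
  ref <- pipeline_stage("simulate", log, generate_calibration_phantom(
    n_particles = cfg$phantom$n_particles, stresses = 0, noise = noise,
    seed = derive_seed(cfg$seed, "phantom"), model = model))
  det_ref <- pipeline_stage("detect", log, detect_particles(
    ref$volume, min_contrast = cfg$detection$min_contrast,
    min_separation = cfg$detection$min_separation, gap = cfg$detection$gap))
  flt_ref <- filter_aggregates(det_ref, cfg$filter$sbr_max,
                               cfg$filter$area_max_px, cfg$filter$logic)
  model$reference_sbr0 <- estimate_reference_sbr0(flt_ref$retained)
  write_detections_csv(det_ref, out("reference_phantom_detections.csv"))
  write_calibration_json(model, out("calibration_model.json"))
  log(sprintf("  reference phantom: %d detections, %d retained, sbr0 = %.4f",
              nrow(det_ref), nrow(flt_ref$retained), model$reference_sbr0))
  log(sprintf("  thresholds: aggregation sbr > %g %s area > %d px; gating %g mm",
              cfg$filter$sbr_max, toupper(cfg$filter$logic),
              cfg$filter$area_max_px, cfg$tracking$max_displacement))
  report$reference <- list(n_detected = nrow(det_ref),
                           n_retained = nrow(flt_ref$retained),
                           reference_sbr0 = model$reference_sbr0)

  # longitudinal tracking arm
  if (isTRUE(cfg$timeseries$enabled)) {
    profile <- loading_profile(cfg$timeseries$stress_profile,
                               duration_h = max(cfg$timeseries$sessions) * 24)
    ts <- pipeline_stage("simulate", log, generate_tumor_timeseries(
      n_particles = cfg$timeseries$n_particles,
      sessions = cfg$timeseries$sessions,
      trajectories = profile,
      growth_rate = cfg$timeseries$growth_rate, noise = noise,
      seed = derive_seed(cfg$seed, "timeseries"),
      aggregate_fraction = cfg$timeseries$aggregate_fraction, model = model))
    dets <- lapply(ts$volumes, function(v) pipeline_stage(
      "detect", log, detect_particles(
        v, min_contrast = cfg$detection$min_contrast,
        min_separation = cfg$detection$min_separation,
        gap = cfg$detection$gap)))
    flts <- lapply(dets, filter_aggregates, sbr_max = cfg$filter$sbr_max,
                   area_max_px = cfg$filter$area_max_px,
                   logic = cfg$filter$logic)
    retained <- lapply(flts, `[[`, "retained")
    n_excluded <- vapply(flts, function(f) nrow(f$excluded), integer(1))
    for (j in seq_along(retained)) {
      retained[[j]]$normalized_signal <- normalize_signal(
        retained[[j]]$sbr, model$reference_sbr0, model)
      write_detections_csv(dets[[j]],
                           out(sprintf("session%02d_detections.csv", j)))
    }
    trajs <- pipeline_stage("track", log, link_particles(
      retained, times = cfg$timeseries$sessions,
      max_displacement = cfg$tracking$max_displacement,
      growth_correction = cfg$tracking$growth_correction))
    trajs <- lapply(trajs, trajectory_stress, model = model)
    tdf <- trajectories_to_df(trajs)
    write_detections_csv(tdf, out("trajectories.csv"))
    log(sprintf("  sessions: %d; detections %s; excluded aggregates %s; trajectories %d",
                length(dets), paste(vapply(dets, nrow, integer(1)),
                                    collapse = "/"),
                paste(n_excluded, collapse = "/"), length(trajs)))
    report$tracking <- list(
      n_detected = vapply(dets, nrow, integer(1)),
      n_excluded = n_excluded,
      n_retained = vapply(retained, nrow, integer(1)),
      n_trajectories = length(trajs),
      true_aggregates = sum(ts$scene$particles$is_aggregate))
  }

  # registration + region statistics arm
  if (isTRUE(cfg$region_study$enabled)) {
    rs <- pipeline_stage("simulate", log, generate_region_study(
      n_sensors = cfg$region_study$n_sensors,
      stress_positive = cfg$region_study$stress_positive,
      stress_negative = cfg$region_study$stress_negative,
      vimentin_fraction = cfg$region_study$vimentin_fraction,
      noise = noise, seed = derive_seed(cfg$seed, "regions"), model = model))
    det_rs <- pipeline_stage("detect", log, detect_particles(
      rs$volume, min_contrast = cfg$detection$min_contrast,
      min_separation = cfg$detection$min_separation,
      gap = cfg$detection$gap))
    flt_rs <- filter_aggregates(det_rs, cfg$filter$sbr_max,
                                cfg$filter$area_max_px, cfg$filter$logic)
    keep <- flt_rs$retained
    keep$normalized_signal <- normalize_signal(keep$sbr, model$reference_sbr0,
                                               model)
    S_est <- invert_signal(model, keep$normalized_signal, clamp = TRUE,
                           clamp_slack = Inf)
    reg <- pipeline_stage("register", log, register_cpd(
      rs$source, rs$target, mode = cfg$cpd$mode, w = cfg$cpd$w,
      beta = cfg$cpd$beta, lambda = cfg$cpd$lambda,
      max_iter = cfg$cpd$max_iter, tol = cfg$cpd$tol))
    mapped <- transform_points(reg, as.matrix(keep[, c("z_mm", "y_mm",
                                                       "x_mm")]))
    assign <- assign_regions(mapped, rs$labels,
                             sampling_radius = cfg$regions$sampling_radius)
    stats <- region_stats(assign, as.numeric(S_est))
    assign$stress_kPa <- as.numeric(S_est)
    write_detections_csv(assign, out("region_assignments.csv"))
    write_detections_csv(stats$table, out("region_stats.csv"))
    log(sprintf("  region study: %d detections, %d retained; groups n=%d/%d, means %.2f/%.2f kPa",
                nrow(det_rs), nrow(keep), stats$table$n[1], stats$table$n[2],
                stats$table$mean_kPa[1], stats$table$mean_kPa[2]))
    report$regions <- list(n_detected = nrow(det_rs),
                           n_retained = nrow(keep),
                           stats = stats,
                           cpd_converged = reg$converged)
  }

  write_pipeline_config(cfg, out("resolved_config.yaml"))
  writeLines(lines, out("report.txt"))
  jsonlite::write_json(report[setdiff(names(report), "stages")],
                       out("summary.json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  report$report_lines <- lines
  report$output_dir <- cfg$output_dir
  invisible(report)
}
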