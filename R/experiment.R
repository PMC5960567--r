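#' Configuration for the in silico evaluation
#'
#' Mirrors the in silico study protocol: noise-free stereo silhouettes of the
#' synthetic stem are rendered at each pixel spacing, initial poses are drawn
#' uniformly within the given per-axis bounds, and each trial is registered
#' with the five-stage coarse-to-fine schedule.
#'
#' @param pixel_spacings detector pixel sizes to evaluate, mm/px.
#' @param bounds maximal initial per-axis offsets, mm and degrees.
#' @param trials registrations per (spacing, bound) cell, >= 1.
#' @param seed master seed; every random draw derives from it.
#' @param mode `"binary"` or `"grayscale"` radiographs.
#' @param dropout if `TRUE`, apply ball-head drop-out masks in every trial.
#' @param dropout_fraction masked fraction of the lit area when `dropout`.
#' @param noise_sigma grayscale intensity noise SD.
#' @param angle_deg stereo angle, degrees.
#' @param margin_mm ROI margin in millimetres (converted to px per spacing);
#'   sized to exceed the largest initial-pose silhouette displacement.
#' @param threshold grayscale segmentation threshold.
#' @param schedule difference-spacing schedule, mm-or-degrees.
#' @param mesh_seed seed of the synthetic stem.
#' @return a list of class `insilico_config`.
#' @export
insilico_config <- function(pixel_spacings = c(0.5, 0.35, 0.143),
                            bounds = 5, trials = 20L, seed = 1L,
                            mode = c("binary", "grayscale"),
                            dropout = FALSE, dropout_fraction = 0.15,
                            noise_sigma = 0, angle_deg = 90,
                            margin_mm = 16, threshold = 0.5,
                            schedule = c(10, 1, 0.1, 0.01, 0.001),
                            mesh_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(trials >= 1L, all(bounds >= 0), all(pixel_spacings > 0))
  structure(list(pixel_spacings = pixel_spacings, bounds = bounds,
                 trials = as.integer(trials), seed = as.integer(seed),
                 mode = mode, dropout = dropout,
                 dropout_fraction = dropout_fraction,
                 noise_sigma = noise_sigma, angle_deg = angle_deg,
                 margin_mm = margin_mm, threshold = threshold,
                 schedule = schedule, mesh_seed = as.integer(mesh_seed)),
            class = "insilico_config")
}

#' Run the in silico registration experiment
#'
#' For every (pixel spacing, initial-error bound) cell: simulate the stereo
#' radiographs at the ground-truth pose, draw `trials` random initial poses,
#' register each, and record per-axis absolute pose errors, iteration counts
#' and the residual relative NOA. Trials that hit the iteration cap are
#' recorded with `converged = FALSE`, never dropped.
#'
#' @param config an [insilico_config()].
#' @param progress print one line per completed trial.
#' @return a tibble of class `insilico_experiment`, one row per trial, with
#'   absolute errors `err_rx`..`err_tz` (degrees / mm) and
#'   `relative_noa_pct`.
#' @export
run_insilico_experiment <- function(config = insilico_config(),
                                    progress = FALSE) {
  stopifnot(inherits(config, "insilico_config"))
  rows <- list()
  cell <- 0L
  for (spacing in config$pixel_spacings) {
    scene <- phantom_scene(config$mesh_seed, pixel_spacing = spacing,
                           angle_deg = config$angle_deg)
    truth <- scene$ground_truth_pose
    margin_px <- as.integer(ceiling(config$margin_mm / spacing))
    dr <- list(
      ap = simulate_radiograph(scene, "ap", config$mode,
                               config$noise_sigma, config$seed + 11L),
      lat = simulate_radiograph(scene, "lat", config$mode,
                                config$noise_sigma, config$seed + 12L))
    masks <- list(ap = NULL, lat = NULL)
    if (config$dropout) {
      if (config$mode == "grayscale") {
        sc <- make_dropout_scenario(scene, config$dropout_fraction,
                                    radiographs = dr)
        dr <- sc$radiographs
        masks <- sc$masks
      } else {
        masks <- make_dropout_scenario(scene, config$dropout_fraction)$masks
      }
    }
    for (bound in config$bounds) {
      cell <- cell + 1L
      poses <- sample_initial_poses(truth, bound, config$trials,
                                    seed = config$seed + 97L * cell)
      for (k in seq_len(config$trials)) {
        fit <- noa_register(
          list(list(dr = dr$ap, camera = scene$cameras$ap, mask = masks$ap),
               list(dr = dr$lat, camera = scene$cameras$lat,
                    mask = masks$lat)),
          scene$mesh, poses[[k]], schedule = config$schedule,
          margin_px = margin_px, threshold = config$threshold)
        err <- pose_error(fit$pose, truth)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          pixel_spacing = spacing, bound = bound, mode = config$mode,
          dropout = config$dropout, trial = k,
          converged = fit$converged,
          iterations = fit$total_iterations,
          noa = fit$noa,
          relative_noa_pct = 100 * fit$relative_noa,
          err_rx = err[["rx"]], err_ry = err[["ry"]], err_rz = err[["rz"]],
          err_tx = err[["tx"]], err_ty = err[["ty"]], err_tz = err[["tz"]],
          wall_time = fit$wall_time)
        if (progress)
          message(sprintf(
            "spacing %.3g bound %.3g trial %d: |dry| %.2e deg, NOA %.4g, %d it",
            spacing, bound, k, err[["ry"]], fit$noa, fit$total_iterations))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("insilico_experiment", class(out))
  attr(out, "config") <- config
  out
}

#' Summarize an in silico experiment per cell
#'
#' Per (spacing, bound, mode): mean and SD of the absolute per-axis errors,
#' mean iteration count and mean relative NOA in percent — the columns of
#' the standard accuracy table.
#'
#' @param results an [run_insilico_experiment()] tibble.
#' @return a tibble, one row per cell.
#' @export
summarize_insilico <- function(results) {
  dplyr::summarise(
    dplyr::group_by(results, .data$pixel_spacing, .data$bound, .data$mode),
    dplyr::across(dplyr::starts_with("err_"),
                  list(mean = mean, sd = stats::sd)),
    iterations = mean(.data$iterations),
    relative_noa_pct = mean(.data$relative_noa_pct),
    n_trials = dplyr::n(),
    n_converged = sum(.data$converged),
    .groups = "drop")
}

#' Write experiment results as CSV
#' @param results a results tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_experiment_csv <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}
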