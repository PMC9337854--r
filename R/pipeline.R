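#' Pick the turning concentration that yields a target straightness
#'
#' Runs [calibrate_straightness()] on a kappa grid and interpolates the
#' monotone straightness curve (linearly in `log2(kappa + 1)`) at the
#' requested target.
#'
#' @param motion a [motion_spec()] (its kappa is ignored).
#' @param target straightness in (0, 1).
#' @param kappa_grid grid to calibrate over.
#' @param n_tracks simulated tracks per grid point.
#' @param seed integer seed.
#' @return list `kappa` (interpolated) and `calibration` (the grid table).
#' @export
kappa_for_straightness <- function(motion, target,
                                   kappa_grid = c(0, 1, 2, 4, 8, 16, 32, 64),
                                   n_tracks = 400L, seed = 1L) {
  cal <- calibrate_straightness(motion, kappa_grid, n_tracks, seed)
  s <- cal$straightness
  if (target <= min(s) || target >= max(s))
    stop("target straightness ", target, " outside calibrated range [",
         round(min(s), 3), ", ", round(max(s), 3), "]")
  x <- log2(cal$kappa + 1)
  kap <- 2^stats::approx(s, x, xout = target, ties = "ordered")$y - 1
  list(kappa = kap, calibration = cal)
}

#' Simulate, render, detect, link and measure one migration cohort
#'
#' The full closed loop on synthetic organoids: calibrates the motion
#' model to a target straightness, renders time-lapse movies of cells
#' migrating out of a VZ shell (depth attenuation with the surface power
#' raised to compensate, as done in practice, plus shot and read noise),
#' then runs the detection / linking / metric pipeline and compares the
#' recovered group statistics with the generator's calibrated targets.
#'
#' @param mean_speed,speed_sd um/hr of the motion model.
#' @param target_straightness straightness the cohort is calibrated to.
#' @param radial_bias outward bias of the motion model.
#' @param n_movies rendered movies (fields of view).
#' @param n_cells cells per movie.
#' @param n_frames timepoints per movie (20-min interval).
#' @param seed integer seed.
#' @param voxel_size rendering voxel size `(z,y,x)` um.
#' @return list: `target` (speed, straightness after calibration),
#'   `recovered` (from detected+linked tracks), `truth` (metrics of
#'   ground-truth tracks), `link_accuracy`, `n_tracks`, `kappa`.
#' @export
migration_cohort_experiment <- function(mean_speed, speed_sd = 4,
                                        target_straightness = 0.88,
                                        radial_bias = 0.2,
                                        n_movies = 9L, n_cells = 25L,
                                        n_frames = 19L, seed = 1L,
                                        voxel_size = c(5, 4, 4)) {
  motion <- motion_spec(n_cells = n_cells, frame_interval = 20,
                        n_frames = n_frames, mean_speed = mean_speed,
                        speed_sd = speed_sd, turning_concentration = 1,
                        radial_bias = radial_bias)
  calib <- kappa_for_straightness(motion, target_straightness,
                                  n_tracks = 400L, seed = seed)
  motion$turning_concentration <- calib$kappa
  # the calibrated target is the expected straightness at the chosen kappa
  target_s <- calibrate_straightness(motion, calib$kappa, n_tracks = 800L,
                                     seed = seed + 1L)$straightness

  spec <- phantom_spec(organoid_radius = 180, n_ventricles = 1,
                       ventricle_radius_range = c(20, 20),
                       vz_shell_thickness = 20, cp_soma_density = 0,
                       soma_radius = 5, voxel_size = voxel_size,
                       margin_um = 15,
                       ventricle_centers = matrix(0, 1, 3))
  # power raised with depth to hold delivered excitation constant
  optics <- optics_spec(
    extinction_length = 150,
    surface_power_by_depth = data.frame(
      z_um = seq(0, 500, 25), power_mW = exp(seq(0, 500, 25) / 150)),
    shot_noise_scale = 0.5, read_noise_sd = 2)

  est <- list(); truth <- list()
  n_correct <- 0L; n_links <- 0L
  for (i in seq_len(n_movies)) {
    tl <- generate_timelapse(spec, motion, optics, seed = seed + 1000L * i)
    spots <- detect_spots(tl$movie, sigma_range = c(2.5, 4),
                          threshold = 0.25, n_scales = 2L)
    tracks <- link_tracks(spots, max_step = 20, max_gap_frames = 1L,
                          min_frames = 4L)
    acc <- link_accuracy(tracks, tl$tracks, match_radius = 6)
    n_correct <- n_correct + acc$correct
    n_links <- n_links + acc$total
    est[[i]] <- track_table_metrics(tracks)
    truth[[i]] <- track_table_metrics(tl$tracks)
  }
  est <- do.call(rbind, est)
  truth <- do.call(rbind, truth)
  list(target = list(mean_speed = mean_speed,
                     straightness = target_s),
       recovered = list(mean_speed = mean(est$mean_speed_um_hr),
                        straightness = mean(est$straightness, na.rm = TRUE),
                        displacement = mean(est$displacement_um)),
       truth = list(mean_speed = mean(truth$mean_speed_um_hr),
                    straightness = mean(truth$straightness, na.rm = TRUE),
                    displacement = mean(truth$displacement_um)),
       link_accuracy = n_correct / n_links,
       n_tracks = nrow(est), kappa = calib$kappa,
       metrics = est)
}

#' Extinction-length recovery experiment on uniform phantoms
#'
#' Renders uniform stacks attenuated at known extinction lengths,
#' optionally with Poisson shot noise, and refits each with
#' [extract_depth_profile()] + [fit_extinction()].
#'
#' @param lengths true extinction lengths, um.
#' @param n_seeds noise replicates per length.
#' @param shot_noise_scale photons per signal unit (0 = noiseless);
#'   surface intensity is 100 signal units, so a scale of 1 gives 100
#'   expected photons per voxel in the brightest slice.
#' @param seed integer seed.
#' @param depth_um,z_step_um stack geometry.
#' @return data.frame `true_length, seed, fitted_length, rel_error`.
#' @export
extinction_recovery_experiment <- function(lengths = c(100, 150, 200),
                                           n_seeds = 1L,
                                           shot_noise_scale = 0,
                                           seed = 1L, depth_um = 300,
                                           z_step_um = 2) {
  nz <- round(depth_um / z_step_um) + 1L
  vol <- image_volume(array(100, c(nz, 12, 12)), c(z_step_um, 2, 2))
  rows <- list()
  for (l in lengths) {
    optics <- optics_spec(l, 1, shot_noise_scale = shot_noise_scale)
    att <- apply_attenuation(vol, optics)
    for (s in seq_len(n_seeds)) {
      img <- if (shot_noise_scale > 0)
        add_noise(att, optics, seed = seed + 131L * s + round(l)) else att
      prof <- extract_depth_profile(img, 1, summary = "mean")
      fit <- fit_extinction(prof, 3)
      rows[[length(rows) + 1L]] <- data.frame(
        true_length = l, seed = s, fitted_length = fit$extinction_length,
        rel_error = abs(fit$extinction_length - l) / l)
    }
  }
  do.call(rbind, rows)
}
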