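small_spec <- function(...) {
  args <- utils::modifyList(
    list(organoid_radius = 60, n_ventricles = 1,
         ventricle_radius_range = c(15, 15), vz_shell_thickness = 20,
         cp_soma_density = 2e4, voxel_size = c(2, 2, 2),
         ventricle_centers = matrix(0, 1, 3)),
    list(...))
  do.call(phantom_spec, args)
}

test_that("degenerate geometry: no ventricles gives a uniform CP ball", {
  sp <- phantom_spec(organoid_radius = 50, n_ventricles = 0,
                     cp_soma_density = 0, voxel_size = c(2, 2, 2))
  ph <- generate_phantom(sp, seed = 1)
  expect_true(all(ph$labels$labels == 0L))
  vals <- unique(as.vector(ph$image$data))
  expect_setequal(vals, c(0, sp$cp_intensity))
})

test_that("ground-truth shell volume matches the analytic shell", {
  sp <- small_spec(cp_soma_density = 0)
  ph <- generate_phantom(sp, seed = 1)
  shell_vox <- sum(ph$labels$labels == 1L)
  analytic <- 4 / 3 * pi * (35^3 - 15^3)
  expect_lt(abs(shell_vox * 8 - analytic) / analytic, 0.05)
})

test_that("fixed geometry: seeds change somata only; same seed identical", {
  sp <- small_spec()
  a <- generate_phantom(sp, seed = 1)
  b <- generate_phantom(sp, seed = 2)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_false(identical(a$somata, b$somata))
  expect_identical(generate_phantom(sp, seed = 1)$image$data, a$image$data)
})

test_that("impossible geometry raises a parameter error", {
  expect_error(phantom_spec(organoid_radius = 30,
                            ventricle_radius_range = c(20, 25),
                            vz_shell_thickness = 15),
               "fit inside")
  sp <- phantom_spec(organoid_radius = 70, n_ventricles = 8,
                     ventricle_radius_range = c(25, 30),
                     vz_shell_thickness = 15, voxel_size = c(4, 4, 4))
  expect_error(generate_phantom(sp, seed = 1), "could not place")
})

test_that("volumes are non-negative and share geometry with labels", {
  ph <- generate_phantom(small_spec(), seed = 3)
  expect_true(all(ph$image$data >= 0))
  expect_identical(dim(ph$image$data), dim(ph$labels$labels))
  expect_identical(ph$image$voxel_size, ph$labels$voxel_size)
  opt <- optics_spec(120, 2, shot_noise_scale = 1, read_noise_sd = 3)
  noisy <- add_noise(apply_attenuation(ph$image, opt), opt, seed = 5)
  expect_true(all(noisy$data >= 0))
})

test_that("attenuation limits: no decay, closed-form e^-3, invertibility", {
  vol <- image_volume(array(7, c(76, 6, 6)), c(2, 2, 2))
  ident <- apply_attenuation(vol, optics_spec(Inf, 3))
  expect_equal(ident$data, vol$data)

  att <- apply_attenuation(vol, optics_spec(150, 3))
  # z = 150 um is slice index 76 (2-um steps): scale = e^-3 of surface
  expect_equal(att$data[76, 1, 1] / att$data[1, 1, 1], exp(-3),
               tolerance = 1e-12)

  # power ratio enters as (P(z)/P(0))^n
  pw <- data.frame(z_um = c(0, 150), power_mW = c(1, 2))
  att2 <- apply_attenuation(vol, optics_spec(150, pw))
  expect_equal(att2$data[76, 1, 1] / att2$data[1, 1, 1], 2^3 * exp(-3),
               tolerance = 1e-12)
})

test_that("attenuation refuses to extrapolate the power log", {
  vol <- image_volume(array(1, c(76, 4, 4)), c(2, 2, 2))
  pw <- data.frame(z_um = c(0, 100), power_mW = c(1, 2))
  expect_error(apply_attenuation(vol, optics_spec(150, pw)),
               "does not cover")
})

test_that("attenuation/fit round trip recovers the extinction length", {
  vol <- image_volume(array(50, c(76, 8, 8)), c(2, 2, 2))
  att <- apply_attenuation(vol, optics_spec(150, 1.2))
  prof <- extract_depth_profile(att, 1.2, summary = "mean")
  fit <- fit_extinction(prof, 3)
  expect_lt(abs(fit$extinction_length - 150) / 150, 0.01)
})

test_that("deterministic motion limit: straight radial lines", {
  m <- motion_spec(n_cells = 3, frame_interval = 20, n_frames = 11,
                   mean_speed = 24, speed_sd = 0,
                   turning_concentration = Inf, radial_bias = 1)
  starts <- rbind(c(0, 0, 30), c(0, 25, 0), c(10, 10, 10))
  tab <- simulate_tracks(m, starts, seed = 8)
  mets <- track_table_metrics(tab)
  expect_equal(mets$straightness, rep(1, 3))
  expect_equal(mets$mean_speed_um_hr, rep(24, 3))
  # every step is exactly 8 um (24 um/hr x 1/3 hr)
  one <- tab[tab$track_id == 1, ]
  steps <- sqrt(diff(one$z_um)^2 + diff(one$y_um)^2 + diff(one$x_um)^2)
  expect_equal(steps, rep(8, 10))
})

test_that("uniform directions give low straightness over long walks", {
  m <- motion_spec(n_cells = 100, frame_interval = 20, n_frames = 101,
                   mean_speed = 20, speed_sd = 0,
                   turning_concentration = 0, radial_bias = 0)
  starts <- matrix(rep(c(0, 0, 50), 100), ncol = 3, byrow = TRUE)
  tab <- simulate_tracks(m, starts, seed = 9)
  mets <- track_table_metrics(tab)
  expect_lt(mean(mets$straightness), 0.2)
})

test_that("two-step kappa=0 straightness matches the brute-force oracle", {
  # equal step lengths: straightness = |u1 + u2| / 2 for uniform unit
  # vectors; brute-force Monte-Carlo oracle (closed form 2/3)
  with_seed(21, {
    n <- 20000
    u1 <- matrix(rnorm(3 * n), n); u1 <- u1 / sqrt(rowSums(u1^2))
    u2 <- matrix(rnorm(3 * n), n); u2 <- u2 / sqrt(rowSums(u2^2))
    oracle <- mean(sqrt(rowSums((u1 + u2)^2)) / 2)
  })
  m <- motion_spec(n_cells = 1, frame_interval = 20, n_frames = 3,
                   mean_speed = 20, speed_sd = 0,
                   turning_concentration = 0, radial_bias = 0)
  cal <- calibrate_straightness(m, kappa_grid = 0, n_tracks = 4000,
                                seed = 5)
  expect_equal(cal$straightness, oracle, tolerance = 0.02)
  expect_equal(oracle, 2 / 3, tolerance = 0.01)
})

test_that("calibration is monotone in kappa and exact at the Inf limit", {
  m <- motion_spec(n_frames = 19, mean_speed = 23, speed_sd = 4,
                   radial_bias = 0)
  cal <- calibrate_straightness(m, c(0, 1, 4, 16, Inf), n_tracks = 300,
                                seed = 3)
  expect_true(all(diff(cal$straightness) >= 0))
  expect_equal(cal$straightness[cal$kappa == Inf], 1)
  expect_warning(calibrate_straightness(m, 1, n_tracks = 50, seed = 1),
                 "unstable")
})

test_that("ground-truth track statistics match calibrated targets", {
  m <- motion_spec(n_frames = 19, mean_speed = 23, speed_sd = 4,
                   turning_concentration = 8, radial_bias = 0.2)
  cal <- calibrate_straightness(m, 8, n_tracks = 400, seed = 13)
  starts <- matrix(rep(c(0, 0, 40), 250), ncol = 3, byrow = TRUE)
  tab <- simulate_tracks(m, starts, seed = 14)
  mets <- track_table_metrics(tab)
  expect_equal(mean(mets$straightness), cal$straightness, tolerance = 0.03)
  expect_equal(mean(mets$mean_speed_um_hr), 23, tolerance = 0.03)
})

test_that("cells leaving the volume are truncated and flagged", {
  sp <- small_spec(cp_soma_density = 0)
  m <- motion_spec(n_cells = 6, frame_interval = 20, n_frames = 40,
                   mean_speed = 60, speed_sd = 0,
                   turning_concentration = Inf, radial_bias = 1)
  tl <- generate_timelapse(sp, m, optics = NULL, seed = 2)
  trunc <- attr(tl$tracks, "truncated")
  expect_length(trunc, 6)
  expect_true(any(trunc))  # 20 um/frame outward walk must exit a 60-um ball
  # truncated tracks are shorter but present
  counts <- table(tl$tracks$track_id)
  expect_length(counts, 6)
  expect_true(all(counts[trunc] < 40))
})

test_that("rendered time-lapse is reproducible and consistent with truth", {
  sp <- small_spec(cp_soma_density = 0, voxel_size = c(4, 4, 4))
  m <- motion_spec(n_cells = 4, n_frames = 5, mean_speed = 20, speed_sd = 2)
  a <- generate_timelapse(sp, m, seed = 6)
  b <- generate_timelapse(sp, m, seed = 6)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$tracks, b$tracks)
  expect_equal(dim(a$movie$data)[1], 5)
  # soma blobs brighten the rendered frame at the track positions
  p1 <- a$tracks[a$tracks$frame == 0 & a$tracks$track_id == 1, ]
  vox <- round(c(p1$z_um, p1$y_um, p1$x_um) / 4) + 1
  expect_gt(a$movie$data[1, vox[1], vox[2], vox[3]],
            max(a$phantom$image$data[vox[1], vox[2], vox[3]], 1))
})
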