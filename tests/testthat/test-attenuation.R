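test_that("depth profile of a uniform stack is constant; summaries agree", {
  vol <- image_volume(array(5, c(20, 10, 10)), c(2, 2, 2))
  prof <- extract_depth_profile(vol, 1, summary = "mean")
  expect_equal(nrow(prof), 20)
  expect_true(all(prof$signal == 5))
  expect_true(all(prof$power_mW == 1))
  # top_fraction = 1 with mean_top_fraction equals plain mean
  with_seed(7, vol2 <- image_volume(array(runif(20 * 100), c(20, 10, 10)),
                                    c(2, 2, 2)))
  p_mean <- extract_depth_profile(vol2, 1, summary = "mean")
  p_top1 <- extract_depth_profile(vol2, 1, summary = "mean_top_fraction",
                                  top_fraction = 1)
  expect_equal(p_top1$signal, p_mean$signal)
})

test_that("profile of an attenuated uniform phantom follows exp(-3z/l)", {
  vol <- image_volume(array(100, c(40, 8, 8)), c(2, 2, 2))
  att <- apply_attenuation(vol, optics_spec(150, 1))
  prof <- extract_depth_profile(att, 1, summary = "mean")
  expect_equal(prof$signal / 100, exp(-3 * prof$z_um / 150),
               tolerance = 1e-10)
})

test_that("masked profiles use in-mask voxels and exclude empty slices", {
  arr <- array(1, c(10, 6, 6))
  arr[, 1:3, ] <- 9
  vol <- image_volume(arr, c(2, 2, 2))
  lab <- array(0L, c(10, 6, 6))
  lab[1:8, 1:3, ] <- 1L  # slices 9-10 empty in mask
  mask <- label_volume(lab, c(2, 2, 2))
  expect_warning(
    prof <- extract_depth_profile(vol, 1, summary = "mean", mask = mask),
    "excluded")
  expect_equal(nrow(prof), 8)
  expect_true(all(prof$signal == 9))
  expect_error(extract_depth_profile(vol, -1), "power")
})

test_that("fit_extinction inverts the slope and flags non-decay", {
  # constant signal: slope 0, non-physical, infinity sentinel
  flat <- data.frame(z_um = seq(0, 100, 10), signal = 3, power_mW = 1)
  f0 <- fit_extinction(flat)
  expect_true(f0$non_physical)
  expect_equal(f0$extinction_length, Inf)

  # exact synthetic decay: l = 150 recovered exactly
  z <- seq(0, 300, 5)
  prof <- data.frame(z_um = z, signal = exp(-3 * z / 150), power_mW = 1)
  f1 <- fit_extinction(prof, 3)
  expect_equal(f1$extinction_length, 150, tolerance = 1e-9)
  expect_equal(f1$r_squared, 1, tolerance = 1e-9)

  # slope -3/162.5 -> 162.5 um (a representative wild-type organoid value)
  slope <- -3 / 162.5
  prof2 <- data.frame(z_um = z, signal = exp(slope * z), power_mW = 1)
  f2 <- fit_extinction(prof2, 3)
  expect_equal(f2$slope, slope, tolerance = 1e-10)
  expect_equal(f2$extinction_length, 162.5, tolerance = 1e-6)

  expect_error(fit_extinction(prof[1:2, ]), "at least 3")
  expect_error(fit_extinction(transform(prof, signal = 0)),
               "no positive signal")
})

test_that("z_window restricts the fitted range", {
  z <- seq(0, 300, 5)
  sig <- exp(-3 * z / 150)
  sig[z < 30] <- 5  # surface interface peak
  prof <- data.frame(z_um = z, signal = sig, power_mW = 1)
  fit_all <- fit_extinction(prof, 3)
  fit_win <- fit_extinction(prof, 3, z_window = c(30, 300))
  expect_equal(fit_win$extinction_length, 150, tolerance = 1e-9)
  expect_gt(abs(fit_all$extinction_length - 150), 1)
  expect_equal(fit_win$z_range_used, c(30, 300))
})

test_that("scale and power invariances hold", {
  with_seed(31, {
    z <- seq(0, 250, 10)
    sig <- exp(-3 * z / 180) * exp(rnorm(length(z), 0, 0.05))
    prof <- data.frame(z_um = z, signal = sig, power_mW = 1.5)
  })
  base <- fit_extinction(prof, 3)
  scaled <- fit_extinction(transform(prof, signal = signal * 37), 3)
  expect_equal(scaled$slope, base$slope, tolerance = 1e-12)
  expect_equal(scaled$extinction_length, base$extinction_length,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(scaled$intercept, base$intercept)))
  repow <- fit_extinction(transform(prof, power_mW = power_mW * 2.5), 3)
  expect_equal(repow$extinction_length, base$extinction_length,
               tolerance = 1e-12)
})

test_that("OLS slope agrees with an independent numerical minimizer", {
  with_seed(17, {
    for (k in 1:3) {
      z <- sort(runif(12, 0, 200))
      sig <- exp(-3 * z / runif(1, 100, 200)) * exp(rnorm(12, 0, 0.1))
      prof <- data.frame(z_um = z, signal = sig, power_mW = 1)
      fit <- fit_extinction(prof, 3)
      sse <- function(p) sum((log(sig) - p[1] - p[2] * z)^2)
      opt <- optim(c(0, -0.01), sse, method = "BFGS",
                   control = list(reltol = 1e-14))
      expect_equal(fit$slope, opt$par[2], tolerance = 1e-6)
    }
  })
})

test_that("compare_extinction summarizes groups and rejects n = 1", {
  z <- seq(0, 300, 10)
  mkfit <- function(l) fit_extinction(
    data.frame(z_um = z, signal = exp(-3 * z / l), power_mW = 1), 3)
  wt <- lapply(c(150, 155, 149, 152), mkfit)
  res_id <- compare_extinction(list(a = wt, b = wt))
  expect_equal(res_id$tests$p_pooled, 1)
  mt <- lapply(c(120, 126, 131, 124), mkfit)
  res <- compare_extinction(list(WT = wt, MT = mt))
  expect_lt(res$tests$p_pooled, 0.001)
  expect_error(compare_extinction(list(a = wt, b = mt[1])), ">= 2")
})
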