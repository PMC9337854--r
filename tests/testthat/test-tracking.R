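render_somata_frame <- function(points_um, dim3, voxel, intensity = 300,
                                soma_radius = 5) {
  arr <- othg:::render_somata(array(0, dim3), points_um, voxel,
                              soma_radius, intensity)
  arr
}

test_that("blank volumes yield an empty spot table", {
  vol <- image_volume(array(0, c(10, 20, 20)), c(2, 2, 2))
  spots <- detect_spots(vol)
  expect_equal(nrow(spots), 0)
})

test_that("isolated somata are detected with subvoxel accuracy", {
  with_seed(23, {
    dim3 <- c(30, 60, 60); voxel <- c(4, 2, 2)
    n <- 20
    pts <- cbind(runif(n, 20, 96), runif(n, 12, 104), runif(n, 12, 104))
    # enforce >= 18 um separation so blobs are isolated
    keep <- rep(TRUE, n)
    for (i in 2:n)
      if (min(sqrt(rowSums(sweep(pts[seq_len(i - 1), , drop = FALSE], 2,
                                 pts[i, ])^2))) < 18) keep[i] <- FALSE
    pts <- pts[keep, , drop = FALSE]
  })
  arr <- render_somata_frame(pts, dim3, voxel)
  vol <- image_volume(arr, voxel)
  spots <- detect_spots(vol, sigma_range = c(2, 4), threshold = 0.2)
  expect_gte(nrow(spots), nrow(pts) - 1)
  # match each truth point to nearest detection
  err <- vapply(seq_len(nrow(pts)), function(i) {
    dd <- sqrt((spots$z_um - pts[i, 1])^2 + (spots$y_um - pts[i, 2])^2 +
               (spots$x_um - pts[i, 3])^2)
    min(dd)
  }, numeric(1))
  expect_lt(sqrt(mean(err^2)), max(voxel))  # < 1 voxel RMS

  # relative threshold: doubling intensity changes nothing
  spots2 <- detect_spots(image_volume(arr * 2, voxel),
                         sigma_range = c(2, 4), threshold = 0.2)
  expect_equal(spots2[, c("z_um", "y_um", "x_um")],
               spots[, c("z_um", "y_um", "x_um")])
})

test_that("two well-separated parallel cells give two clean tracks", {
  mk <- function(y0) data.frame(frame = 0:9, t_min = (0:9) * 20,
                                z_um = 50, y_um = y0, x_um = 10 + (0:9) * 5)
  spots <- rbind(mk(40), mk(160))
  tracks <- link_tracks(spots, max_step = 20, min_frames = 4)
  expect_length(tracks, 2)
  ys <- sort(vapply(tracks, function(t) t$points$y_um[1], numeric(1)))
  expect_equal(ys, c(40, 160))
  expect_true(all(vapply(tracks, function(t) length(t$gaps) == 0,
                         logical(1))))
})

test_that("gap closing joins a track across one missing frame", {
  spots <- data.frame(frame = c(0, 2, 3), t_min = c(0, 40, 60),
                      z_um = c(10, 14, 16), y_um = 20, x_um = 20)
  tracks <- link_tracks(spots, max_step = 10, max_gap_frames = 1,
                        min_frames = 2)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$gaps, 1L)
  # without gap closing the fragment is split
  split <- link_tracks(spots, max_step = 10, max_gap_frames = 0,
                       min_frames = 1)
  expect_length(split, 2)
})

test_that("track metrics: straight line, 3-4-5 oracle, loop, stationary", {
  straight <- data.frame(t_min = (0:10) * 20, z_um = 0, y_um = 0,
                         x_um = (0:10) * 8)
  m <- compute_metrics(straight)
  expect_equal(m$displacement_um, 80)
  expect_equal(m$path_length_um, 80)
  expect_equal(m$straightness, 1)
  expect_equal(m$mean_speed_um_hr, 24)

  tri <- data.frame(t_min = c(0, 20, 40), z_um = c(0, 3, 3),
                    y_um = c(0, 4, 4), x_um = c(0, 0, 5))
  m2 <- compute_metrics(tri)
  expect_equal(m2$path_length_um, 10)
  expect_equal(m2$displacement_um, sqrt(50))
  expect_equal(m2$straightness, sqrt(50) / 10)
  expect_equal(m2$duration_hr, 2 / 3)
  expect_equal(m2$mean_speed_um_hr, 15)
  expect_equal(m2$instantaneous_speed_um_hr, c(15, 15))

  loop <- data.frame(t_min = (0:4) * 20, z_um = c(0, 0, 5, 5, 0),
                     y_um = c(0, 5, 5, 0, 0), x_um = 0)
  expect_equal(compute_metrics(loop)$displacement_um, 0)
  expect_equal(compute_metrics(loop)$straightness, 0)

  still <- data.frame(t_min = c(0, 20, 40), z_um = 1, y_um = 2, x_um = 3)
  expect_true(is.na(compute_metrics(still)$straightness))
})

test_that("metrics are invariant under rigid rotation and translation", {
  with_seed(41, {
    pts <- cbind(cumsum(rnorm(8)), cumsum(rnorm(8)), cumsum(rnorm(8)))
    tr <- data.frame(t_min = (0:7) * 20, z_um = pts[, 1], y_um = pts[, 2],
                     x_um = pts[, 3])
    m0 <- compute_metrics(tr)
    th <- runif(1, 0, 2 * pi)
    R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
    rot <- sweep(pts %*% t(R), 2, c(5, -3, 11), `+`)
    m1 <- compute_metrics(data.frame(t_min = (0:7) * 20, z_um = rot[, 1],
                                     y_um = rot[, 2], x_um = rot[, 3]))
    expect_equal(m1$displacement_um, m0$displacement_um)
    expect_equal(m1$path_length_um, m0$path_length_um)
    expect_equal(m1$straightness, m0$straightness)
  })
})

test_that("temporal subsampling never increases path length", {
  with_seed(43, {
    pts <- cbind(cumsum(rnorm(21, 0, 3)), cumsum(rnorm(21, 0, 3)),
                 cumsum(rnorm(21, 0, 3)))
  })
  tr <- data.frame(t_min = (0:20) * 20, z_um = pts[, 1], y_um = pts[, 2],
                   x_um = pts[, 3])
  full <- compute_metrics(tr)
  sub <- compute_metrics(tr[seq(1, 21, 2), ])
  expect_lte(sub$path_length_um, full$path_length_um)
  expect_equal(sub$displacement_um, full$displacement_um)
  # straight tracks are unchanged by subsampling
  straight <- data.frame(t_min = (0:10) * 20, z_um = (0:10) * 2,
                         y_um = (0:10) * 3, x_um = (0:10) * 6)
  expect_equal(compute_metrics(straight[c(1, 4, 8, 11), ])$straightness, 1)
  expect_equal(compute_metrics(straight[c(1, 4, 8, 11), ])$displacement_um,
               compute_metrics(straight)$displacement_um)
})

test_that("straightness is 1 iff monotone collinear", {
  collinear_back <- data.frame(t_min = (0:3) * 20, z_um = c(0, 5, 3, 8),
                               y_um = 0, x_um = 0)
  expect_lt(compute_metrics(collinear_back)$straightness, 1)
})

test_that("group summaries reproduce printed speed significance", {
  # per-cell speeds: WT 23.4 +/- 0.2 (n = 208), MT 13.3 +/- 0.1 (n = 217);
  # the bound must hold whether the +/- is read as SEM or 90% CI half-width
  for (kind in c("sem", "ci90")) {
    ts <- t_test_from_summary(
      summary_from_errorbar(23.4, 0.2, 208, kind, "WT"),
      summary_from_errorbar(13.3, 0.1, 217, kind, "MT"))
    expect_lt(ts$p, 1e-4)
  }
  # straightness 0.881 +/- 0.004 vs 0.658 +/- 0.006, displacement
  # 244.4 +/- 3.6 vs 133.2 +/- 2.4
  for (kind in c("sem", "ci90")) {
    expect_lt(t_test_from_summary(
      summary_from_errorbar(0.881, 0.004, 208, kind),
      summary_from_errorbar(0.658, 0.006, 217, kind))$p, 1e-4)
    expect_lt(t_test_from_summary(
      summary_from_errorbar(244.4, 3.6, 208, kind),
      summary_from_errorbar(133.2, 2.4, 217, kind))$p, 1e-4)
  }
})

test_that("summarize_track_groups returns summaries and pairwise tests", {
  mk <- function(speed, n, seed) {
    with_seed(seed, data.frame(
      displacement_um = rnorm(n, speed * 6, 10),
      mean_speed_um_hr = rnorm(n, speed, 1),
      straightness = pmin(1, pmax(0, rnorm(n, 0.8, 0.05)))))
  }
  res <- summarize_track_groups(list(WT = mk(23, 40, 1), MT = mk(13, 40, 2)))
  expect_named(res, c("displacement", "mean_speed", "straightness"))
  expect_lt(res$mean_speed$tests$p_pooled, 1e-6)
  expect_equal(res$mean_speed$summaries$WT$n, 40)
  ident <- summarize_track_groups(list(a = mk(20, 30, 3), b = mk(20, 30, 3)))
  expect_equal(ident$mean_speed$tests$p_pooled, 1)
})
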