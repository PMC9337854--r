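test_that("digital ball matches analytic sphere metrics", {
  lv <- make_ball(20, c(1, 1, 1))
  m <- measure_region(lv, 1)
  expect_lt(abs(m$volume_um3 - 4 / 3 * pi * 20^3) / (4 / 3 * pi * 20^3),
            0.02)
  expect_lt(abs(m$surface_area_um2 - 4 * pi * 20^2) / (4 * pi * 20^2),
            0.05)
  expect_lt(abs(m$thickness_um - 20 / 3) / (20 / 3), 0.05)
  expect_false(m$clipped)
})

test_that("spherical shell matches analytic volume and two-sided area", {
  lv <- make_shell(40, 60, c(1, 1, 1))
  m <- measure_region(lv, 1)
  v_true <- 4 / 3 * pi * (60^3 - 40^3)
  a_true <- 4 * pi * (60^2 + 40^2)
  expect_lt(abs(m$volume_um3 - v_true) / v_true, 0.02)
  expect_lt(abs(m$surface_area_um2 - a_true) / a_true, 0.05)
  expect_lt(abs(m$thickness_um - v_true / a_true) / (v_true / a_true), 0.05)
})

test_that("random blobs: volume exact, area near the face-count oracle", {
  for (s in 1:3) {
    blob <- make_blob(seed = s)
    lv <- label_volume(array(as.integer(blob), dim(blob)), c(1, 1, 1))
    m <- measure_region(lv, 1)
    expect_equal(m$volume_um3, sum(blob))  # brute-force voxel count
    # voxel-face counting overestimates smooth surfaces by ~3/2; the
    # corrected oracle must agree within 15%
    a_faces <- face_count_area(blob, c(1, 1, 1)) * 2 / 3
    expect_lt(abs(m$surface_area_um2 - a_faces) / a_faces, 0.15)
  }
})

test_that("V scales with voxel volume and A with its square rescale", {
  blob <- make_blob(seed = 4)
  lv1 <- label_volume(array(as.integer(blob), dim(blob)), c(1, 1, 1))
  lv2 <- label_volume(array(as.integer(blob), dim(blob)), c(2, 2, 2))
  m1 <- measure_region(lv1, 1, smooth_um = 1)
  m2 <- measure_region(lv2, 1, smooth_um = 2)
  expect_equal(m2$volume_um3, 8 * m1$volume_um3)
  expect_lt(abs(m2$surface_area_um2 - 4 * m1$surface_area_um2) /
              (4 * m1$surface_area_um2), 0.02)
})

test_that("thickness is invariant to 90-degree rotations", {
  blob <- make_blob(seed = 5)
  lv <- label_volume(array(as.integer(blob), dim(blob)), c(1, 1, 1))
  m <- measure_region(lv, 1)
  rot <- aperm(array(as.integer(blob), dim(blob)), c(2, 3, 1))
  mrot <- measure_region(label_volume(rot, c(1, 1, 1)), 1)
  expect_equal(mrot$volume_um3, m$volume_um3)
  expect_equal(mrot$surface_area_um2, m$surface_area_um2, tolerance = 0.01)
})

test_that("shell thickness V/A is monotone in true shell thickness", {
  va <- vapply(c(4, 8, 12, 16, 20), function(t) {
    m <- measure_region(make_shell(30, 30 + t, c(2, 2, 2)), 1)
    m$thickness_um
  }, numeric(1))
  expect_true(all(diff(va) > 0))
})

test_that("anisotropic voxels are handled in physical units", {
  lv <- make_ball(20, c(2, 1, 1))
  m <- measure_region(lv, 1)
  expect_lt(abs(m$volume_um3 - 4 / 3 * pi * 20^3) / (4 / 3 * pi * 20^3),
            0.03)
  expect_lt(abs(m$surface_area_um2 - 4 * pi * 20^2) / (4 * pi * 20^2),
            0.08)
})

test_that("segmentation recovers phantom ventricles above Jaccard 0.7", {
  spec <- phantom_spec(organoid_radius = 110, n_ventricles = 3,
                       ventricle_radius_range = c(16, 24),
                       vz_shell_thickness = 16, cp_soma_density = 5e3,
                       voxel_size = c(2, 2, 2))
  ph <- generate_phantom(spec, seed = 42)
  seg <- segment_vz(ph$image)
  expect_equal(max(seg$labels), 3L)
  for (i in 1:3)
    expect_gt(best_jaccard(ph$labels$labels == i, seg$labels), 0.7)
})

test_that("blank volumes give zero labels, with a warning", {
  vol <- image_volume(array(0, c(10, 12, 12)), c(2, 2, 2))
  expect_warning(seg <- segment_vz(vol))
  expect_true(all(seg$labels == 0L))
  org <- measure_organoid(seg)
  expect_equal(org$n_ventricles, 0L)
  expect_equal(org$total_vz_volume_um3, 0)
})

test_that("imported manual masks survive relabeling unchanged", {
  arr <- array(0L, c(10, 20, 20))
  arr[3:6, 3:8, 3:8] <- 1L
  arr[3:6, 12:17, 12:17] <- 1L  # drawn with the same pen value
  lv <- import_masks(arr, c(2, 2, 2))
  expect_equal(max(lv$labels), 2L)  # two components, two labels
  expect_identical(lv$labels > 0L, arr > 0L)
  expect_equal(lv$provenance, "manual_import")
})

test_that("organoid summary aggregates per-region metrics", {
  arr <- array(0L, c(12, 30, 30))
  arr[3:8, 3:12, 3:12] <- 1L
  arr[3:8, 18:27, 18:27] <- 2L
  lv <- label_volume(arr, c(2, 2, 2))
  org <- measure_organoid(lv)
  expect_equal(org$n_ventricles, 2L)
  expect_equal(org$total_vz_volume_um3, sum(org$regions$volume_um3))
  expect_equal(org$mean_thickness_um, mean(org$regions$thickness_um))
  expect_equal(org$pooled_thickness_um,
               sum(org$regions$volume_um3) / sum(org$regions$surface_area_um2))
  # label permutation leaves the count invariant
  perm <- arr
  perm[arr == 1L] <- 7L
  expect_equal(measure_organoid(label_volume(perm, c(2, 2, 2)))$n_ventricles,
               2L)
})

test_that("regions touching the boundary are flagged clipped", {
  arr <- array(0L, c(8, 10, 10))
  arr[1:4, 2:5, 2:5] <- 1L  # touches z = 0 face
  m <- measure_region(label_volume(arr, c(1, 1, 1)), 1)
  expect_true(m$clipped)
})
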