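test_that("background-only stacks yield no detections at default settings", {
  pe <- field_preset("noise", 0, 0, 0, 1, 0.5,
                     extent = c(x = 15, y = 15, z = 6))
  fp <- vapply(1:5, function(s) {
    st <- render_field(sample_field(pe, s), seed = s)
    n_puncta(detect_puncta(st, "ctbp2"))
  }, numeric(1))
  expect_identical(sum(fp), 0)
})

test_that("well-separated noiseless spots are all found and localised", {
  # 49 spots on a jittered grid, >= 3 um apart
  ext <- c(x = 24, y = 24, z = 6)
  p <- field_preset("grid", 49, 0, 0, 1, 0.5, extent = ext)
  f <- sample_field(p, 1)
  g <- expand.grid(x = seq(2, 22, length.out = 7),
                   y = seq(2, 22, length.out = 7))
  set.seed(42)
  f$pre_points <- data.frame(x = g$x + runif(49, -0.3, 0.3),
                             y = g$y + runif(49, -0.3, 0.3),
                             z = runif(49, 1.5, 4.5))
  st <- render_field(f, seed = 1, background = 0, noise = FALSE,
                     photon_scale = 500)
  det <- detect_puncta(st, "ctbp2")
  expect_identical(n_puncta(det), 49L)
  voxdiag <- sqrt(sum(st$voxel_size^2))
  errs <- vapply(seq_len(49), function(j) {
    sqrt(min((det$puncta$x_um - f$pre_points$x[j])^2 +
               (det$puncta$y_um - f$pre_points$y[j])^2 +
               (det$puncta$z_um - f$pre_points$z[j])^2))
  }, numeric(1))
  expect_lt(max(errs), 0.25 * voxdiag)
})

test_that("spots closer than min_distance merge into one punctum", {
  ext <- c(x = 8, y = 8, z = 4)
  p <- field_preset("pair", 2, 0, 0, 1, 0.5, extent = ext)
  f <- sample_field(p, 1)
  f$pre_points <- data.frame(x = c(4.0, 4.3), y = c(4, 4), z = c(2, 2))
  st <- render_field(f, seed = 1, background = 0, noise = FALSE)
  det <- detect_puncta(st, "ctbp2", min_distance = 1)
  expect_identical(n_puncta(det), 1L)
})

test_that("percentile-of-positive thresholding finds the same bright spots", {
  ext <- c(x = 12, y = 12, z = 5)
  p <- field_preset("pct", 6, 0, 0, 1, 0.5, extent = ext)
  f <- sample_field(p, 11)
  f$pre_points <- data.frame(x = c(2, 6, 10, 2, 6, 10),
                             y = c(3, 3, 3, 9, 9, 9),
                             z = rep(2.5, 6))
  st <- render_field(f, seed = 1)
  abs_det <- detect_puncta(st, "ctbp2")
  pct_det <- detect_puncta(st, "ctbp2",
                           threshold_mode = "percentile-of-positive",
                           threshold_value = 99.99)
  expect_identical(n_puncta(abs_det), 6L)
  expect_identical(n_puncta(pct_det), 6L)
  expect_equal(sort(pct_det$puncta$x_um), sort(abs_det$puncta$x_um),
               tolerance = 1e-6)
})

test_that("raising the threshold never increases the puncta count", {
  p <- small_preset()
  st <- render_field(sample_field(p, 3), seed = 3)
  counts <- vapply(c(20, 50, 80, 120, 200), function(thr)
    n_puncta(detect_puncta(st, "ctbp2", threshold_value = thr)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is translation-equivariant for whole-voxel shifts", {
  ext <- c(x = 14, y = 14, z = 6)
  p <- field_preset("shift", 10, 0, 0, 1, 0.5, extent = ext)
  f <- sample_field(p, 6)
  f$pre_points <- data.frame(x = runif(10, 3, 9), y = runif(10, 3, 9),
                             z = runif(10, 2, 4))
  shift <- c(x = 5 * 0.104, y = 3 * 0.104, z = 1 * 0.40)
  f2 <- f
  f2$pre_points <- data.frame(x = f$pre_points$x + shift[["x"]],
                              y = f$pre_points$y + shift[["y"]],
                              z = f$pre_points$z + shift[["z"]])
  d1 <- detect_puncta(render_field(f, seed = 1, background = 0,
                                   noise = FALSE), "ctbp2")
  d2 <- detect_puncta(render_field(f2, seed = 1, background = 0,
                                   noise = FALSE), "ctbp2")
  expect_identical(n_puncta(d1), n_puncta(d2))
  o1 <- order(d1$puncta$x_um); o2 <- order(d2$puncta$x_um)
  expect_equal(d2$puncta$x_um[o2] - d1$puncta$x_um[o1],
               rep(shift[["x"]], 10), tolerance = 1e-6)
  expect_equal(d2$puncta$y_um[o2] - d1$puncta$y_um[o1],
               rep(shift[["y"]], 10), tolerance = 1e-6)
  expect_equal(d2$puncta$z_um[o2] - d1$puncta$z_um[o1],
               rep(shift[["z"]], 10), tolerance = 1e-6)
})

test_that("unknown channels error and an all-zero channel yields an empty set", {
  p <- small_preset()
  st <- render_field(sample_field(p, 1), seed = 1)
  expect_error(detect_puncta(st, "dapi"), "unknown channel")
  vox <- st$voxels
  vox[1, , , ] <- 0
  st0 <- confocal_stack(vox, st$voxel_size, st$channel_labels,
                        origin = vestisyn:::stack_origin(st))
  expect_identical(n_puncta(detect_puncta(st0, "ctbp2")), 0L)
})

test_that("mask filtering keeps what the mask covers", {
  p <- small_preset(n_pre = 40, n_post = 0, paired_fraction = 0)
  f <- sample_field(p, 8)
  st <- render_field(f, seed = 8)
  det <- detect_puncta(st, "ctbp2")
  # full-field mask: identity
  expect_identical(filter_by_mask(det, st)$puncta, det$puncta)
  # empty mask with zero margin: annihilates
  vox <- st$voxels
  vox[3, , , ] <- 0
  st_empty <- confocal_stack(vox, st$voxel_size, st$channel_labels,
                             origin = vestisyn:::stack_origin(st))
  expect_identical(n_puncta(filter_by_mask(det, st_empty, margin = 0)), 0L)
  # half-field mask at zero margin: retained fraction tracks the x cut
  vox2 <- st$voxels
  nx <- dim(vox2)[4]
  vox2[3, , , (nx %/% 2 + 1):nx] <- 0
  st_half <- confocal_stack(vox2, st$voxel_size, st$channel_labels,
                            origin = vestisyn:::stack_origin(st))
  kept <- filter_by_mask(det, st_half, margin = 0)
  in_half <- sum(det$puncta$x_um <= (nx %/% 2) * st$voxel_size[["dx"]])
  expect_identical(n_puncta(kept), in_half)
  expect_error(filter_by_mask(det, st, margin = -1), "margin")
})
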