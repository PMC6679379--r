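test_that("field sampling is deterministic and serialises byte-identically", {
  p <- load_field_preset("sham-utricle")
  f1 <- sample_field(p, 7)
  f2 <- sample_field(p, 7)
  expect_identical(f1, f2)
  t1 <- tempfile(fileext = ".csv"); t2 <- tempfile(fileext = ".csv")
  write_field(f1, t1); write_field(f2, t2)
  expect_identical(readBin(t1, "raw", file.size(t1)),
                   readBin(t2, "raw", file.size(t2)))
  f3 <- sample_field(p, 8)
  expect_false(identical(f1$pre_points, f3$pre_points))
})

test_that("generated fields respect preset invariants across seeds", {
  p <- load_field_preset("sham-utricle")
  for (s in 1:5) {
    f <- sample_field(p, s)
    ext <- p$extent
    for (pts in list(f$pre_points, f$post_points)) {
      expect_true(all(pts$x >= 0 & pts$x <= ext[["x"]]))
      expect_true(all(pts$y >= 0 & pts$y <= ext[["y"]]))
      expect_true(all(pts$z >= 0 & pts$z <= ext[["z"]]))
    }
    expect_true(all(f$pairing$pre %in% seq_len(nrow(f$pre_points))))
    expect_true(all(f$pairing$post %in% seq_len(nrow(f$post_points))))
    expect_false(any(duplicated(f$pairing$pre)))
    expect_false(any(duplicated(f$pairing$post)))
    # pairing count fixed by construction (sham scales are 1)
    expect_identical(nrow(f$pairing),
                     as.integer(round(p$paired_fraction * nrow(f$pre_points))))
  }
})

test_that("degenerate presets behave as contracted", {
  # paired offsets pinned at zero: every pre coincides with its partner
  p0 <- field_preset("degenerate", 30, 30, 1, 0, 1e-12,
                     extent = c(x = 10, y = 10, z = 5))
  f <- sample_field(p0, 1)
  d <- nn_distances(field_puncta(f, "pre"), field_puncta(f, "post"))
  expect_true(all(d$distances < 1e-6))
  # no presynaptic puncta at all
  pe <- field_preset("nopre", 0, 10, 0.5, 1, 0.5,
                     extent = c(x = 10, y = 10, z = 5))
  fe <- sample_field(pe, 1)
  expect_identical(nrow(fe$pre_points), 0L)
  expect_identical(nrow(fe$pairing), 0L)
})

test_that("invalid presets are rejected", {
  expect_error(field_preset("bad", -5, 10, 0.5, 1, 0.5), "count")
  expect_error(field_preset("bad", 5, 10, 1.4, 1, 0.5), "paired_fraction")
  expect_error(field_preset("bad", 5, 10, 0.5, 1, 0.5,
                            extent = c(x = -1, y = 10, z = 5)), "extent")
  expect_error(load_field_preset("no-such-preset"), "unknown field preset")
})

test_that("paper-mode presets use the standard observation field", {
  for (lab in list_field_presets()) {
    p <- load_field_preset(lab)
    expect_equal(unname(p$extent[["x"]] * p$extent[["y"]]) * 1e-6, 4.5e-3,
                 tolerance = 1e-3)
  }
  sham <- load_field_preset("sham-utricle")
  expect_identical(sham$expression_scale_pre, 1)
  expect_identical(sham$expression_scale_post, 1)
})

test_that("calibration hits anchors, including the saturated case", {
  base <- field_preset("cal-base", 120, 150, 0.5, 1.0, 0.8,
                       extent = c(x = 30, y = 30, z = 8))
  cal <- calibrate_preset(data.frame(distance_um = c(1, 2),
                                     fraction = c(0.40, 0.75)),
                          base, seed = 11, n_fields = 30)
  chk <- vestisyn:::gt_cdf(cal, c(1, 2), seed = 99, n_fields = 30)
  expect_lt(max(abs(chk - c(0.40, 0.75))), 0.03)
  # saturated single anchor: full pairing, offset scale shrunk toward zero
  sat <- calibrate_preset(data.frame(distance_um = 1, fraction = 1),
                          base, seed = 11, n_fields = 20)
  expect_identical(sat$paired_fraction, 1)
  expect_lt(sat$offset_sigma, base$offset_sigma)
  chk1 <- vestisyn:::gt_cdf(sat, 1, seed = 99, n_fields = 20)
  expect_gt(chk1, 0.97)
})

test_that("infeasible anchors raise a calibration error", {
  base <- field_preset("cal-base", 50, 60, 0.5, 1.0, 0.8,
                       extent = c(x = 20, y = 20, z = 6))
  expect_error(calibrate_preset(data.frame(distance_um = c(1, 2),
                                           fraction = c(0.8, 0.3)),
                                base, seed = 1), "nondecreasing")
})

test_that("shipped presets reproduce their cumulative anchors", {
  # ground-truth CDF at the calibration anchors within 3 percentage points,
  # aggregated over enough fields for >= 5000 source puncta
  for (lab in list_field_presets()) {
    p <- load_field_preset(lab)
    n_per <- p$n_pre * p$expression_scale_pre
    nf <- max(15L, ceiling(5000 / n_per))
    got <- vestisyn:::gt_cdf(p, p$anchors$distance_um, seed = 314,
                             n_fields = nf)
    expect_lt(max(abs(got - p$anchors$fraction)), 0.03,
              label = sprintf("%s anchor deviation", lab))
  }
})
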