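test_that("default geometry has seven mirror-symmetric columns labelled A-G", {
  g <- chip_geometry()
  expect_s3_class(g, "chip_geometry")
  expect_identical(g$labels, LETTERS[1:7])
  expect_true(g$mirror_symmetric)
  expect_equal(g$footprint_width_um, 7 * g$channels$pitch_um)

  # reflection about the central axis leaves the parametric layout unchanged
  expect_identical(reflect_geometry(g), g)

  # round trip through the serialised configuration list
  expect_identical(build_geometry(as.list(g)), g)
})

test_that("geometry validation rejects degenerate or inconsistent configs", {
  expect_error(chip_geometry(gap_depth_um = 0), "gap_depth_um")
  expect_error(chip_geometry(channels = list(count = 6, width_um = 500, depth_um = 87,
                                             length_um = 20000, pitch_um = 1500)),
               "odd channel count")
  expect_error(chip_geometry(wells = list(per_column = 6, diameter_um = -5,
                                          depth_um = 300, first_y_um = 8000,
                                          pitch_um = 800)),
               "well_diameter_um")
  expect_error(build_geometry(list(gab_depth_um = 50)), "unknown config key")
  expect_error(build_geometry(list(channels = list(widht_um = 300))), "unknown key")
})

test_that("UV dose is exposure time times irradiance", {
  expect_identical(exposure_to_dose(32, 20), 640)
  expect_identical(exposure_to_dose(0, 20), 0)
  expect_identical(exposure_to_dose(28, 20), 560)
  expect_error(exposure_to_dose(-1, 20), ">= 0")
  expect_error(exposure_to_dose(10, 0), "> 0")
})

test_that("exposure-depth calibration interpolates the measured depths monotonically", {
  cal <- calibrate_exposure_depth(c(24, 26, 28, 30), c(162.1, 106.6, 92.6, 57.3))
  # passes exactly through the calibration points
  expect_equal(depth_at(cal, c(24, 26, 28, 30)), c(162.1, 106.6, 92.6, 57.3))
  expect_equal(depth_at(cal, 28), 92.6)
  # interpolated values stay inside the bracketing depths
  d25 <- depth_at(cal, 25)
  expect_gt(d25, 106.6)
  expect_lt(d25, 162.1)
  # order-preserving: depth decreases strictly over the whole range
  tq <- seq(24, 30, by = 0.05)
  expect_true(all(diff(depth_at(cal, tq)) < 0))
  # UV dose column uses the configured irradiance
  expect_equal(cal$records$uv_dose_mJ_cm2, c(480, 520, 560, 600))
})

test_that("exposure-depth calibration edge cases", {
  # two points: linear, midpoint is the mean depth
  cal2 <- calibrate_exposure_depth(c(24, 30), c(162.1, 57.3))
  expect_equal(depth_at(cal2, 27), mean(c(162.1, 57.3)))
  # inconsistent (non-monotone) calibration data are rejected
  expect_error(calibrate_exposure_depth(c(24, 26, 28), c(100, 120, 80)),
               "decrease strictly")
  expect_error(calibrate_exposure_depth(c(24, 24, 28), c(120, 100, 80)), "distinct")
  expect_error(calibrate_exposure_depth(24, 162.1), "at least 2")
  # no extrapolation
  cal <- calibrate_exposure_depth(c(24, 26, 28, 30), c(162.1, 106.6, 92.6, 57.3))
  expect_error(depth_at(cal, 31), "extrapolate")
  expect_error(depth_at(cal, 23), "extrapolate")
})

test_that("spheroid retention rule counts whole cell diameters through the gap", {
  expect_identical(min_retained_spheroid_cells(92.6, 15), 6L)
  expect_identical(min_retained_spheroid_cells(15, 15), 1L)
  expect_identical(min_retained_spheroid_cells(162.1, 15), 10L)
  expect_error(min_retained_spheroid_cells(0, 15), "> 0")
  # monotone: non-decreasing in gap depth, non-increasing in cell diameter
  gaps <- seq(20, 300, by = 7)
  expect_true(all(diff(min_retained_spheroid_cells(gaps, 15)) >= 0))
  cells <- seq(10, 30, by = 2)
  expect_true(all(diff(sapply(cells, function(cd)
    min_retained_spheroid_cells(92.6, cd))) <= 0))
})
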