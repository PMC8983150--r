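test_that("rasterize produces a consistent, mirror-symmetric mask", {
  g <- chip_geometry()
  gr <- rasterize(g, 100)
  expect_equal(gr$nx, 105)
  expect_equal(gr$ny, 200)
  # symmetric geometry: mask equals its own mirror image
  expect_identical(gr$mask[gr$nx:1, ], gr$mask)
  # well cells present for every column, equally many per column
  counts <- tabulate(gr$well_column[gr$well_column > 0], nbins = 7)
  expect_true(all(counts > 0))
  expect_true(length(unique(counts)) == 1)
  # ~ per-column well area: 6 wells of radius 200 um -> ~ 6 * pi r^2 / dx^2
  expect_lt(abs(counts[1] - 6 * pi * 200^2 / 100^2) / counts[1], 0.2)
  # halving the cell size quadruples the cell count
  gr2 <- rasterize(g, 50)
  expect_equal(gr2$nx * gr2$ny, 4 * gr$nx * gr$ny)
  # inlet coverage splits the edge exactly in half
  expect_equal(sum(gr$inlet_left), gr$nx / 2)
})

test_that("rasterize rejects incompatible cell sizes", {
  g <- chip_geometry()
  expect_error(rasterize(g, 600), "channel width")
  expect_error(rasterize(g, 300), "well_diameter")   # 400/300 misfit > 5%
})

test_that("plug velocity field conserves mass and splits evenly over channels", {
  g <- chip_geometry()
  gr <- rasterize(g, 100)
  vel <- velocity_field(0.0002198, gr, g)
  # plug speed equals Q / (W h)
  Q <- 0.0002198 / 6e7
  expect_equal(vel$v_m_s, Q / (10.5e-3 * 92.6e-6))
  # exactly divergence-free
  expect_equal(max_divergence(vel), 0)
  # flux through each column-pitch strip is Q/7 (one strip per channel)
  flux <- colSums(matrix(vel$qy[, 1], nrow = gr$nx / 7)) * g$gap_depth_um * 1e-6
  expect_equal(flux, rep(Q / 7, 7), tolerance = 1e-12)
  # zero boundary flow gives a zero field
  vel0 <- velocity_field(0, gr, g)
  expect_equal(max(abs(vel0$qy)), 0)
  # a flow_solution can drive the field directly
  fs <- solve_flow(chip_network(g, fluid_properties(), 208))
  vel2 <- velocity_field(fs, gr, g)
  expect_equal(vel2$Q_m3_s, fs$node_net_flux_m3_s[["outlet"]])
})

test_that("pure diffusion with a uniform inlet gives a uniform unit field", {
  g <- chip_geometry()
  gr <- rasterize(g, 100)
  gr$inlet_left <- rep(1, gr$nx)        # same tracer on both inlet segments
  vel0 <- velocity_field(0, gr, g)
  f <- solve_steady_transport(gr, vel0, 5e-10, "left")
  expect_equal(range(f$frac), c(1, 1), tolerance = 1e-9)
})

test_that("two-drug solve is mirror-symmetric and obeys the maximum principle", {
  sol <- get_grad100()
  f_tmz <- sol$fields$tmz$frac
  f_bay <- sol$fields$bay$frac
  nx <- nrow(f_tmz)
  # drug B's field is the mirror image of drug A's
  expect_equal(f_bay, f_tmz[nx:1, ], tolerance = 1e-9)
  # the two fractions partition the flow: cA + cB = 1 everywhere
  expect_lt(max(abs(f_tmz + f_bay - 1)), 1e-6)
  # discrete maximum principle
  expect_gt(min(f_tmz), -1e-9)
  expect_lt(max(f_tmz), 1 + 1e-9)
  expect_lt(sol$fields$tmz$residual_rel, 1e-10)
})

test_that("column dose map has the published gradient shape", {
  sol <- get_grad100()
  dm <- sol$dose_map
  expect_identical(dm$column, LETTERS[1:7])
  # strictly decreasing left-inlet drug, mirrored right-inlet drug
  expect_true(all(diff(dm$frac_tmz) < 0))
  expect_true(all(diff(dm$frac_bay) > 0))
  expect_equal(dm$frac_bay, rev(dm$frac_tmz), tolerance = 1e-9)
  # central column splits 50/50; advection keeps the edge column nearly pure
  expect_equal(dm$frac_tmz[4], 0.5, tolerance = 0.01)
  expect_gte(dm$frac_tmz[1], 0.99)
  # absolute doses scale fractions by the inlet concentrations
  expect_equal(dm$dose_tmz_uM, dm$frac_tmz * 600)
  expect_equal(dm$dose_bay_uM, dm$frac_bay * 10)
  # qualitative match to the published seven-column sequence
  expect_lt(max(abs(100 * dm$frac_tmz - unname(published_fracs))), 5)
})

test_that("swapping the drugs' transport parameters swaps the dose map", {
  sol <- get_grad100()
  p <- transport_params()
  swapped <- extract_column_doses(list(tmz = sol$fields$bay, bay = sol$fields$tmz),
                                  sol$grid,
                                  transport_params(inlet_tmz_uM = p$inlet_bay_uM,
                                                   inlet_bay_uM = p$inlet_tmz_uM))
  expect_equal(swapped$frac_tmz, sol$dose_map$frac_bay)
  expect_equal(swapped$dose_tmz_uM, sol$dose_map$dose_bay_uM)
})

test_that("column extraction demands well coverage", {
  sol <- get_grad100()
  gr <- sol$grid
  gr$well_column[gr$well_column == 4L] <- 0L
  expect_error(extract_column_doses(sol$fields, gr), "D")
})

test_that("tracer flux balances at steady state and flags corrupted fields", {
  sol <- get_grad100()
  imb <- check_conservation(sol$fields$tmz, sol$velocity, sol$grid)
  expect_lte(imb, 1e-3)
  # a field that did not converge (here: damaged by hand) is flagged
  bad <- sol$fields$tmz
  bad$frac <- bad$frac * 0.5
  expect_gt(check_conservation(bad, sol$velocity, sol$grid), 1e-3)
})
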