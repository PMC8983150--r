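test_that("rectangular channel resistance follows the wide-duct law", {
  mu <- 8.9e-4
  r1 <- rect_channel_resistance(5e-4, 1e-4, 0.02, mu)
  # linear in length
  expect_equal(rect_channel_resistance(5e-4, 1e-4, 0.04, mu), 2 * r1)
  # slit limit: within 1% of 12 mu L / (w h^3) for h/w = 0.01
  w <- 1e-2; h <- 1e-4; L <- 0.02
  slit <- 12 * mu * L / (w * h^3)
  expect_lt(abs(rect_channel_resistance(w, h, L, mu) - slit) / slit, 0.01)
  # and within 1% across aspect ratios up to 0.02
  for (ar in c(0.002, 0.005, 0.02)) {
    h <- w * ar
    slit <- 12 * mu * L / (w * h^3)
    expect_lt(abs(rect_channel_resistance(w, h, L, mu) - slit) / slit, 0.0130)
  }
  expect_error(rect_channel_resistance(1e-4, 5e-4, 0.02, mu), "swap")
})

test_that("hydrostatic pressure of the tilted chip", {
  fl <- fluid_properties()
  expect_equal(hydrostatic_pressure(0.05, fl, 0), 0)
  expect_equal(hydrostatic_pressure(0.05, fl, 90), 1000 * 9.81 * 0.05)
  expect_equal(hydrostatic_pressure(0.05, fl, 45), 1000 * 9.81 * 0.05 * sqrt(0.5),
               tolerance = 1e-12)
  expect_equal(hydrostatic_pressure(0.05, fl, 45), 346.8, tolerance = 2e-4)
  expect_error(hydrostatic_pressure(0.05, fl, 95), "\\[0, 90\\]")
})

test_that("solve_flow matches closed forms on elementary networks", {
  one <- function(R, dp) {
    net <- hydraulic_network(
      data.frame(id = c("a", "b"), pressure_pa = c(dp, 0)),
      data.frame(from = "a", to = "b", kind = "rectangular_channel", resistance = R))
    solve_flow(net)
  }
  # single edge: Q = dP / R
  s <- one(2, 2)
  expect_equal(s$edges$flow_m3_s, 1)
  # two equal parallel edges each carry half the total
  net2 <- hydraulic_network(
    data.frame(id = c("a", "b"), pressure_pa = c(1, 0)),
    data.frame(from = c("a", "a"), to = c("b", "b"),
               kind = "rectangular_channel", resistance = c(4, 4)))
  s2 <- solve_flow(net2)
  expect_equal(s2$edges$flow_m3_s, c(0.25, 0.25))
  expect_equal(s2$total_inflow_m3_s, 0.5)
  # two identical edges in series carry half the flow of one at equal dP
  net3 <- hydraulic_network(
    data.frame(id = c("a", "m", "b"), pressure_pa = c(2, NA, 0)),
    data.frame(from = c("a", "m"), to = c("m", "b"),
               kind = "rectangular_channel", resistance = c(2, 2)))
  expect_equal(solve_flow(net3)$edges$flow_m3_s, c(0.5, 0.5))
})

test_that("solve_flow agrees with a brute-force nodal solve on a random network", {
  set.seed(7)
  ids <- paste0("n", 1:6)
  # ring plus chords keeps the graph connected
  ed <- rbind(data.frame(from = ids[-6], to = ids[-1]),
              data.frame(from = sample(ids, 5, TRUE), to = sample(ids, 5, TRUE)))
  ed <- ed[ed$from != ed$to, ]
  ed$kind <- "rectangular_channel"
  ed$resistance <- runif(nrow(ed), 0.5, 3)
  nodes <- data.frame(id = ids, pressure_pa = c(1.3, NA, NA, NA, NA, 0))
  net <- hydraulic_network(nodes, ed)
  sol <- solve_flow(net)

  # independent oracle: loop-assembled nodal balance equations
  unk <- ids[is.na(nodes$pressure_pa)]
  A <- matrix(0, length(unk), length(unk), dimnames = list(unk, unk))
  b <- stats::setNames(numeric(length(unk)), unk)
  pknown <- stats::setNames(nodes$pressure_pa, ids)
  for (u in unk) {
    for (e in seq_len(nrow(ed))) {
      other <- if (ed$from[e] == u) ed$to[e] else if (ed$to[e] == u) ed$from[e] else NA
      if (is.na(other)) next
      g <- 1 / ed$resistance[e]
      A[u, u] <- A[u, u] + g
      if (other %in% unk) A[u, other] <- A[u, other] - g
      else b[u] <- b[u] + g * pknown[other]
    }
  }
  p_oracle <- solve(A, b)
  expect_equal(unname(sol$node_pressure_pa[unk]), unname(p_oracle), tolerance = 1e-10)
  # conservation at every interior node
  expect_lte(sol$rel_imbalance, 1e-12)
})

test_that("solve_flow rejects under-constrained problems", {
  expect_error(hydraulic_network(
    data.frame(id = c("a", "b", "c"), pressure_pa = c(1, 0, NA)),
    data.frame(from = "a", to = "b", kind = "x", resistance = 1)),
    "not connected")
  net1 <- hydraulic_network(
    data.frame(id = c("a", "b"), pressure_pa = c(1, NA)),
    data.frame(from = "a", to = "b", kind = "x", resistance = 1))
  expect_error(solve_flow(net1), "at least 2")
})

test_that("forward perfusion model hits the channel-only anchor and is monotone", {
  g <- chip_geometry()
  q0 <- predict_perfusion(g, 0)
  # channel-only baseline calibrated against the measured 0.12 +- 0.01 mL/min
  expect_lt(abs(q0 - 0.12), 0.01)
  # strictly increasing in gap depth
  hs <- c(0, 25, 50, 92.6, 150, 300, 500)
  qs <- vapply(hs, function(h) predict_perfusion(g, h), 0)
  expect_true(all(diff(qs) > 0))
  expect_error(predict_perfusion(g, -5), ">= 0")
})

test_that("gap-depth inversion round-trips the forward model", {
  g <- chip_geometry()
  for (h in c(10, 57.3, 92.6, 106.6, 162.1, 300)) {
    q <- predict_perfusion(g, h)
    expect_lt(abs(estimate_gap_depth(q, g) - h), 1e-3)
  }
  # at or below the channel-only baseline the gap is reported as closed
  q0 <- predict_perfusion(g, 0)
  expect_identical(estimate_gap_depth(q0, g), 0)
  expect_warning(h_low <- estimate_gap_depth(0.5 * q0, g), "below the channel-only")
  expect_identical(h_low, 0)
  # unbracketable measurement is refused
  q_big <- predict_perfusion(g, 600)
  expect_error(estimate_gap_depth(q_big, g), "not bracketable")
})
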