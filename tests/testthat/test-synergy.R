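test_that("Bliss combined effect follows the independence rule", {
  expect_equal(bliss_effect(0, 0.37), 0.37)
  expect_equal(bliss_effect(1, 0.37), 1)
  # published patient-derived day-7 anchors: viability 20.8% (drug A edge),
  # 25.1% (drug B edge) against a 70.5% control
  ea <- 1 - 20.8 / 70.5
  eb <- 1 - 25.1 / 70.5
  expect_equal(bliss_effect(ea, eb), 0.895, tolerance = 5e-4)
  # symmetry and bounds
  set.seed(5)
  a <- runif(50); b <- runif(50)
  expect_equal(bliss_effect(a, b), bliss_effect(b, a))
  expect_true(all(bliss_effect(a, b) >= pmax(a, b) - 1e-12))
  expect_true(all(bliss_effect(a, b) <= 1))
  # equals the probabilistic union exactly
  expect_equal(bliss_effect(a, b), 1 - (1 - a) * (1 - b))
  expect_error(bliss_effect(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(bliss_effect(0.5, 1.2), "\\[0, 1\\]")
})

test_that("Welch test from summary statistics matches closed forms", {
  s <- summary_stat(60, 3, 5)
  w0 <- welch_from_summary(s, s)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  # published U87 day-7 column B vs column G summaries
  w <- welch_from_summary(summary_stat(58.9, 3.7, 5), summary_stat(70.6, 4.4, 5))
  expect_equal(w$t, -2.03517, tolerance = 1e-4)
  expect_equal(w$df, 7.7713, tolerance = 1e-3)
  expect_equal(w$p, 2 * pt(-abs(w$t), w$df))
  # doubling both SEMs halves t
  w2 <- welch_from_summary(summary_stat(58.9, 7.4, 5), summary_stat(70.6, 8.8, 5))
  expect_equal(w2$t, w$t / 2)
  expect_error(welch_from_summary(summary_stat(1, 0, 5), summary_stat(2, 0, 5)),
               "SEMs are zero")
  expect_error(summary_stat(1, 1, 1), "n must be")
})

test_that("summary-level Welch equals a replicate-level Welch with the same moments", {
  set.seed(21)
  for (i in 1:10) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    ma <- runif(1, 40, 90); mb <- runif(1, 40, 90)
    sa <- runif(1, 1, 6); sb <- runif(1, 1, 6)
    xa <- make_replicates(ma, sa, na)
    xb <- make_replicates(mb, sb, nb)
    ref <- stats::t.test(xa, xb, var.equal = FALSE)
    w <- welch_from_summary(summary_stat(ma, sa, na), summary_stat(mb, sb, nb))
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(w$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("synergy report on an effect-free table shows zero effect and no excess", {
  h_tmz <- hill_params(1, 0.4, 250, 1.5)
  h_bay <- hill_params(1, 0.28, 0.1, 0.8)
  tab <- flat_table(0.9)
  rep0 <- build_synergy_report(published_dose_map, tab, flat_table(0.9), h_tmz, h_bay)
  expect_equal(rep0$effect_obs, rep(0, 7))
  expect_equal(rep0$excess, -rep0$effect_bliss)
  expect_true(all(rep0$excess <= 0))
  expect_equal(rep0$t_vs_A, rep(0, 7))
})

test_that("synergy report ranks columns and applies Holm correction", {
  set.seed(99)
  spec <- synthetic_spec(kappa = 0, noise_sd = 0.05)
  ex <- simulate_viability_experiment(spec, published_dose_map, seed = 4)
  d7 <- ex$treated[ex$treated$day == 7, ]
  c7 <- ex$control[ex$control$day == 7, ]
  rep7 <- build_synergy_report(published_dose_map, d7, c7,
                               spec$hill_tmz, spec$hill_bay)
  expect_identical(rep7$column, LETTERS[1:7])
  expect_identical(attr(rep7, "best_column"),
                   rep7$column[which.max(rep7$effect_obs)])
  # Holm-adjusted p never smaller than raw p
  ok <- !is.na(rep7$p_holm_vs_A)
  expect_true(all(rep7$p_holm_vs_A[ok] >= rep7$p_vs_A[ok] - 1e-12))
  expect_true(all(rep7$p_holm_vs_ctrl >= rep7$p_vs_ctrl - 1e-12))
  # drug-treated columns sit clearly below control here
  expect_true(all(rep7$effect_obs > 0.2))
  expect_true(all(rep7$p_holm_vs_ctrl < 0.05))
})

test_that("synergy report validates its inputs", {
  h <- hill_params(1, 0.4, 250, 1.5)
  tab <- flat_table(0.8)
  expect_error(build_synergy_report(published_dose_map, tab[tab$column != "C", ],
                                    flat_table(0.9), h, h),
               "missing column\\(s\\) C")
  both_days <- rbind(flat_table(0.8, day = 4), flat_table(0.8, day = 7))
  expect_error(build_synergy_report(published_dose_map, both_days,
                                    flat_table(0.9), h, h), "single day")
})
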