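test_that("scenario profiles hit their prescribed breakpoints", {
  # acute ramp reaches (1 - drop) * optimum exactly at the ramp end
  for (drop in c(0.05, 0.2)) {
    for (ramp in c(30, 120)) {
      prof <- acute_hypocalcemia_profile(drop, ramp, 90)
      v <- profile_value(prof, c(0, ramp / 2, ramp, ramp + 500))
      expect_equal(v$ca, c(5, 5 - drop * 5 / 2, (1 - drop) * 5, (1 - drop) * 5))
      expect_equal(v$p, rep(4.5, 4))
    }
  }
  # zero drop gives flat profiles
  flat <- hysteresis_profile(drop = 0)
  v <- profile_value(flat, seq(0, profile_duration(flat), length.out = 7))
  expect_true(all(v$ca == 5))
  vc <- profile_value(chronic_hypocalcemia_profile(0, 10), c(0, 7200))
  expect_true(all(vc$ca == 5))
  # chronic clamp ends delta below the optimum
  vc <- profile_value(chronic_hypocalcemia_profile(0.25, 200), 200 * 1440)
  expect_equal(vc$ca, 4.75)
  # CKD arms must share a horizon
  expect_error(ckd_profile(data.frame(time = c(0, 1000), value = c(4.5, 9)),
                           c(45, 15), days = 2), "horizon")
})

test_that("flat CKD inputs at the optimum leave PTH at steady state", {
  prof <- ckd_profile(c(4.5, 4.5), c(45, 45), days = 2)
  tr <- simulate_ptg(base_params, prof, output_grid = seq(0, 2880, by = 60))
  expect_equal(tr$pth, rep(tr$pth[1], length(tr$pth)), tolerance = 1e-6)
})

test_that("peak detector ignores monotone rises and flat runs", {
  t <- 0:100
  flat <- rep(2, 101)
  expect_false(detect_peak(t, flat, baseline = 2)$detected)
  rising <- 2 + t / 100
  expect_false(detect_peak(t, rising, baseline = 2)$detected)
  spike <- 2 + exp(-(t - 30)^2 / 20)
  pk <- detect_peak(t, spike, baseline = 2)
  expect_true(pk$detected)
  expect_equal(pk$peak_time, 30)
  # a bump below the threshold is not a peak
  small <- 2 + 0.05 * exp(-(t - 30)^2 / 20)
  expect_false(detect_peak(t, small, baseline = 2, threshold = 0.05)$detected)
})

test_that("identical trajectories yield equality relations, not errors", {
  prof <- acute_hypocalcemia_profile(0.05, 30, 90)
  tr <- simulate_ptg(base_params, prof, t_span = c(0, 300),
                     output_grid = seq(0, 300, by = 1))
  hy <- tr
  attr(hy, "phases") <- list(hypo1 = c(0, 150), normo = c(150, 200),
                             hypo2 = c(200, 300))
  rpt <- evaluate_checks(tr, tr, hy, tr, tr, tr,
                         slope_window_min = 100)
  expect_s3_class(rpt, "ptg_report")
  expect_equal(nrow(rpt$checks), 4L)
  expect_equal(rpt$checks$relation[rpt$checks$name == "acute_fast_peak_gt_slow"],
               "equal")
  expect_true(rpt$checks$passed[rpt$checks$name == "ckd_high_p_dominates"])
})

test_that("sensitivity sweep reports exact zeros at factor one", {
  prof <- ckd_profile(c(4.5, 6.6), c(45, 30), days = 1)
  sw <- sensitivity_sweep(base_params, c("pathways.production.p",
                                         "expression.p_ca"),
                          factors = 1, profile = prof, t_end = 1440,
                          output_grid = seq(0, 1440, by = 10))
  expect_equal(sw$max_rel_dev, c(0, 0))
})

test_that("sweep deviations are stable under output-grid refinement", {
  prof <- ckd_profile(c(4.5, 6.6), c(45, 30), days = 2)
  g1 <- seq(0, 2880, length.out = 500)
  g2 <- seq(0, 2880, length.out = 999)
  s1 <- sensitivity_sweep(base_params, "pathways.production.p", 2, prof,
                          t_end = 2880, output_grid = g1)
  s2 <- sensitivity_sweep(base_params, "pathways.production.p", 2, prof,
                          t_end = 2880, output_grid = g2)
  expect_equal(s1$max_rel_dev, s2$max_rel_dev, tolerance = 1e-3)
})

test_that("the 7-day sweep ranks production and expression intensities highest", {
  # normocalcemia with developing hyperphosphatemia and declining 1,25D
  prof <- ckd_profile(c(4.5, 6.6), c(45, 30), days = 7)
  intensities <- c("pathways.degradation.p", "pathways.degradation.n",
                   "pathways.production.p", "pathways.production.n",
                   "pathways.proliferation.p", "pathways.proliferation.n",
                   "expression.p_ca", "expression.n_ca",
                   "expression.p_d", "expression.n_d")
  sw <- sensitivity_sweep(base_params, intensities, factors = c(0.5, 2),
                          profile = prof, t_end = 7 * 1440,
                          output_grid = seq(0, 7 * 1440, by = 30))
  by_param <- tapply(sw$max_rel_dev, sw$parameter, max)
  top4 <- names(sort(by_param, decreasing = TRUE))[1:4]
  expect_setequal(top4, c("pathways.production.p", "pathways.production.n",
                          "expression.p_ca", "expression.n_ca"))
})
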