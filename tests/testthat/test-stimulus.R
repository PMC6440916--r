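test_that("stimulus function is zero at the optimum, bounded, and terraced", {
  sp <- base_params$stimulus
  for (w in names(sp)) {
    expect_equal(stim(0, sp[[w]]$K, sp[[w]]$W1), 0, tolerance = 1e-15,
                 label = paste("stim(0) for", w))
  }
  # logistic limits
  expect_equal(stim(1e6, 2.5, 2.5), 1)
  expect_equal(stim(-1e6, 2.5, 2.5), -1)

  # hand-evaluated two-logistic value at the low end of the phosphate range:
  # 1/(1+exp(9)) + 1/(1+exp(-3.5)) - 1 = -0.0291886
  expect_equal(stim(-1.1, K = 2.5, W1 = 2.5), -0.0291886, tolerance = 1e-4)

  # plateau: tiny response well inside the half-width
  expect_lt(abs(stim(0.2, 2.5, 2.5)), 0.01)
})

test_that("stimulus function is odd and monotone for all three species", {
  set.seed(42)
  x <- runif(200, -10, 10)
  sp <- base_params$stimulus
  for (w in names(sp)) {
    K <- sp[[w]]$K; W1 <- sp[[w]]$W1
    expect_equal(stim(-x, K, W1), -stim(x, K, W1), tolerance = 1e-12)
    xs <- sort(x)
    expect_true(all(diff(stim(xs, K, W1)) >= 0))
    expect_true(all(abs(stim(x, K, W1)) < 1))
  }
})

test_that("mean stimulus slopes over the reference ranges are small", {
  # phosphate 3.4-4.5 mg/dL, i.e. deviations -1.1..0 from the 4.5 optimum
  expect_lte(mean_stimulus_slope(2.5, 2.5, -1.1, 0), 0.08)
  # 1,25D 20-60 units, deviations -25..+15 from the 45 optimum
  expect_lte(mean_stimulus_slope(0.2, 45, -25, 15), 0.0035)
})

test_that("effect-state dynamics have the stated rest points and slopes", {
  expect_identical(effect_state_rhs(0, 0, 0.1), 0)
  expect_equal(effect_state_rhs(0, 0.5, 0.1), 0.05)
  # closed-form fixed point e = s/(1+|s|) zeroes the derivative
  for (s in c(-1, -0.5, -0.01, 0, 0.3, 1)) {
    expect_equal(effect_state_rhs(effect_state_steady(s), s, 0.2), 0,
                 tolerance = 1e-15)
  }
  expect_identical(effect_state_steady(0), 0)
  expect_equal(effect_state_steady(-0.5), -1 / 3)
  expect_equal(effect_state_steady(1), 0.5)
})

test_that("effect states stay inside (-1, 1) under bounded stimulus signals", {
  set.seed(7)
  for (rep in 1:5) {
    e0 <- runif(1, -0.95, 0.95)
    knots <- runif(6, -1, 1)  # piecewise-constant stimulus in [-1, 1]
    s_fun <- function(t) knots[pmin(floor(t / 50) + 1, 6)]
    tau <- runif(1, 0.05, 0.5)
    # fixed-step integration, recording the running extremes
    e <- e0
    ok <- TRUE
    dt <- 0.02
    for (i in seq_len(300 / dt)) {
      e <- e + dt * effect_state_rhs(e, s_fun(i * dt), tau)
      if (abs(e) >= 1) ok <- FALSE
    }
    expect_true(ok, label = sprintf("bounded run %d (e0=%.2f)", rep, e0))
  }
})

test_that("effect states converge to the closed-form fixed point", {
  for (s in c(-0.8, -0.1, 0.25, 1)) {
    for (tau in c(0.05, 0.2)) {
      e_end <- integrate_effect_state(0, function(t) s, tau,
                                      t_end = 20 / tau, dt = 0.01 / tau)
      expect_equal(e_end, effect_state_steady(s), tolerance = 1e-6)
    }
  }
})
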