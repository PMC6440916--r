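test_that("optimal steady state is an exact rest point with a 0.2 active fraction", {
  p <- base_params
  y0 <- steady_state(p)
  expect_equal(unname(y0["s"] / (y0["s"] + y0["q"])), 0.2)
  expect_equal(round(unname(y0["s"]), 4), 0.1934)
  r <- full_rhs(0, y0, constant_profile(duration = 10), p)
  expect_lt(max(abs(r)), 1e-10)
})

test_that("compiled and R right-hand sides agree at random states", {
  set.seed(99)
  p <- base_params
  y0 <- steady_state(p)
  prof <- acute_hypocalcemia_profile(0.05, 30, 90)
  for (rep in 1:20) {
    y <- unname(y0) * exp(runif(21, -0.2, 0.2))
    # effect states live near zero; place them in (-1, 1) directly
    idx <- c(3, 4, 5, 9, 10, 12, 13, 15, 16)
    y[idx] <- runif(9, -0.8, 0.8)
    names(y) <- state_names()
    t <- runif(1, 0, 120)
    rR <- unname(full_rhs(t, y, prof, p))
    rC <- as.numeric(ptgsim:::ptg_rhs_cpp(t, unname(y),
                                          ptgsim:::flatten_params(p),
                                          prof$times, prof$ca, prof$p, prof$d))
    expect_equal(rC, rR, tolerance = 1e-12)
  }
})

test_that("perturbing only calcium leaves the 1,25D effect state at rest initially", {
  p <- base_params
  y <- steady_state(p)
  y["cs"] <- 4.8  # sensed calcium displaced, sensed 1,25D still optimal
  prof <- input_profile(c(0, 1), ca = c(5, 4), p = 4.5, d = 45, duration = 10)
  r <- full_rhs(0.5, y, prof, p)
  expect_equal(unname(r["delta_in"]), 0, tolerance = 1e-15)
  expect_true(abs(r["chi_in"]) > 0)
})

test_that("simulation honours the output grid and is deterministic", {
  p <- base_params
  prof <- acute_hypocalcemia_profile(0.05, 30, 90)
  grid <- seq(0, 240, by = 2.5)
  tr1 <- simulate_ptg(p, prof, t_span = c(0, 240), output_grid = grid)
  expect_identical(nrow(tr1), length(grid))
  expect_identical(tr1$time_min, grid)
  expect_identical(ncol(tr1), 29L)
  tr2 <- simulate_ptg(p, prof, t_span = c(0, 240), output_grid = grid)
  expect_identical(tr1, tr2)
  expect_error(simulate_ptg(p, prof, t_span = c(0, 240),
                            output_grid = c(0, 300)), "within t_span")
})

test_that("integration failure under ill-posed inputs names the failing time", {
  # sustained marked hypercalcemia drives the signaling activities beyond
  # their finite-fixed-point region (net stimulus above n/p); the solver must
  # fail loudly with the failing time rather than return garbage
  p <- base_params
  hyper <- input_profile(c(0, 10), ca = c(5, 9), p = 4.5, d = 45,
                         duration = 5000)
  expect_error(simulate_ptg(p, hyper, t_span = c(0, 5000),
                            output_grid = c(0, 5000)),
               "integration failed.*t = ")
})

test_that("constant optimal inputs hold the steady state over a million minutes", {
  p <- base_params
  tr <- simulate_ptg(p, constant_profile(duration = 1e6),
                     t_span = c(0, 1e6), output_grid = c(0, 1e6))
  y0 <- steady_state(p)
  expect_lt(max(abs(as.numeric(tr[2, state_names()]) - unname(y0))), 1e-6)
})

test_that("halving the tolerances barely moves the terminal serum PTH", {
  p <- base_params
  prof <- acute_hypocalcemia_profile(0.05, 30, 90)
  a1 <- simulate_ptg(p, prof, t_span = c(0, 1440), output_grid = c(0, 1440))
  a2 <- simulate_ptg(p, prof, t_span = c(0, 1440), output_grid = c(0, 1440),
                     rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(a2$pth[2] - a1$pth[2]) / a1$pth[2], 1e-4)
})

test_that("short fixed-step RK4 and the adaptive solver agree", {
  # cheap version of the acceptance-level oracle comparison: 2 h of the fast
  # acute protocol, dt = 0.01 min
  p <- base_params
  prof <- acute_hypocalcemia_profile(0.05, 30, 90)
  rk <- integrate_rk4(p, prof, 0, 120, 0.01, record_every = 3000)
  ad <- simulate_ptg(p, prof, t_span = c(0, 120),
                     output_grid = rk$time_min[-1])
  A <- as.matrix(ad[, state_names()])
  R <- as.matrix(rk[-1, state_names()])
  expect_lt(max(abs(A - R) / pmax(abs(R), 1e-6)), 1e-4)
})
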