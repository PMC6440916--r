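# Shared fixtures for the suite. The model is deterministic; property tests
# that need random cases fix their own seeds.

base_params <- default_parameters()

# classical RK4 for a single effect state under a stimulus signal s_fun(t);
# independent scalar oracle for the effect-state dynamics
integrate_effect_state <- function(e0, s_fun, tau, t_end, dt) {
  e <- e0
  t <- 0
  n <- round(t_end / dt)
  f <- function(t, e) effect_state_rhs(e, s_fun(t), tau)
  for (i in seq_len(n)) {
    k1 <- f(t, e)
    k2 <- f(t + dt / 2, e + dt / 2 * k1)
    k3 <- f(t + dt / 2, e + dt / 2 * k2)
    k4 <- f(t + dt, e + dt * k3)
    e <- e + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- i * dt
  }
  e
}

# Random admissible input profile. Ranges stay inside the region where the
# signaling activities have finite fixed points (sustained net positive
# stimulus beyond n/p destabilizes the linear activity equations; see the
# methods vignette): calcium mildly hypo- to mildly hypercalcemic, phosphate
# optimal to strongly elevated, 1,25D across its full reference span.
random_profile <- function(duration = 2000, n_knots = 5) {
  times <- sort(c(0, runif(n_knots - 1, 0, duration)))
  input_profile(times,
                ca = runif(n_knots, 3.75, 5.25),
                p = runif(n_knots, 4, 9),
                d = runif(n_knots, 10, 90),
                duration = duration)
}
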