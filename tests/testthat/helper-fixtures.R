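# Shared fixtures for the test suite. Everything is built in code.

fixture_registry <- generate_fixture_registry()

# Fourth-order numerical integration of the logistic ODE, used as the
# independent oracle for the closed-form growth solution.
ode_grow <- function(B, r, K, duration) {
  out <- deSolve::ode(
    y = c(B = B), times = c(0, duration),
    func = function(t, y, parms) list(parms$r * y * (1 - y / parms$K)),
    parms = list(r = r, K = K),
    method = "ode45", rtol = 1e-10, atol = 1e-12)
  unname(out[nrow(out), "B"])
}

# Random valid growth parameter draws for property-style tests.
random_growth_cases <- function(n, seed) {
  set.seed(seed)
  data.frame(r_max = runif(n, 0.1, 3),
             B_max = runif(n, 50, 2000),
             b0_frac = runif(n, 0.001, 0.2),
             light = sample(c(1, 0.5, 0.25, runif(n, 0.05, 1)), n, replace = TRUE),
             duration = runif(n, 0, 50))
}
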