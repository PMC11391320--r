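single_meadow <- function(B) {
  patch_network(matrix(c(0, 1, 1, 0), 2, 2), biomass = c(0, B), disturbed = 1)
}

star <- function(B, n) {
  Q <- matrix(0, n + 1, n + 1)
  if (n > 0) { Q[1, -1] <- 1; Q[-1, 1] <- 1 }
  patch_network(Q, biomass = c(0, rep(B, n)), disturbed = 1)
}

test_that("patch network invariants are enforced", {
  expect_error(patch_network(matrix(c(0, 1, 0, 0), 2, 2), c(0, 10)), "symmetric")
  expect_error(patch_network(matrix(c(1, 1, 1, 0), 2, 2), c(0, 10)), "diagonal")
  expect_error(patch_network(matrix(c(0, 2, 2, 0), 2, 2), c(0, 10)), "0/1")
  expect_error(patch_network(matrix(c(0, 1, 1, 0), 2, 2), c(5, 10)),
               "zero biomass")
  expect_error(patch_network(matrix(c(0, 1, 1, 0), 2, 2), c(0, -1)),
               "non-negative")
})

test_that("dispersal probability matches direct scalar evaluation", {
  pars <- dispersal_params(L_max = 0.3, tau = 200, nu = 0.01)
  # one patch at B = 400: logistic argument is exactly +2
  expect_equal(annual_dispersal_probability(single_meadow(400), pars),
               0.3 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(round(annual_dispersal_probability(single_meadow(400), pars), 5),
               0.26424)
  # an isolated disturbed patch can never be recolonized
  expect_identical(annual_dispersal_probability(star(400, 0), pars), 0)
})

test_that("dispersal over identical patches equals the closed-form identity", {
  pars <- dispersal_params(L_max = 0.3, tau = 200, nu = 0.01)
  set.seed(11)
  for (i in 1:20) {
    B <- runif(1, 10, 1500)
    n <- sample(1:10, 1)
    p1 <- pars$L_max / (1 + exp(-pars$nu * (B - pars$tau)))
    # brute-force product oracle
    oracle <- 1 - prod(rep(1 - p1, n))
    expect_equal(annual_dispersal_probability(star(B, n), pars),
                 1 - (1 - p1)^n, tolerance = 1e-12)
    expect_equal(annual_dispersal_probability(star(B, n), pars), oracle,
                 tolerance = 1e-12)
  }
})

test_that("recolonization probabilities are monotone and bounded", {
  dpars <- dispersal_params(L_max = 0.3, tau = 200, nu = 0.01)
  rpars <- recruitment_params(R_max = 0.38, tau = 200, nu = 0.01)
  # non-decreasing in each connected patch's biomass
  Bs <- seq(10, 2000, length.out = 25)
  pd <- vapply(Bs, function(B) annual_dispersal_probability(single_meadow(B), dpars),
               numeric(1))
  pr <- vapply(Bs, function(B) annual_recruitment_probability(single_meadow(B), rpars),
               numeric(1))
  expect_true(all(diff(pd) > 0))
  expect_true(all(diff(pr) > 0))
  # non-decreasing in L_max / R_max
  pd2 <- annual_dispersal_probability(single_meadow(400),
                                      dispersal_params(0.6, 200, 0.01))
  expect_gt(pd2, pd[which.min(abs(Bs - 400))])
  # dispersal grows towards 1 with connections; recruitment is capped at R_max
  pn <- vapply(1:40, function(n) annual_dispersal_probability(star(400, n), dpars),
               numeric(1))
  expect_true(all(diff(pn) > 0))
  expect_true(all(pn < 1))
  expect_gt(pn[40], 0.999)
  prn <- vapply(1:40, function(n) annual_recruitment_probability(star(400, n), rpars),
                numeric(1))
  expect_true(all(diff(prn) >= 0))
  expect_true(all(prn <= rpars$R_max))
})

test_that("recruitment probability follows the summed-biomass logistic", {
  pars <- recruitment_params(R_max = 0.38, tau = 200, nu = 0.01)
  # summed connected biomass at tau is the logistic midpoint
  expect_equal(annual_recruitment_probability(star(100, 2), pars), 0.38 / 2,
               tolerance = 1e-12)
  expect_equal(annual_recruitment_probability(single_meadow(400), pars),
               0.38 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(round(annual_recruitment_probability(single_meadow(400), pars), 5),
               0.33470)
  # saturation towards R_max, and the degree-0 convention
  expect_equal(annual_recruitment_probability(star(1e6, 5), pars), 0.38,
               tolerance = 1e-9)
  expect_identical(annual_recruitment_probability(star(400, 0), pars), 0)
})

test_that("tau calibration inverts the logistic curve exactly", {
  # midpoint: target at half the maximum sits exactly at the reference biomass
  expect_equal(calibrate_tau(0.15, 0.3, nu = 0.01, reference_biomass = 350), 350)
  tau <- calibrate_tau(0.24, 0.375, nu = 0.01, reference_biomass = 600)
  expect_equal(tau, 600 - log(0.64 / 0.36) / 0.01, tolerance = 1e-12)
  expect_equal(round(tau, 2), 542.46)
  # residual: the calibrated curve reproduces the target probability
  p_at_ref <- annual_dispersal_probability(
    single_meadow(600), dispersal_params(0.375, tau, 0.01))
  expect_lt(abs(p_at_ref - 0.24), 1e-10)
  # numeric root-finding oracle agrees with the closed form
  root <- uniroot(function(tt) 0.375 / (1 + exp(-0.01 * (600 - tt))) - 0.24,
                  c(1, 5000), tol = 1e-12)$root
  expect_equal(tau, root, tolerance = 1e-8)
  # infeasible targets are rejected, as is a tau <= 0 solution
  expect_error(calibrate_tau(0.4, 0.375, 0.01, 600), "infeasible")
  expect_error(calibrate_tau(0.375, 0.375, 0.01, 600), "infeasible")
  expect_error(calibrate_tau(0.3749999999, 0.375, 0.01, 600), "tau > 0")
})

test_that("recolonization parameter invariants are enforced", {
  expect_error(dispersal_params(1.5, 200, 0.01), "L_max")
  expect_error(dispersal_params(0.3, -1, 0.01), "tau")
  expect_error(recruitment_params(0.38, 200, 0), "nu")
  expect_error(recruitment_params(0, 200, 0.01), "R_max")
})
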