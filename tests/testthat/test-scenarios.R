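reg <- fixture_registry
zgp <- registry_growth(reg, "zostera-like")

test_that("star networks have the expected structure", {
  net <- build_network(3, zgp, light_scenario(1))
  expect_equal(dim(net$Q), c(4, 4))
  expect_true(all(net$Q == t(net$Q)))
  expect_true(all(diag(net$Q) == 0))
  expect_equal(sum(net$Q[1, ]), 3)
  expect_equal(net$biomass, c(0, rep(600, 3)))
  # stressed light lowers every remnant's biomass
  net_lo <- build_network(3, zgp, 0.5)
  expect_equal(net_lo$biomass[-1], rep(300, 3))
  iso <- build_network(0, zgp, 1)
  expect_equal(dim(iso$Q), c(1, 1))
  expect_equal(sum(iso$Q), 0)
})

test_that("management actions map onto the documented policies", {
  mk <- function(model, mgmt, light = 0.5)
    apply_management(scenario("zostera-like", model, 1, light, mgmt))
  expect_equal(mk("dispersal", "none")$override, "none")
  expect_equal(mk("dispersal", "seed")$override, "certain")
  expect_equal(mk("recruitment", "seed")$override, "saturated")
  expect_equal(mk("recruitment", "stabilize")$override, "certain")
  expect_equal(mk("dispersal", "stabilize")$override, "none")
  pol <- mk("dispersal", "light")
  expect_equal(pol$light$light_fraction, 1)
  expect_equal(pol$override, "none")
  # the lmax robustness variant for seeding under dispersal
  s <- scenario("zostera-like", "dispersal", 1, 0.5, "seed")
  expect_equal(apply_management(s, "lmax")$override, "lmax")
  s$management <- "dredge"
  expect_error(apply_management(s), "unknown management")
  expect_error(scenario("zostera-like", "dispersal", 1, 0.5, "dredge"))
})

test_that("stabilizing recruitment is a no-op under uncertain dispersal", {
  base <- run_scenario(scenario("zostera-like", "dispersal", 2, 0.5, "none"), reg)
  stab <- run_scenario(scenario("zostera-like", "dispersal", 2, 0.5, "stabilize"), reg)
  expect_identical(stab$annual_probability, base$annual_probability)
  expect_identical(stab$distribution$rate, base$distribution$rate)
  expect_identical(stab$summary, base$summary)
  expect_equal(years_saved(stab, base), 0)
})

test_that("seeding collapses dispersal uncertainty to pure regrowth", {
  seeded <- run_scenario(scenario("zostera-like", "dispersal", 1, 1, "seed"), reg)
  t_grow <- time_to_fraction(zgp, 1)
  expect_equal(seeded$annual_probability, 1)
  expect_equal(seeded$summary$median, t_grow)
  expect_equal(seeded$summary$q975, t_grow)
  # under uncertain recruitment, seeding caps the probability at R_max,
  # which equals the baseline once supply already saturates the curve
  base_hi <- run_scenario(scenario("zostera-like", "recruitment", 10, 1, "none"), reg)
  seed_hi <- run_scenario(scenario("zostera-like", "recruitment", 10, 1, "seed"), reg)
  expect_equal(seed_hi$annual_probability, reg$recruitment$R_max)
  expect_equal(seed_hi$summary$median, base_hi$summary$median, tolerance = 1e-4)
})

test_that("recovery medians fall with connectivity and plateau under recruitment", {
  grid <- run_scenario_grid(reg, species = "zostera-like", n_connected = 1:10,
                            light_fraction = 1)
  disp <- grid[grid$model == "dispersal", ]
  recr <- grid[grid$model == "recruitment", ]
  disp <- disp[order(disp$n_connected), ]
  recr <- recr[order(recr$n_connected), ]
  expect_true(all(diff(disp$median) < 0))          # strictly decreasing
  expect_true(all(diff(recr$median) <= 1e-12))     # non-increasing
  plateau <- recr$median[recr$n_connected >= 3]
  expect_lt(max(plateau) - min(plateau), 0.01)     # flat at its minimum
  # every recovery time is bounded below by the growth translation
  expect_true(all(grid$median >= grid$t_grow))
  expect_true(all(grid$q025 >= grid$t_grow))
})

test_that("low-light stress slows recovery most at low connectivity", {
  for (model in c("dispersal", "recruitment")) {
    g <- run_scenario_grid(reg, species = "zostera-like", model = model,
                           n_connected = 1:10, light_fraction = c(1, 0.25))
    lo <- g[g$light_fraction == 0.25, ]; lo <- lo[order(lo$n_connected), ]
    hi <- g[g$light_fraction == 1, ]; hi <- hi[order(hi$n_connected), ]
    expect_true(all(lo$median > hi$median))
    expect_true(all(lo$q975 - lo$q025 >= hi$q975 - hi$q025))
    gap <- lo$median - hi$median
    expect_true(all(diff(gap) < 0))    # stress penalty shrinks with connections
  }
  # under uncertain recruitment the waiting-time law converges across light
  # scenarios once supply saturates the curve (centred on the growth time)
  centred <- function(l) {
    r <- run_scenario(scenario("zostera-like", "recruitment", 10, l), reg)
    r$summary$median - r$distribution$translation
  }
  waits <- vapply(c(1, 0.5, 0.25), centred, numeric(1))
  expect_lt(max(waits) - min(waits), 0.01 * min(waits) + 1e-6)
})

test_that("years saved is non-negative and largest for low light and connectivity", {
  cells <- expand.grid(model = c("dispersal", "recruitment"),
                       n = c(1, 8), l = c(1, 0.25), stringsAsFactors = FALSE)
  saved <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    base <- run_scenario(scenario("zostera-like", cl$model, cl$n, cl$l, "none"), reg)
    data.frame(cl, t(vapply(c("seed", "stabilize", "light"), function(a) {
      m <- run_scenario(scenario("zostera-like", cl$model, cl$n, cl$l, a), reg)
      c(saved = years_saved(m, base))
    }, numeric(1))))
  }))
  expect_true(all(saved$seed >= 0 & saved$stabilize >= 0 & saved$light >= 0))
  best_gain <- apply(saved[, c("seed", "stabilize", "light")], 1, max)
  worst_cell <- saved$n == 1 & saved$l == 0.25
  for (model in c("dispersal", "recruitment")) {
    m <- saved$model == model
    expect_equal(unname(which.max(best_gain[m])), which(worst_cell[m]))
  }
  # seeding under dispersal saves exactly the median waiting time
  base <- run_scenario(scenario("zostera-like", "dispersal", 1, 1, "none"), reg)
  seeded <- run_scenario(scenario("zostera-like", "dispersal", 1, 1, "seed"), reg)
  expect_equal(years_saved(seeded, base),
               log(2) / base$distribution$rate, tolerance = 1e-12)
  # mismatched axes are refused
  other <- run_scenario(scenario("zostera-like", "dispersal", 2, 1, "none"), reg)
  expect_error(years_saved(seeded, other), "n_connected")
})

test_that("analytic and simulated scenario summaries agree", {
  cfg <- sim_config(n_reps = 4e4, seed = 21)
  ana <- run_scenario(scenario("zostera-like", "dispersal", 3, 0.5), reg)
  sim <- run_scenario(scenario("zostera-like", "dispersal", 3, 0.5), reg,
                      mode = "simulate", config = cfg)
  expect_equal(sim$annual_probability, ana$annual_probability)
  for (col in c("median", "q125", "q875", "q025", "q975"))
    expect_lt(abs(sim$summary[[col]] - ana$summary[[col]]),
              max(0.02 * ana$summary[[col]], 0.05))
})

test_that("parameter sweeps reproduce the base case and flag infeasible cells", {
  base <- scenario("zostera-like", "dispersal", 1, 1)
  base_res <- run_scenario(base, reg)
  sw <- sweep_parameter(base, "tau", registry = reg)
  expect_equal(nrow(sw), 9)
  expect_equal(sw$multiplier[5], 1)
  expect_equal(sw$median[5], base_res$summary$median, tolerance = 1e-12)
  expect_true(all(sw$feasible))
  # recovery time never speeds up as the productivity parameter grows
  expect_true(all(diff(sw$median) >= 0))
  # recruitment with many connected patches stays saturated across tau
  swr <- sweep_parameter(scenario("zostera-like", "recruitment", 10, 1), "tau",
                         registry = reg)
  expect_lt(max(swr$median) - min(swr$median), 0.05)
  # multipliers pushing L_max beyond 1 are flagged infeasible, not dropped
  swL <- sweep_parameter(base, "L_max", registry = reg)
  expect_equal(nrow(swL), 9)
  bad <- swL$value > 1
  expect_true(any(bad))
  expect_true(all(!swL$feasible[bad]))
  expect_true(all(is.na(swL$median[bad])))
  expect_true(all(swL$feasible[!bad]))
})

test_that("the best action is model-specific and robust to tau", {
  ba_d <- best_action(reg, "zostera-like", "dispersal", 1, 1)
  expect_equal(ba_d$best, "seed")
  ba_r <- best_action(reg, "zostera-like", "recruitment", 1, 1)
  expect_equal(ba_r$best, "stabilize")
  # ties are reported as sets: none and light coincide at normal light
  tied <- ba_r$ranking[ba_r$ranking$action %in% c("none", "light"), ]
  expect_equal(tied$rank[1], tied$rank[2])
  # the winner is invariant across the tau sweep for fixed model/connectivity
  for (m in sweep_factors()) {
    reg_m <- parameter_registry(
      species = lapply(reg$species, `[[`, "growth"),
      dispersal = dispersal_params(reg$dispersal$L_max,
                                   reg$dispersal$tau * m, reg$dispersal$nu),
      recruitment = recruitment_params(reg$recruitment$R_max,
                                       reg$recruitment$tau * m,
                                       reg$recruitment$nu))
    expect_equal(best_action(reg_m, "zostera-like", "dispersal", 1, 1)$best,
                 "seed")
    expect_equal(best_action(reg_m, "zostera-like", "recruitment", 1, 1)$best,
                 "stabilize")
  }
})
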