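#' Default multiplier grid for sensitivity sweeps
#'
#' Nine log-spaced multipliers from a four-times reduction to a four-times
#' increase (0.25 to 4), centred on 1; an eight-fold span is wide enough to
#' cover the biologically plausible range of the recolonization parameters.
#'
#' @param n Number of multipliers (odd values keep 1 on the grid).
#' @return Numeric vector of multipliers.
#' @export
sweep_factors <- function(n = 9L) {
  exp(seq(log(0.25), log(4), length.out = n))
}

#' Sensitivity sweep over one parameter
#'
#' Re-runs a base scenario with one parameter multiplied by each factor in
#' turn, holding everything else fixed. `tau` and `nu` are shared by the
#' two recolonization curves and are scaled in both; `L_max` / `R_max`
#' scale their own curve; `r_max` / `B_max` scale the base species' growth
#' parameters (the colonization biomass `B0` is a distinct parameter and is
#' held fixed). A multiplier that violates a parameter invariant (for
#' example `L_max * m > 1`) is flagged `feasible = FALSE` with the message,
#' never dropped silently.
#'
#' @param base A [scenario()] giving the cell to perturb.
#' @param parameter One of `"L_max"`, `"R_max"`, `"tau"`, `"nu"`,
#'   `"r_max"`, `"B_max"`.
#' @param factors Multipliers; default [sweep_factors()].
#' @param registry A [parameter_registry()].
#' @param mode,config,seed_dispersal,hazard_map Passed to [run_scenario()].
#' @return A `data.frame` with one row per multiplier: `parameter`,
#'   `multiplier`, `value` (the scaled parameter), `feasible`, `message`,
#'   `annual_probability` and the recovery-time summary columns.
#' @export
sweep_parameter <- function(base, parameter, factors = sweep_factors(),
                            registry, mode = "analytic",
                            config = sim_config(),
                            seed_dispersal = "immediate",
                            hazard_map = "matched-annual") {
  stopifnot(inherits(base, "scenario"), inherits(registry, "parameter_registry"))
  parameter <- match.arg(parameter,
                         c("L_max", "R_max", "tau", "nu", "r_max", "B_max"))
  base_value <- switch(parameter,
    L_max = registry$dispersal$L_max,
    R_max = registry$recruitment$R_max,
    tau = registry$dispersal$tau,
    nu = registry$dispersal$nu,
    r_max = registry_growth(registry, base$species)$r_max,
    B_max = registry_growth(registry, base$species)$B_max)
  rows <- lapply(factors, function(m) {
    out <- data.frame(parameter = parameter, multiplier = m,
                      value = base_value * m, feasible = TRUE,
                      message = NA_character_)
    res <- tryCatch({
      reg_m <- scale_registry_parameter(registry, base$species, parameter, m)
      run_scenario(base, reg_m, mode = mode, config = config,
                   seed_dispersal = seed_dispersal, hazard_map = hazard_map)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$feasible <- FALSE
      out$message <- conditionMessage(res)
      cbind(out, annual_probability = NA_real_, rate = NA_real_,
            t_grow = NA_real_,
            data.frame(median = NA_real_, q125 = NA_real_, q875 = NA_real_,
                       q025 = NA_real_, q975 = NA_real_, mean = NA_real_,
                       n = NA_integer_, n_censored = NA_integer_,
                       frac_censored = NA_real_))
    } else {
      cbind(out, annual_probability = res$annual_probability,
            rate = res$distribution$rate,
            t_grow = res$distribution$translation, res$summary)
    }
  })
  do.call(rbind, rows)
}

# Return a copy of the registry with one parameter scaled by m, revalidated
# through the constructors so invariant violations surface as errors.
scale_registry_parameter <- function(registry, species, parameter, m) {
  d <- registry$dispersal
  r <- registry$recruitment
  sp <- registry$species
  g <- sp[[species]]$growth
  switch(parameter,
    L_max = { d <- dispersal_params(d$L_max * m, d$tau, d$nu) },
    R_max = { r <- recruitment_params(r$R_max * m, r$tau, r$nu) },
    tau = {
      d <- dispersal_params(d$L_max, d$tau * m, d$nu)
      r <- recruitment_params(r$R_max, r$tau * m, r$nu)
    },
    nu = {
      d <- dispersal_params(d$L_max, d$tau, d$nu * m)
      r <- recruitment_params(r$R_max, r$tau, r$nu * m)
    },
    r_max = {
      sp[[species]]$growth <- growth_params(g$r_max * m, g$B_max, g$B0,
                                            g$light_response)
    },
    B_max = {
      sp[[species]]$growth <- growth_params(g$r_max, g$B_max * m, g$B0,
                                            g$light_response)
    })
  parameter_registry(sp, d, r, provenance = "sweep")
}

#' Rank management actions for one scenario cell
#'
#' Runs each candidate action on the same (species, model, connectivity,
#' light) cell and ranks them by a recovery-time statistic. Ties (within
#' `tol` years) are reported as sets — the winner is every action whose
#' statistic is within `tol` of the minimum — with no arbitrary
#' tie-breaking.
#'
#' @param registry A [parameter_registry()].
#' @param species,model,n_connected,light Scenario axes (see [scenario()]).
#' @param actions Candidate management actions, length >= 2.
#' @param statistic Summary column to rank on (default `"median"`).
#' @param fraction Recovery threshold.
#' @param mode,config,seed_dispersal,hazard_map Passed to [run_scenario()].
#' @param tol Tie tolerance in years.
#' @return A list of class `action_ranking`: `ranking` (data frame sorted
#'   by the statistic, with tie-aware `rank`) and `best` (character vector
#'   of all co-winners).
#' @export
best_action <- function(registry, species, model, n_connected, light,
                        actions = c("none", "seed", "stabilize", "light"),
                        statistic = "median", fraction = 0.5,
                        mode = "analytic", config = sim_config(),
                        seed_dispersal = "immediate",
                        hazard_map = "matched-annual", tol = 1e-9) {
  if (length(actions) < 2L) stop("need at least two actions to rank")
  vals <- vapply(actions, function(a) {
    res <- run_scenario(scenario(species, model, n_connected, light, a, fraction),
                        registry, mode = mode, config = config,
                        seed_dispersal = seed_dispersal, hazard_map = hazard_map)
    res$summary[[statistic]]
  }, numeric(1))
  ord <- order(vals)
  ranking <- data.frame(action = actions[ord], statistic = statistic,
                        years = vals[ord], row.names = NULL)
  # tie-aware ranks: equal (within tol) values share the lowest rank
  rk <- integer(nrow(ranking))
  rk[1] <- 1L
  for (i in seq_len(nrow(ranking))[-1]) {
    rk[i] <- if (ranking$years[i] - ranking$years[i - 1] <= tol) rk[i - 1] else i
  }
  ranking$rank <- rk
  best <- ranking$action[ranking$years <= min(ranking$years) + tol]
  structure(list(ranking = ranking, best = best), class = "action_ranking")
}

#' @export
print.action_ranking <- function(x, ...) {
  cat("Management action ranking (", x$ranking$statistic[1], " recovery time):\n",
      sep = "")
  print(x$ranking, row.names = FALSE)
  cat("best:", paste(x$best, collapse = ", "), "\n")
  invisible(x)
}
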