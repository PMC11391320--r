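#' Define a recovery scenario
#'
#' One cell of the factorial design: species, source of recolonization
#' uncertainty, number of connected remnant patches, chronic light stress,
#' management action and recovery threshold.
#'
#' @param species Species name (resolved against a [parameter_registry()]
#'   when the scenario is run).
#' @param model `"dispersal"` (uncertain dispersal) or `"recruitment"`
#'   (uncertain recruitment).
#' @param n_connected Number of connected remnant patches acting as
#'   propagule sources, >= 0 (the study grids use 1-10).
#' @param light A [light_scenario()] or bare light fraction in (0, 1].
#' @param management `"none"`, `"seed"` (spread propagules / plant),
#'   `"stabilize"` (stabilize recruitment conditions) or `"light"`
#'   (mitigate the chronic light stressor).
#' @param fraction Recovery threshold as a fraction of the light-specific
#'   equilibrium biomass, default 0.5.
#' @return An object of class `scenario`.
#' @seealso [run_scenario()], [apply_management()]
#' @export
scenario <- function(species, model = c("dispersal", "recruitment"),
                     n_connected, light,
                     management = c("none", "seed", "stabilize", "light"),
                     fraction = 0.5) {
  model <- match.arg(model)
  management <- match.arg(management)
  stopifnot(is.character(species), length(species) == 1L,
            is.numeric(n_connected), length(n_connected) == 1L)
  n_connected <- as.integer(n_connected)
  if (is.na(n_connected) || n_connected < 0L)
    stop("'n_connected' must be a count >= 0")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie in (0, 1)")
  structure(list(species = species, model = model,
                 n_connected = n_connected,
                 light = as_light_scenario(light),
                 management = management,
                 fraction = as.numeric(fraction)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario: %s | %s model | %d connected patch(es) | light %g | management %s | threshold %g\n",
              x$species, x$model, x$n_connected, x$light$light_fraction,
              x$management, x$fraction))
  invisible(x)
}

#' Build the star network of a scenario cell
#'
#' One disturbed patch (index 1, biomass 0) connected to `n_connected`
#' identical remnant patches, each at the light-specific equilibrium
#' biomass. All patches share growth parameters and light level, matching
#' the design in which every source patch has the same size and propagule
#' production rate.
#'
#' @param n_connected Number of remnant patches, >= 0.
#' @param growth A [growth_params()] object.
#' @param light A [light_scenario()] or bare light fraction.
#' @return A [patch_network()] with `n_connected + 1` patches.
#' @export
build_network <- function(n_connected, growth, light) {
  n_connected <- as.integer(n_connected)
  if (is.na(n_connected) || n_connected < 0L)
    stop("'n_connected' must be a count >= 0")
  n <- n_connected + 1L
  Q <- matrix(0, n, n)
  if (n_connected > 0L) {
    Q[1, 2:n] <- 1
    Q[2:n, 1] <- 1
  }
  B_eq <- equilibrium_biomass(growth, light)
  patch_network(Q, biomass = c(0, rep(B_eq, n_connected)), disturbed = 1L)
}

#' Translate a management action into an effective recolonization policy
#'
#' Management actions act on different parts of the model:
#' \describe{
#'   \item{seed}{Spreading propagules or planting saturates propagule supply
#'     at the disturbed patch. Under the dispersal model this removes the
#'     only stochastic step, so colonization is immediate (p = 1 by default;
#'     set `seed_dispersal = "lmax"` to cap it at `L_max` instead as a
#'     robustness check). Under the recruitment model arrivals still have to
#'     recruit, so the probability is the saturation value `R_max`.}
#'   \item{stabilize}{Stabilizing recruitment conditions (e.g. sediment
#'     stabilization) makes recruitment certain. Under the recruitment model
#'     colonization becomes immediate; under the dispersal model recruitment
#'     was already certain, so nothing changes.}
#'   \item{light}{Mitigating the chronic stressor restores the light
#'     fraction to 1; the recolonization model itself is unchanged.}
#'   \item{none}{Baseline; nothing changes.}
#' }
#'
#' @param scn A [scenario()].
#' @param seed_dispersal `"immediate"` (default) or `"lmax"`: how seeding is
#'   modelled under the dispersal model.
#' @return A list of class `recolonization_policy` with elements `light`
#'   (the effective [light_scenario()]) and `override` (`"none"`,
#'   `"certain"`, `"saturated"` or `"lmax"`).
#' @export
apply_management <- function(scn, seed_dispersal = c("immediate", "lmax")) {
  stopifnot(inherits(scn, "scenario"))
  seed_dispersal <- match.arg(seed_dispersal)
  light <- scn$light
  override <- "none"
  switch(scn$management,
    none = NULL,
    light = { light <- light_scenario(1) },
    seed = {
      override <- if (scn$model == "dispersal") {
        if (seed_dispersal == "immediate") "certain" else "lmax"
      } else "saturated"
    },
    stabilize = {
      if (scn$model == "recruitment") override <- "certain"
    },
    stop("unknown management action '", scn$management, "'")
  )
  structure(list(light = light, override = override),
            class = "recolonization_policy")
}

#' Run one scenario
#'
#' Composes the pipeline for a single factorial cell: apply the management
#' action, build the star network at the effective light level, evaluate the
#' annual recolonization probability under the scenario's uncertainty model,
#' and form the recovery-time distribution — analytically (deterministic) or
#' by Monte Carlo simulation.
#'
#' @param scn A [scenario()].
#' @param registry A [parameter_registry()] resolving the scenario species.
#' @param mode `"analytic"` (default) or `"simulate"`.
#' @param config A [sim_config()]; used in simulate mode.
#' @param seed_dispersal Passed to [apply_management()].
#' @param hazard_map Passed to [analytic_distribution()].
#' @return An object of class `scenario_result`: list with the scenario,
#'   `annual_probability`, the analytic `distribution`, a one-row `summary`
#'   data frame (see [summarize_samples()]) and the mode. A probability of
#'   0 (isolated patch, no management) yields the no-recovery sentinel
#'   distribution with infinite quantiles.
#' @examples
#' reg <- generate_fixture_registry()
#' run_scenario(scenario("zostera-like", "dispersal", 1, 1), reg)
#' @export
run_scenario <- function(scn, registry, mode = c("analytic", "simulate"),
                         config = sim_config(),
                         seed_dispersal = c("immediate", "lmax"),
                         hazard_map = "matched-annual") {
  mode <- match.arg(mode)
  stopifnot(inherits(scn, "scenario"))
  growth <- registry_growth(registry, scn$species)
  policy <- apply_management(scn, seed_dispersal)
  network <- build_network(scn$n_connected, growth, policy$light)
  p <- switch(policy$override,
    certain = 1,
    saturated = registry$recruitment$R_max,
    lmax = registry$dispersal$L_max,
    none = if (scn$model == "dispersal") {
      annual_dispersal_probability(network, registry$dispersal)
    } else {
      annual_recruitment_probability(network, registry$recruitment)
    }
  )
  dist <- analytic_distribution(p, growth, policy$light, scn$fraction,
                                hazard_map)
  summary <- if (mode == "analytic") {
    summarize_distribution(dist)
  } else {
    summarize_samples(simulate_recovery_times(p, growth, policy$light,
                                              scn$fraction, config))
  }
  structure(list(scenario = scn, annual_probability = p,
                 distribution = dist, summary = summary, mode = mode,
                 config = if (mode == "simulate") config else NULL),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("  annual recolonization probability: %.4g (%s mode)\n",
              x$annual_probability, x$mode))
  s <- x$summary
  cat(sprintf("  median %.3g years, 75%% interval [%.3g, %.3g], 95%% interval [%.3g, %.3g]\n",
              s$median, s$q125, s$q875, s$q025, s$q975))
  invisible(x)
}

#' Run a factorial grid of scenarios
#'
#' Expands the supplied axes into every factorial combination, runs each
#' cell with [run_scenario()], and returns a tidy table with one row per
#' cell: the scenario columns followed by the annual probability, the
#' hazard rate and growth translation, and the recovery-time summary
#' statistics.
#'
#' @param registry A [parameter_registry()].
#' @param species,model,n_connected,light_fraction,management Axis values
#'   (vectors); defaults cover the core study grid for every registry
#'   species.
#' @param fraction Recovery threshold, a single value.
#' @param mode,config,seed_dispersal,hazard_map Passed to [run_scenario()].
#' @return A `data.frame`, one row per factorial cell.
#' @export
run_scenario_grid <- function(registry,
                              species = names(registry$species),
                              model = c("dispersal", "recruitment"),
                              n_connected = 1:10,
                              light_fraction = c(1, 0.5, 0.25),
                              management = "none",
                              fraction = 0.5,
                              mode = c("analytic", "simulate"),
                              config = sim_config(),
                              seed_dispersal = "immediate",
                              hazard_map = "matched-annual") {
  mode <- match.arg(mode)
  cells <- expand.grid(species = species, model = model,
                       n_connected = n_connected,
                       light_fraction = light_fraction,
                       management = management,
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    res <- run_scenario(
      scenario(cell$species, cell$model, cell$n_connected,
               cell$light_fraction, cell$management, fraction),
      registry, mode = mode, config = config,
      seed_dispersal = seed_dispersal, hazard_map = hazard_map)
    cbind(cell,
          fraction = fraction,
          annual_probability = res$annual_probability,
          rate = res$distribution$rate,
          t_grow = res$distribution$translation,
          res$summary,
          row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Years of recovery time saved by a management action
#'
#' Difference in a recovery-time statistic between the no-management
#' baseline and a managed scenario sharing the same species, uncertainty
#' model, connectivity and recovery threshold (the light level may differ:
#' that is exactly what the `"light"` action changes). Under this model no
#' implemented action can slow recovery, so the saving is never negative.
#'
#' @param managed,baseline `scenario_result` objects from [run_scenario()].
#' @param statistic Summary column to compare: `"median"` (default),
#'   `"mean"`, `"q125"`, `"q875"`, `"q025"` or `"q975"`.
#' @return Years saved (baseline minus managed).
#' @export
years_saved <- function(managed, baseline, statistic = "median") {
  stopifnot(inherits(managed, "scenario_result"),
            inherits(baseline, "scenario_result"))
  statistic <- match.arg(statistic,
                         c("median", "mean", "q125", "q875", "q025", "q975"))
  for (ax in c("species", "model", "n_connected", "fraction")) {
    if (!identical(managed$scenario[[ax]], baseline$scenario[[ax]]))
      stop("cannot compare scenarios that differ in '", ax, "' (",
           managed$scenario[[ax]], " vs ", baseline$scenario[[ax]], ")")
  }
  baseline$summary[[statistic]] - managed$summary[[statistic]]
}
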