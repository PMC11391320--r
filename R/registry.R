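#' Parameter registry
#'
#' Named growth-parameter entries for one or more species, plus the shared
#' recolonization parameter sets for the two uncertainty models. Every
#' entry carries a provenance note (for example `"placeholder"` or a
#' literature citation) that propagates into output metadata, so calibrated
#' stand-in values are never silently confused with field estimates.
#'
#' @param species Named list; each element is either a [growth_params()]
#'   object or a list with elements `growth` (a [growth_params()]) and
#'   `provenance` (character).
#' @param dispersal A [dispersal_params()] object.
#' @param recruitment A [recruitment_params()] object.
#' @param provenance Default provenance tag applied where an entry supplies
#'   none.
#' @return An object of class `parameter_registry`.
#' @seealso [generate_fixture_registry()], [registry_growth()]
#' @export
parameter_registry <- function(species, dispersal, recruitment,
                               provenance = "user") {
  stopifnot(is.list(species), length(species) >= 1L,
            inherits(dispersal, "dispersal_params"),
            inherits(recruitment, "recruitment_params"))
  if (is.null(names(species)) || any(!nzchar(names(species))))
    stop("'species' must be a fully named list")
  species <- lapply(species, function(sp) {
    if (inherits(sp, "growth_params"))
      sp <- list(growth = sp, provenance = provenance)
    if (!inherits(sp$growth, "growth_params"))
      stop("each species entry must contain a 'growth_params' object")
    if (is.null(sp$provenance)) sp$provenance <- provenance
    sp[c("growth", "provenance")]
  })
  structure(list(species = species,
                 dispersal = dispersal,
                 recruitment = recruitment,
                 provenance = list(
                   dispersal = attr(dispersal, "provenance") %||% provenance,
                   recruitment = attr(recruitment, "provenance") %||% provenance)),
            class = "parameter_registry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.parameter_registry <- function(x, ...) {
  cat("Parameter registry\n  species:\n")
  for (nm in names(x$species)) {
    sp <- x$species[[nm]]
    cat(sprintf("    %-14s r_max = %-5g B_max = %-8.6g B0 = %-8.4g [%s]\n",
                nm, sp$growth$r_max, sp$growth$B_max, sp$growth$B0,
                sp$provenance))
  }
  cat(sprintf("  dispersal:   L_max = %g, tau = %g, nu = %g [%s]\n",
              x$dispersal$L_max, x$dispersal$tau, x$dispersal$nu,
              x$provenance$dispersal))
  cat(sprintf("  recruitment: R_max = %g, tau = %g, nu = %g [%s]\n",
              x$recruitment$R_max, x$recruitment$tau, x$recruitment$nu,
              x$provenance$recruitment))
  invisible(x)
}

#' Look up a species' growth parameters
#'
#' @param registry A [parameter_registry()].
#' @param species Species name present in the registry.
#' @return The species' [growth_params()].
#' @export
registry_growth <- function(registry, species) {
  stopifnot(inherits(registry, "parameter_registry"))
  if (!species %in% names(registry$species))
    stop("species '", species, "' not found in the registry (available: ",
         paste(names(registry$species), collapse = ", "), ")")
  registry$species[[species]]$growth
}

#' Generate the bundled placeholder parameter registry
#'
#' Builds a fully specified registry for two seagrass-like species so the
#' package runs end-to-end with no external data. All values are tagged
#' `"placeholder"`: direct field estimates of the recolonization curves are
#' unavailable, so the curve is pinned by calibration instead. Both species
#' share one recolonization curve (`L_max = R_max = 0.375`, `nu = 0.01`
#' per g dry wt m^-2); `tau` is calibrated with [calibrate_tau()] so that a
#' single remnant meadow at the zostera-like equilibrium biomass
#' (600 g dry wt m^-2) yields an annual recolonization probability of 0.24,
#' and the halodule-like equilibrium biomass is placed where the same curve
#' yields 0.32. Growth rates (2.0 and 1.6 per year) are set so recovery
#' plays out over the years-to-decades horizon reported for these taxa.
#'
#' @param seed Integer recorded with the registry for interface symmetry;
#'   the construction is fully deterministic.
#' @return A [parameter_registry()] with species `"zostera-like"` and
#'   `"halodule-like"`, all provenance tags `"placeholder"`.
#' @examples
#' reg <- generate_fixture_registry()
#' net <- build_network(1, registry_growth(reg, "zostera-like"), light_scenario(1))
#' annual_dispersal_probability(net, reg$dispersal)  # 0.24 by calibration
#' @export
generate_fixture_registry <- function(seed = 1L) {
  p_max <- 0.375
  nu <- 0.01
  B_zostera <- 600
  tau <- calibrate_tau(0.24, p_max, nu, B_zostera)
  # Biomass at which the shared curve gives the halodule-like target 0.32.
  B_halodule <- tau - log(p_max / 0.32 - 1) / nu
  reg <- parameter_registry(
    species = list(
      "zostera-like" = growth_params(r_max = 2.0, B_max = B_zostera),
      "halodule-like" = growth_params(r_max = 1.6, B_max = B_halodule)
    ),
    dispersal = dispersal_params(L_max = p_max, tau = tau, nu = nu),
    recruitment = recruitment_params(R_max = p_max, tau = tau, nu = nu),
    provenance = "placeholder"
  )
  attr(reg, "seed") <- as.integer(seed)
  reg
}

# Flatten a registry to plain named lists for metadata / config output.
registry_as_list <- function(registry) {
  list(
    species = lapply(registry$species, function(sp) {
      list(r_max = sp$growth$r_max, B_max = sp$growth$B_max,
           B0 = sp$growth$B0,
           light_response = if (is.character(sp$growth$light_response))
             sp$growth$light_response else "custom-function",
           provenance = sp$provenance)
    }),
    dispersal = list(L_max = registry$dispersal$L_max,
                     tau = registry$dispersal$tau,
                     nu = registry$dispersal$nu,
                     provenance = registry$provenance$dispersal),
    recruitment = list(R_max = registry$recruitment$R_max,
                       tau = registry$recruitment$tau,
                       nu = registry$recruitment$nu,
                       provenance = registry$provenance$recruitment)
  )
}
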