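#' Parameters of the uncertain dispersal model
#'
#' The uncertain dispersal model treats the arrival of propagules at the
#' disturbed patch as the stochastic step: each connected remnant patch
#' independently supplies propagules in a given year with a probability that
#' is a logistic function of that patch's biomass, and arrivals recruit with
#' certainty. The per-patch curve is
#' \deqn{p_1(B) = \frac{L_{max}}{1 + e^{-\nu (B - \tau)}},}
#' with `L_max` the dispersal suitability (maximum annual probability of
#' propagules dispersing from one source patch), `tau` the productivity
#' parameter (biomass at which the probability is half of `L_max`; lower
#' values mean more propagules per unit biomass) and `nu` the threshold
#' parameter (steepness of the biomass-probability curve).
#'
#' @param L_max Maximum annual dispersal probability, in (0, 1].
#' @param tau Biomass at half-`L_max` (g dry wt m^-2), > 0.
#' @param nu Steepness (per g dry wt m^-2), > 0.
#' @return An object of class `dispersal_params`.
#' @seealso [annual_dispersal_probability()], [calibrate_tau()]
#' @export
dispersal_params <- function(L_max, tau, nu) {
  check_recol_params(L_max, tau, nu, "L_max")
  structure(list(L_max = as.numeric(L_max), tau = as.numeric(tau),
                 nu = as.numeric(nu)),
            class = c("dispersal_params", "recolonization_params"))
}

#' Parameters of the uncertain recruitment model
#'
#' The uncertain recruitment model treats propagule dispersal as
#' deterministic and recruitment at the disturbed patch as the stochastic
#' step. The annual probability that at least one propagule recruits is a
#' logistic function of the summed biomass of all connected remnant patches,
#' \deqn{p_R = \frac{R_{max}}{1 + e^{-\nu (S - \tau)}},}
#' where `R_max` is the recruitment suitability (maximum annual recruitment
#' probability when propagule supply saturates), `tau` the summed biomass at
#' half-`R_max`, and `nu` the steepness. Unlike the dispersal model, the
#' probability is bounded by `R_max` no matter how many patches connect.
#'
#' @param R_max Maximum annual recruitment probability, in (0, 1].
#' @param tau Summed-biomass half-saturation (g dry wt m^-2), > 0.
#' @param nu Steepness (per g dry wt m^-2), > 0.
#' @return An object of class `recruitment_params`.
#' @seealso [annual_recruitment_probability()], [calibrate_tau()]
#' @export
recruitment_params <- function(R_max, tau, nu) {
  check_recol_params(R_max, tau, nu, "R_max")
  structure(list(R_max = as.numeric(R_max), tau = as.numeric(tau),
                 nu = as.numeric(nu)),
            class = c("recruitment_params", "recolonization_params"))
}

check_recol_params <- function(p_max, tau, nu, max_name) {
  stopifnot(is.numeric(p_max), length(p_max) == 1L,
            is.numeric(tau), length(tau) == 1L,
            is.numeric(nu), length(nu) == 1L)
  if (!is.finite(p_max) || p_max <= 0 || p_max > 1)
    stop("'", max_name, "' must lie in (0, 1]; got ", p_max)
  if (!is.finite(tau) || tau <= 0)
    stop("'tau' must be a positive biomass; got ", tau)
  if (!is.finite(nu) || nu <= 0)
    stop("'nu' must be a positive steepness; got ", nu)
  invisible(TRUE)
}

#' @export
print.recolonization_params <- function(x, ...) {
  mx <- if (inherits(x, "dispersal_params")) "L_max" else "R_max"
  cat(sprintf("%s model parameters: %s = %g, tau = %g g dry wt m^-2, nu = %g\n",
              if (mx == "L_max") "Uncertain dispersal" else "Uncertain recruitment",
              mx, x[[mx]], x$tau, x$nu))
  invisible(x)
}

# Maximum annual probability, whichever of L_max/R_max the object carries.
max_annual_probability <- function(params) {
  if (inherits(params, "dispersal_params")) params$L_max else params$R_max
}

#' Patch network
#'
#' A set of habitat patches with a symmetric binary connectivity matrix `Q`
#' (1 = connected, 0 = not, zero diagonal), a per-patch biomass vector, and
#' the index of the disturbed patch. The disturbed patch starts with zero
#' biomass: it retains no remnant habitat or seed bank.
#'
#' @param Q Square symmetric 0/1 matrix with zero diagonal. Dimnames, if
#'   present, are kept as patch identifiers.
#' @param biomass Non-negative per-patch biomass (g dry wt m^-2), one entry
#'   per row of `Q`.
#' @param disturbed Index (or patch identifier) of the disturbed patch;
#'   its biomass must be 0.
#' @return An object of class `patch_network`.
#' @seealso [build_network()] for the star networks used in scenario grids;
#'   [read_patch_network()] to load one from CSV files.
#' @export
patch_network <- function(Q, biomass, disturbed = 1L) {
  Q <- as.matrix(Q)
  if (nrow(Q) != ncol(Q)) stop("'Q' must be square")
  if (!all(Q %in% c(0, 1))) stop("'Q' must contain only 0/1 entries")
  if (any(diag(Q) != 0)) stop("'Q' must have a zero diagonal")
  if (!isTRUE(all.equal(Q, t(Q)))) stop("'Q' must be symmetric")
  biomass <- as.numeric(biomass)
  if (length(biomass) != nrow(Q))
    stop("'biomass' must have one entry per patch (", nrow(Q), ")")
  if (any(!is.finite(biomass)) || any(biomass < 0))
    stop("'biomass' must be finite and non-negative")
  if (is.character(disturbed)) {
    ids <- rownames(Q)
    if (is.null(ids) || !(disturbed %in% ids))
      stop("disturbed patch identifier '", disturbed, "' not found in Q dimnames")
    disturbed <- match(disturbed, ids)
  }
  disturbed <- as.integer(disturbed)
  if (disturbed < 1L || disturbed > nrow(Q))
    stop("'disturbed' index out of range")
  if (biomass[disturbed] != 0)
    stop("the disturbed patch must start at zero biomass ",
         "(no remnant habitat or seed bank); got ", biomass[disturbed])
  structure(list(Q = Q, biomass = biomass, disturbed = disturbed),
            class = "patch_network")
}

#' @export
print.patch_network <- function(x, ...) {
  deg <- sum(x$Q[x$disturbed, ])
  cat(sprintf("Patch network: %d patches, disturbed patch #%d with %d connection(s)\n",
              nrow(x$Q), x$disturbed, deg))
  invisible(x)
}

# Indices of remnant patches connected to the disturbed patch.
connected_patches <- function(network) {
  which(network$Q[network$disturbed, ] == 1)
}

#' Annual recolonization probability under uncertain dispersal
#'
#' Probability that propagules from at least one connected remnant patch
#' reach (and, in this model, certainly recruit at) the disturbed patch in
#' one year:
#' \deqn{p_D = 1 - \prod_{j: Q_{ij} = 1}
#'   \left(1 - \frac{L_{max}}{1 + e^{-\nu (B_j - \tau)}}\right).}
#' The product runs only over connected patches, so an isolated disturbed
#' patch has probability exactly 0, and the probability approaches 1 as
#' connections accumulate.
#'
#' @param network A [patch_network()].
#' @param params A [dispersal_params()] object.
#' @return Annual probability in `[0, 1)`.
#' @export
annual_dispersal_probability <- function(network, params) {
  stopifnot(inherits(network, "patch_network"),
            inherits(params, "dispersal_params"))
  js <- connected_patches(network)
  if (length(js) == 0L) return(0)
  p1 <- params$L_max / (1 + exp(-params$nu * (network$biomass[js] - params$tau)))
  1 - prod(1 - p1)
}

#' Annual recolonization probability under uncertain recruitment
#'
#' Probability that at least one of the (deterministically arriving)
#' propagules recruits at the disturbed patch in one year, as a logistic
#' function of the summed biomass of connected remnant patches:
#' \deqn{p_R = \frac{R_{max}}{1 + e^{-\nu (S - \tau)}}, \quad
#'   S = \sum_{j: Q_{ij}=1} B_j.}
#' Saturates at `R_max` however large the supply; with zero connected
#' patches there is no propagule supply at all and the probability is
#' defined as exactly 0.
#'
#' @param network A [patch_network()].
#' @param params A [recruitment_params()] object.
#' @return Annual probability in `[0, R_max)`.
#' @export
annual_recruitment_probability <- function(network, params) {
  stopifnot(inherits(network, "patch_network"),
            inherits(params, "recruitment_params"))
  js <- connected_patches(network)
  if (length(js) == 0L) return(0)
  S <- sum(network$biomass[js])
  params$R_max / (1 + exp(-params$nu * (S - params$tau)))
}

#' Calibrate the productivity parameter to a target probability
#'
#' Solves for the half-saturation biomass `tau` such that the logistic
#' recolonization curve with maximum `max_param` and steepness `nu`,
#' evaluated at `reference_biomass` (a single source patch for the dispersal
#' curve, or the summed remnant biomass for the recruitment curve), equals
#' `target_probability`. Inverting the curve gives the closed form
#' \deqn{\tau = B_{ref} + \frac{1}{\nu}
#'   \ln\!\left(\frac{p_{max}}{p_{target}} - 1\right).}
#' Used to pin placeholder parameter sets to a priori recovery expectations
#' when direct field estimates of the curve are unavailable.
#'
#' @param target_probability Desired probability at the reference biomass,
#'   in (0, `max_param`).
#' @param max_param Curve maximum (`L_max` or `R_max`), in (0, 1].
#' @param nu Steepness (per g dry wt m^-2), > 0.
#' @param reference_biomass Biomass at which the curve should hit the
#'   target (g dry wt m^-2), > 0.
#' @return The calibrated `tau` (g dry wt m^-2). Errors if the target is
#'   infeasible (`target_probability >= max_param`) or if the solution
#'   violates `tau > 0`.
#' @examples
#' calibrate_tau(0.24, 0.375, nu = 0.01, reference_biomass = 600)  # ~542.46
#' @export
calibrate_tau <- function(target_probability, max_param, nu, reference_biomass) {
  stopifnot(is.numeric(target_probability), length(target_probability) == 1L,
            is.numeric(max_param), length(max_param) == 1L,
            is.numeric(nu), length(nu) == 1L,
            is.numeric(reference_biomass), length(reference_biomass) == 1L)
  if (!is.finite(max_param) || max_param <= 0 || max_param > 1)
    stop("'max_param' must lie in (0, 1]; got ", max_param)
  if (!is.finite(nu) || nu <= 0) stop("'nu' must be positive; got ", nu)
  if (!is.finite(reference_biomass) || reference_biomass <= 0)
    stop("'reference_biomass' must be positive; got ", reference_biomass)
  if (!is.finite(target_probability) || target_probability <= 0)
    stop("'target_probability' must be positive; got ", target_probability)
  if (target_probability >= max_param)
    stop("infeasible calibration: target probability ", target_probability,
         " must be strictly below the curve maximum ", max_param)
  tau <- reference_biomass + log(max_param / target_probability - 1) / nu
  if (tau <= 0)
    stop("calibrated tau = ", signif(tau, 6), " violates tau > 0; the target ",
         "probability is too close to the curve maximum for this biomass ",
         "and steepness")
  tau
}
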