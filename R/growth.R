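#' Growth parameters for a habitat-forming species
#'
#' Bundles the parameters of deterministic logistic biomass growth towards a
#' light-dependent equilibrium: the intrinsic growth rate and equilibrium
#' biomass at normal light, the biomass a patch is assigned at the moment of
#' successful colonization, and the light-limitation function.
#'
#' Growth at high density is assumed to be limited by self-shading, giving
#' logistic dynamics \deqn{dB/dt = r(\ell)\,B\,(1 - B/B_{eq}(\ell)),} where
#' both the realized rate \eqn{r(\ell) = r_{max} g(\ell)} and the realized
#' equilibrium \eqn{B_{eq}(\ell) = B_{max} g(\ell)} are scaled by the
#' light-limitation function \eqn{g}. The default \eqn{g(\ell) = \ell}
#' (option `"linear"`) makes both proportional to the fraction of normal
#' benthic light; any other response can be supplied as a function.
#'
#' @param r_max Intrinsic per-year growth rate at normal light (1/year), > 0.
#' @param B_max Equilibrium biomass at normal light (g dry wt m^-2), > 0.
#' @param B0 Biomass assigned at the moment of successful colonization
#'   (g dry wt m^-2); default 1% of `B_max`. Must satisfy `0 < B0 < B_max`.
#' @param light_response Either the string `"linear"` (default) or a function
#'   mapping a light fraction in (0, 1] to a growth/capacity multiplier in
#'   (0, 1], with `g(1) == 1`.
#'
#' @return An object of class `growth_params`.
#' @seealso [equilibrium_biomass()], [grow()], [time_to_fraction()]
#' @examples
#' gp <- growth_params(r_max = 0.5, B_max = 600)
#' equilibrium_biomass(gp, light_scenario(0.5))
#' @export
growth_params <- function(r_max, B_max, B0 = 0.01 * B_max,
                          light_response = "linear") {
  stopifnot(is.numeric(r_max), length(r_max) == 1L,
            is.numeric(B_max), length(B_max) == 1L,
            is.numeric(B0), length(B0) == 1L)
  if (!is.finite(r_max) || r_max <= 0)
    stop("'r_max' must be a finite positive rate (1/year), got ", r_max)
  if (!is.finite(B_max) || B_max <= 0)
    stop("'B_max' must be a finite positive biomass, got ", B_max)
  if (!is.finite(B0) || B0 <= 0 || B0 >= B_max)
    stop("'B0' must satisfy 0 < B0 < B_max; got B0 = ", B0,
         " with B_max = ", B_max)
  if (is.character(light_response)) {
    light_response <- match.arg(light_response, "linear")
  } else if (!is.function(light_response)) {
    stop("'light_response' must be \"linear\" or a function of the light fraction")
  }
  structure(
    list(r_max = as.numeric(r_max), B_max = as.numeric(B_max),
         B0 = as.numeric(B0), light_response = light_response),
    class = "growth_params"
  )
}

#' @export
print.growth_params <- function(x, ...) {
  resp <- if (is.character(x$light_response)) x$light_response else "<function>"
  cat("Growth parameters:\n",
      sprintf("  r_max = %g /year, B_max = %g g dry wt m^-2, B0 = %g\n",
              x$r_max, x$B_max, x$B0),
      sprintf("  light response: %s\n", resp), sep = "")
  invisible(x)
}

#' Chronic light-stress scenario
#'
#' A light scenario is the fraction of normal benthic light reaching all
#' patches; chronic low-light stress (for example from declining water
#' quality and turbidity) is represented by fractions below 1. The study
#' scenarios use 1 (normal), 0.5 (stressed) and 0.25 (severely stressed),
#' but any value in (0, 1] is accepted.
#'
#' @param light_fraction Fraction of normal benthic light, in (0, 1].
#' @return An object of class `light_scenario`.
#' @examples
#' light_scenario(0.25)
#' @export
light_scenario <- function(light_fraction) {
  stopifnot(is.numeric(light_fraction), length(light_fraction) == 1L)
  if (!is.finite(light_fraction) || light_fraction <= 0 || light_fraction > 1)
    stop("'light_fraction' must lie in (0, 1]; got ", light_fraction)
  structure(list(light_fraction = as.numeric(light_fraction)),
            class = "light_scenario")
}

#' @export
print.light_scenario <- function(x, ...) {
  cat(sprintf("Light scenario: %g of normal benthic light\n", x$light_fraction))
  invisible(x)
}

# Coerce a bare numeric to a light scenario so call sites accept either.
as_light_scenario <- function(light) {
  if (inherits(light, "light_scenario")) return(light)
  light_scenario(light)
}

# Evaluate the light-limitation multiplier g(l) in (0, 1].
light_multiplier <- function(params, light) {
  light <- as_light_scenario(light)
  l <- light$light_fraction
  g <- if (is.character(params$light_response)) l else params$light_response(l)
  if (!is.finite(g) || g <= 0 || g > 1)
    stop("light response returned ", g, "; must lie in (0, 1]")
  g
}

#' Light-specific equilibrium biomass
#'
#' The maximal biomass a patch can hold at a given light level:
#' \eqn{B_{eq}(\ell) = B_{max}\,g(\ell)}, with \eqn{g} the light-limitation
#' function of the species (`g(1) = 1`, so `equilibrium_biomass()` at normal
#' light equals `B_max`).
#'
#' @param params A [growth_params()] object.
#' @param light A [light_scenario()] or bare light fraction in (0, 1].
#' @return Equilibrium biomass (g dry wt m^-2).
#' @export
equilibrium_biomass <- function(params, light) {
  stopifnot(inherits(params, "growth_params"))
  params$B_max * light_multiplier(params, light)
}

#' Light-specific intrinsic growth rate
#'
#' \eqn{r(\ell) = r_{max}\,g(\ell)}: lower light slows growth as well as
#' lowering the equilibrium biomass.
#'
#' @inheritParams equilibrium_biomass
#' @return Realized intrinsic growth rate (1/year).
#' @export
growth_rate <- function(params, light) {
  stopifnot(inherits(params, "growth_params"))
  params$r_max * light_multiplier(params, light)
}

#' Grow biomass forward in time
#'
#' Closed-form solution of logistic growth with rate \eqn{r(\ell)} and
#' carrying capacity \eqn{B_{eq}(\ell)}:
#' \deqn{B(t) = \frac{B_{eq}}{1 + \left(\frac{B_{eq} - B}{B}\right) e^{-r t}}.}
#' Zero biomass stays zero (an extinct patch cannot regrow without
#' colonization) and biomass at equilibrium stays there. Decline from above
#' the light-specific capacity is out of scope and raises an error.
#'
#' @inheritParams equilibrium_biomass
#' @param B Starting biomass (g dry wt m^-2), in `[0, equilibrium_biomass()]`.
#' @param duration Elapsed time in years, >= 0. Vectorized.
#' @return Biomass after `duration` years (same length as `duration`).
#' @examples
#' gp <- growth_params(r_max = 0.5, B_max = 100, B0 = 1)
#' grow(1, gp, light_scenario(1), duration = 9.19)  # ~50
#' @export
grow <- function(B, params, light, duration) {
  stopifnot(inherits(params, "growth_params"),
            is.numeric(B), length(B) == 1L, is.numeric(duration))
  if (any(!is.finite(duration)) || any(duration < 0))
    stop("'duration' must be finite and >= 0")
  if (B < 0) stop("'B' must be non-negative")
  B_eq <- equilibrium_biomass(params, light)
  if (B > B_eq * (1 + 1e-12))
    stop("starting biomass ", B, " exceeds the light-specific equilibrium ",
         signif(B_eq, 6), "; decline above capacity is out of scope")
  if (B == 0) return(rep(0, length(duration)))
  r <- growth_rate(params, light)
  B_eq / (1 + ((B_eq - B) / B) * exp(-r * duration))
}

#' Deterministic time to reach a fraction of equilibrium biomass
#'
#' Time for a patch colonized at biomass `B0` to grow to a fraction `f` of
#' its light-specific equilibrium, from the inverted logistic solution:
#' \deqn{t_{grow} = \frac{1}{r(\ell)}
#'   \ln\!\left[\frac{f\,(B_{eq} - B_0)}{B_0\,(1 - f)}\right].}
#' For the default half-recovery threshold (`fraction = 0.5`) this reduces
#' to \eqn{\ln((B_{eq} - B_0)/B_0)/r(\ell)}.
#'
#' @inheritParams equilibrium_biomass
#' @param fraction Recovery threshold as a fraction of equilibrium biomass,
#'   in (0, 1); default 0.5.
#' @return Years of deterministic growth, >= 0. If `B0` already meets the
#'   threshold, returns 0 with a warning.
#' @examples
#' gp <- growth_params(r_max = 0.5, B_max = 100, B0 = 1)
#' time_to_fraction(gp, light_scenario(1))  # 2*log(99) ~ 9.19 years
#' @export
time_to_fraction <- function(params, light, fraction = 0.5) {
  stopifnot(inherits(params, "growth_params"),
            is.numeric(fraction), length(fraction) == 1L)
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie in (0, 1); got ", fraction)
  B_eq <- equilibrium_biomass(params, light)
  B0 <- params$B0
  target <- fraction * B_eq
  if (B0 >= target) {
    if (B0 > target)
      warning("colonization biomass B0 = ", B0,
              " already exceeds the recovery threshold ", signif(target, 6),
              "; returning 0 years of growth")
    return(0)
  }
  r <- growth_rate(params, light)
  log(fraction * (B_eq - B0) / (B0 * (1 - fraction))) / r
}
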