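#' Colonization hazard rate from an annual probability
#'
#' Maps the annual Bernoulli recolonization probability `p` onto the rate of
#' a continuous-time exponential waiting time. The default
#' `"matched-annual"` mapping, \eqn{\lambda = -\ln(1 - p)}, makes the
#' exponential's one-year colonization probability equal `p` exactly while
#' allowing sub-annual waiting times. The `"direct"` mapping \eqn{\lambda = p}
#' (small-`p` limit of the former) is kept as an alternative policy.
#'
#' Boundary sentinels: `p = 1` returns `Inf` (immediate colonization) and
#' `p = 0` returns 0, which downstream code treats as "recovery never
#' happens".
#'
#' @param p Annual probability in `[0, 1]`.
#' @param hazard_map `"matched-annual"` (default) or `"direct"`.
#' @return Hazard rate (1/year).
#' @examples
#' hazard_from_annual_probability(0.5)  # log(2)
#' @export
hazard_from_annual_probability <- function(p,
                                           hazard_map = c("matched-annual",
                                                          "direct")) {
  hazard_map <- match.arg(hazard_map)
  stopifnot(is.numeric(p), length(p) == 1L)
  if (!is.finite(p) || p < 0 || p > 1)
    stop("'p' must be a probability in [0, 1]; got ", p)
  if (p == 1) return(Inf)
  if (p == 0) return(0)
  switch(hazard_map,
         "matched-annual" = -log1p(-p),
         "direct" = p)
}

#' Translated-exponential recovery-time distribution
#'
#' The recovery time of a disturbed patch decomposes into a stochastic
#' colonization waiting time, exponential with hazard `rate`, plus a
#' deterministic regrowth time `translation` set by the biomass growth
#' dynamics. The support is `[translation, Inf)`.
#'
#' `rate = Inf` is the immediate-colonization sentinel (all mass at
#' `translation`); `rate = 0` is the no-recovery sentinel (all quantiles
#' infinite).
#'
#' @param rate Colonization hazard (1/year), >= 0 (`Inf` allowed).
#' @param translation Deterministic growth time t_grow (years), >= 0.
#' @return An object of class `recovery_distribution`.
#' @seealso [analytic_distribution()], [distribution_quantile()],
#'   [distribution_mean()]
#' @export
recovery_distribution <- function(rate, translation) {
  stopifnot(is.numeric(rate), length(rate) == 1L,
            is.numeric(translation), length(translation) == 1L)
  if (is.na(rate) || rate < 0)
    stop("'rate' must be >= 0 (Inf allowed); got ", rate)
  if (!is.finite(translation) || translation < 0)
    stop("'translation' must be finite and >= 0; got ", translation)
  structure(list(rate = as.numeric(rate), translation = as.numeric(translation)),
            class = "recovery_distribution")
}

#' @export
print.recovery_distribution <- function(x, ...) {
  if (x$rate == 0) {
    cat(sprintf("Recovery-time distribution: no recovery (rate 0); t_grow = %g years\n",
                x$translation))
  } else if (is.infinite(x$rate)) {
    cat(sprintf("Recovery-time distribution: immediate colonization; recovery at t_grow = %g years\n",
                x$translation))
  } else {
    cat(sprintf("Recovery-time distribution: rate %g /year + %g years growth\n",
                x$rate, x$translation),
        sprintf("  median %.3g years, 95%% interval [%.3g, %.3g] years\n",
                distribution_quantile(x, 0.5),
                distribution_quantile(x, 0.025),
                distribution_quantile(x, 0.975)), sep = "")
  }
  invisible(x)
}

#' Exact recovery-time distribution for an annual probability
#'
#' Combines the colonization hazard implied by the annual recolonization
#' probability with the deterministic time to regrow to the recovery
#' threshold: the result is exponential with rate
#' `hazard_from_annual_probability(p)` translated by
#' `time_to_fraction(growth, light, fraction)`.
#'
#' @param p Annual recolonization probability in `[0, 1]`.
#' @param growth A [growth_params()] object.
#' @param light A [light_scenario()] or bare light fraction.
#' @param fraction Recovery threshold (fraction of equilibrium biomass),
#'   default 0.5.
#' @param hazard_map Passed to [hazard_from_annual_probability()].
#' @return A [recovery_distribution()]; its `annual_probability` attribute
#'   records `p`.
#' @examples
#' gp <- growth_params(r_max = 2, B_max = 600)
#' analytic_distribution(0.24, gp, light_scenario(1))
#' @export
analytic_distribution <- function(p, growth, light, fraction = 0.5,
                                  hazard_map = "matched-annual") {
  rate <- hazard_from_annual_probability(p, hazard_map)
  t_grow <- time_to_fraction(growth, light, fraction)
  dist <- recovery_distribution(rate, t_grow)
  attr(dist, "annual_probability") <- p
  dist
}

#' Quantiles of a recovery-time distribution
#'
#' \eqn{Q(q) = t_{grow} - \ln(1 - q)/\lambda}. The reporting convention for
#' interval summaries pairs `(0.025, 0.975)` ("95% quantiles") and
#' `(0.125, 0.875)` ("75% quantiles") around the median.
#'
#' @param dist A [recovery_distribution()].
#' @param q Probabilities in `[0, 1)`; `q = 0` returns the support infimum
#'   `translation`. Vectorized.
#' @return Years.
#' @export
distribution_quantile <- function(dist, q) {
  stopifnot(inherits(dist, "recovery_distribution"), is.numeric(q))
  if (any(!is.finite(q)) || any(q < 0) || any(q >= 1))
    stop("'q' must lie in [0, 1)")
  if (dist$rate == 0) return(ifelse(q >= 0, Inf, NA_real_))
  if (is.infinite(dist$rate)) return(rep(dist$translation, length(q)))
  dist$translation - log(1 - q) / dist$rate
}

#' Mean and median recovery time
#'
#' The mean is `translation + 1/rate`; the median is the 50% quantile
#' `translation + log(2)/rate`.
#'
#' @param dist A [recovery_distribution()].
#' @return Years.
#' @export
distribution_mean <- function(dist) {
  stopifnot(inherits(dist, "recovery_distribution"))
  dist$translation + 1 / dist$rate
}

#' @rdname distribution_mean
#' @export
distribution_median <- function(dist) {
  distribution_quantile(dist, 0.5)
}

#' Monte Carlo simulation settings
#'
#' @param n_reps Number of replicates, >= 1.
#' @param seed Optional integer RNG seed; recorded in the sample so every
#'   output is reproducible.
#' @param max_years Censoring horizon in years (default 200): replicates
#'   whose recovery time exceeds it are flagged censored, never dropped.
#' @param time_mode `"continuous"` (exponential waiting time; default) or
#'   `"annual"` (discrete annual Bernoulli trials, kept for cross-checking).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_reps = 10000L, seed = NULL, max_years = 200,
                       time_mode = c("continuous", "annual")) {
  time_mode <- match.arg(time_mode)
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("'n_reps' must be >= 1")
  if (!is.numeric(max_years) || !is.finite(max_years) || max_years <= 0)
    stop("'max_years' must be a positive number of years")
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("'seed' must be coercible to an integer")
  }
  structure(list(n_reps = n_reps, seed = seed, max_years = as.numeric(max_years),
                 time_mode = time_mode),
            class = "sim_config")
}

#' Simulate recovery times
#'
#' Draws `n_reps` replicate recovery times: a stochastic colonization
#' waiting time — exponential with rate \eqn{-\ln(1-p)} in continuous mode,
#' or the first success year of annual Bernoulli(p) trials in annual mode —
#' plus the deterministic regrowth time to the recovery threshold.
#' Replicates exceeding the censoring horizon are flagged, not dropped.
#' The same seed always reproduces the identical sample.
#'
#' @inheritParams analytic_distribution
#' @param config A [sim_config()].
#' @return An object of class `recovery_sample`: list with `times` (years),
#'   logical `censored`, `t_grow`, `annual_probability` and the `config`
#'   used (including the seed).
#' @seealso [summarize_samples()]
#' @export
simulate_recovery_times <- function(p, growth, light, fraction = 0.5,
                                    config = sim_config()) {
  stopifnot(inherits(config, "sim_config"),
            is.numeric(p), length(p) == 1L)
  if (!is.finite(p) || p < 0 || p > 1)
    stop("'p' must be a probability in [0, 1]; got ", p)
  t_grow <- time_to_fraction(growth, light, fraction)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_reps
  wait <- if (config$time_mode == "continuous") {
    if (p == 1) rep(0, n)
    else if (p == 0) rep(Inf, n)
    else stats::rexp(n, rate = -log1p(-p))
  } else {
    if (p == 0) rep(Inf, n)
    else stats::rgeom(n, prob = p) + 1  # colonization at the end of the first success year
  }
  times <- wait + t_grow
  structure(list(times = times,
                 censored = times > config$max_years,
                 t_grow = t_grow,
                 annual_probability = p,
                 config = config),
            class = "recovery_sample")
}

#' @export
print.recovery_sample <- function(x, ...) {
  cat(sprintf("Recovery-time sample: %d replicates (%s mode), p = %g, t_grow = %g years, %d censored at %g years\n",
              x$config$n_reps, x$config$time_mode, x$annual_probability,
              x$t_grow, sum(x$censored), x$config$max_years))
  invisible(x)
}

#' Summarize recovery times
#'
#' Empirical summaries of a simulated sample (or bare numeric vector):
#' median, the 12.5/87.5% pair ("75% quantiles") and the 2.5/97.5% pair
#' ("95% quantiles"), mean, and the censored fraction. Quantiles use the
#' linear-interpolation convention (`stats::quantile` type 7). A quantile at
#' probability `q` is reported only when the censored fraction leaves its
#' order statistics observed — i.e. when `frac_censored < 1 - q`; otherwise
#' it is `NA`. The mean is `NA` whenever any replicate is censored.
#'
#' @param sample A `recovery_sample` from [simulate_recovery_times()], or a
#'   numeric vector of recovery times.
#' @param censored Optional logical vector flagging censored entries when
#'   `sample` is a bare numeric vector.
#' @return A one-row `data.frame` with columns `median`, `q125`, `q875`,
#'   `q025`, `q975`, `mean`, `n`, `n_censored`, `frac_censored`.
#' @export
summarize_samples <- function(sample, censored = NULL) {
  if (inherits(sample, "recovery_sample")) {
    times <- sample$times
    censored <- sample$censored
  } else {
    times <- as.numeric(sample)
    if (is.null(censored)) censored <- rep(FALSE, length(times))
  }
  if (length(times) == 0L) stop("empty sample")
  stopifnot(length(censored) == length(times))
  frac_cens <- mean(censored)
  # Censored values only matter through their rank: push them to +Inf so
  # quantiles below the observed fraction are exact, then blank the rest.
  work <- times
  work[censored] <- Inf
  probs <- c(median = 0.5, q125 = 0.125, q875 = 0.875, q025 = 0.025, q975 = 0.975)
  qs <- if (frac_cens == 1) {
    rep(NA_real_, length(probs))
  } else {
    suppressWarnings(as.numeric(stats::quantile(work, probs, names = FALSE, type = 7)))
  }
  qs[!is.finite(qs) | probs >= 1 - frac_cens] <- NA_real_
  out <- as.data.frame(as.list(stats::setNames(qs, names(probs))))
  out$mean <- if (any(censored)) NA_real_ else mean(times)
  out$n <- length(times)
  out$n_censored <- sum(censored)
  out$frac_censored <- frac_cens
  out
}

# Analytic counterpart of summarize_samples() with the same columns, for
# deterministic scenario results. No censoring; n is NA.
summarize_distribution <- function(dist) {
  data.frame(median = distribution_quantile(dist, 0.5),
             q125 = distribution_quantile(dist, 0.125),
             q875 = distribution_quantile(dist, 0.875),
             q025 = distribution_quantile(dist, 0.025),
             q975 = distribution_quantile(dist, 0.975),
             mean = distribution_mean(dist),
             n = NA_integer_, n_censored = 0L, frac_censored = 0)
}
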