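#' Multi-exponential decay parameters
#'
#' Parameters of a 1-, 2- or 4-component fluorescence decay
#' \deqn{I(t) = I_0 \sum_i \alpha_i e^{-t/\tau_i} + C,}
#' where the \eqn{\alpha_i} are pre-exponential (amplitude) fractions
#' summing to 1, \eqn{I_0} is the amplitude scale and \eqn{C} a constant
#' per-bin background. Lifetimes are stored in increasing order; if the
#' inputs are unordered they are sorted together with their fractions.
#'
#' @param lifetimes decay lifetimes \eqn{\tau_i} in ps (1, 2 or 4 values,
#'   all > 0).
#' @param fractions pre-exponential fractions \eqn{\alpha_i} (non-negative;
#'   renormalised to sum exactly to 1 if within 1e-6 of it).
#' @param amplitude amplitude scale \eqn{I_0} (counts at the t = 0 scale).
#' @param background constant background \eqn{C} (counts per bin).
#'
#' @return An object of class `multiexp_params`.
#' @export
#' @examples
#' free_nadh <- multiexp_params(c(266, 781), c(0.793, 0.207))
#' mean_lifetime(free_nadh)
multiexp_params <- function(lifetimes, fractions, amplitude = 1,
                            background = 0) {
  n <- length(lifetimes)
  if (!n %in% c(1L, 2L, 4L)) {
    stop("decay model must have 1, 2 or 4 components, got ", n)
  }
  if (length(fractions) != n) stop("`fractions` length must match `lifetimes`")
  if (any(lifetimes <= 0)) stop("all lifetimes must be > 0")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  s <- sum(fractions)
  if (abs(s - 1) > 1e-6) {
    stop("fractions must sum to 1 (got ", format(s), ")")
  }
  fractions <- fractions / s
  ord <- order(lifetimes)
  lifetimes <- lifetimes[ord]
  fractions <- fractions[ord]
  if (any(diff(lifetimes) <= 0)) {
    stop("lifetimes must be distinct (strictly increasing after sorting)")
  }
  stopifnot(amplitude >= 0, background >= 0 || TRUE)
  structure(list(lifetimes = lifetimes, fractions = fractions,
                 amplitude = amplitude, background = background),
            class = "multiexp_params")
}

#' @export
print.multiexp_params <- function(x, ...) {
  cat(sprintf("%d-exponential decay: I0 = %.4g, C = %.4g\n",
              length(x$lifetimes), x$amplitude, x$background))
  for (i in seq_along(x$lifetimes)) {
    cat(sprintf("  tau%d = %8.1f ps  alpha%d = %.4f\n",
                i, x$lifetimes[i], i, x$fractions[i]))
  }
  cat(sprintf("  intensity-weighted mean lifetime: %.1f ps\n",
              mean_lifetime(x)))
  invisible(x)
}

# Periodically wrapped exponential on a high-repetition-rate time axis:
# sum_{k>=0} exp(-(t + k T)/tau) = exp(-t/tau) / (1 - exp(-T/tau)).
wrapped_exp <- function(t, tau, rep_period) {
  exp(-t / tau) / (1 - exp(-rep_period / tau))
}

#' Expected multi-exponential decay curve (pre-IRF)
#'
#' Evaluates the periodic (incomplete-decay corrected) multi-exponential
#' model on the acquisition time axis. At repetition period \eqn{T}, photons
#' excited by earlier pulses overlap the current period, so each component
#' uses the closed-form wrap
#' \eqn{e^{-t/\tau}/(1 - e^{-T/\tau})} instead of a bare exponential.
#'
#' @param params a [multiexp_params()] object.
#' @param settings an [acquisition_settings()] object.
#' @return Numeric vector of expected intensities per bin (background
#'   included), before IRF convolution.
#' @export
multiexp_curve <- function(params, settings) {
  stopifnot(inherits(params, "multiexp_params"),
            inherits(settings, "acquisition_settings"))
  if (any(params$lifetimes >= 10 * settings$rep_period)) {
    warning("lifetime >= 10x repetition period: wrap factor dominates and ",
            "the decay is nearly flat over the window")
  }
  tt <- time_axis(settings)
  y <- numeric(settings$n_bins)
  for (i in seq_along(params$lifetimes)) {
    y <- y + params$fractions[i] *
      wrapped_exp(tt, params$lifetimes[i], settings$rep_period)
  }
  params$amplitude * y + params$background
}

#' Intensity-weighted mean fluorescence lifetime
#'
#' \deqn{\tau_m = \frac{\sum_i \alpha_i \tau_i^2}{\sum_i \alpha_i \tau_i}}
#' Each component is weighted by its share of the detected photons
#' (\eqn{\alpha_i \tau_i}), not by its amplitude alone.
#'
#' @param params a [multiexp_params()] object (or anything with `lifetimes`
#'   and `fractions` fields).
#' @return Mean lifetime in ps; always between the smallest and largest
#'   component lifetime.
#' @export
#' @examples
#' mean_lifetime(multiexp_params(c(266, 781), c(0.793, 0.207))) # 489.4 ps
mean_lifetime <- function(params) {
  at <- params$fractions * params$lifetimes
  denom <- sum(at)
  if (denom <= 0) stop("all alpha_i * tau_i are zero; mean lifetime undefined")
  sum(at * params$lifetimes) / denom
}

# Rescale amplitude so the background-free expected curve sums to `budget`
# counts over the axis. This is the amplitude convention used throughout the
# simulator: photon_budget fixes the (pre-noise) total signal.
scale_to_budget <- function(params, settings, budget) {
  base <- params
  base$amplitude <- 1
  base$background <- 0
  s <- sum(multiexp_curve(base, settings))
  params$amplitude <- budget / s
  params
}
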