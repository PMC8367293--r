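#' Anisotropy model parameters
#'
#' Single-exponential fluorescence anisotropy decay
#' \eqn{r(t) = r_0 e^{-t/\theta}} with rotational correlation time
#' \eqn{\theta} and initial anisotropy \eqn{r_0}, plus the instrumental
#' G-factor (polarisation detection bias).
#'
#' @param r0 initial anisotropy, in \eqn{[-0.2, 0.4]}. The default 0.35 is
#'   a modelling assumption (the one-photon fundamental limit is 0.4).
#' @param theta rotational correlation time in ps (> 0).
#' @param g_factor detection bias G (> 0); the recorded perpendicular
#'   channel equals the true perpendicular intensity divided by G.
#' @return An object of class `aniso_params`.
#' @export
aniso_params <- function(r0 = 0.35, theta, g_factor = 1) {
  if (r0 < -0.2 || r0 > 0.4) stop("`r0` must lie in [-0.2, 0.4]")
  if (theta <= 0) stop("`theta` must be > 0")
  if (g_factor <= 0) stop("`g_factor` must be > 0")
  structure(list(r0 = r0, theta = theta, g_factor = g_factor),
            class = "aniso_params")
}

#' @export
print.aniso_params <- function(x, ...) {
  cat(sprintf("anisotropy decay: r0 = %.3f, theta = %.0f ps, G = %.4f\n",
              x$r0, x$theta, x$g_factor))
  invisible(x)
}

#' Decay histogram
#'
#' Per-bin photon counts for one polarisation channel, carrying its
#' acquisition settings.
#'
#' @param counts non-negative per-bin counts (length `settings$n_bins`).
#' @param settings an [acquisition_settings()] object.
#' @param channel channel label: one of `"magic"`, `"parallel"`,
#'   `"perpendicular"` or a free-form label.
#' @return An object of class `decay_histogram`.
#' @export
decay_histogram <- function(counts, settings, channel = "magic") {
  stopifnot(inherits(settings, "acquisition_settings"))
  check_same_axis(length(counts), settings$n_bins, "counts/settings")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = as.numeric(counts), settings = settings,
                 channel = channel),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("decay histogram [%s]: %d bins, %.4g total counts, peak bin %d\n",
              x$channel, length(x$counts), sum(x$counts),
              which.max(x$counts) - 1L))
  invisible(x)
}

#' Expected polarised channel triplet
#'
#' Builds the expected (noise-free) parallel, perpendicular and magic-angle
#' decay curves for a multi-exponential emitter with single-exponential
#' anisotropy decay, using the standard photoselection relations
#' \deqn{I_\parallel(t) = \tfrac{1}{3} I(t) (1 + 2 r(t)), \quad
#'       I_\perp(t) = \tfrac{1}{3} I(t) (1 - r(t)),}
#' with \eqn{r(t) = r_0 e^{-t/\theta}}. The recorded perpendicular channel
#' is attenuated by the G-factor (\eqn{I_\perp / G}). Each product
#' \eqn{I(t) r(t)} is itself a sum of wrapped exponentials with rates
#' \eqn{1/\tau_i + 1/\theta}, so the periodic wrap stays exact. Each channel
#' is then circularly convolved with the IRF; the background `C` is added
#' per channel (a constant is invariant under convolution with a unit-sum
#' kernel).
#'
#' @param params decay parameters ([multiexp_params()]); `amplitude` scales
#'   the total intensity \eqn{I(t)}.
#' @param aniso anisotropy parameters ([aniso_params()]).
#' @param settings an [acquisition_settings()] object.
#' @param irf an `irf_kernel`, or `NULL` for no convolution.
#' @return A list with numeric vectors `parallel`, `perpendicular`, `magic`.
#'   With G = 1, `parallel + 2*perpendicular == 3*magic` bin by bin.
#' @export
expected_polarized <- function(params, aniso, settings, irf = NULL) {
  stopifnot(inherits(params, "multiexp_params"),
            inherits(aniso, "aniso_params"))
  tt <- time_axis(settings)
  tot <- numeric(settings$n_bins)
  cross <- numeric(settings$n_bins)
  for (i in seq_along(params$lifetimes)) {
    tau <- params$lifetimes[i]
    tau_c <- 1 / (1 / tau + 1 / aniso$theta) # rate of I(t) * r(t) term
    tot <- tot + params$fractions[i] * wrapped_exp(tt, tau, settings$rep_period)
    cross <- cross +
      params$fractions[i] * wrapped_exp(tt, tau_c, settings$rep_period)
  }
  tot <- params$amplitude * tot
  cross <- params$amplitude * aniso$r0 * cross
  par <- (tot + 2 * cross) / 3
  perp <- (tot - cross) / (3 * aniso$g_factor)
  magic <- tot / 3
  if (!is.null(irf)) {
    par <- reconvolve(par, irf)
    perp <- reconvolve(perp, irf)
    magic <- reconvolve(magic, irf)
  }
  C <- params$background
  list(parallel = par + C, perpendicular = perp + C, magic = magic + C)
}

#' Poisson-sample a decay histogram
#'
#' Draws independent Poisson counts per bin from an expected curve (TCSPC
#' shot noise). Reproducible under a fixed seed; the caller's random state
#' is left untouched.
#'
#' @param expected per-bin expected counts (all >= 0).
#' @param settings an [acquisition_settings()] object.
#' @param seed integer seed.
#' @param channel channel label for the resulting histogram.
#' @return A [decay_histogram()].
#' @export
sample_histogram <- function(expected, settings, seed, channel = "magic") {
  check_same_axis(length(expected), settings$n_bins, "expected/settings")
  bad <- which(expected < 0)
  if (length(bad) > 0) {
    stop("expected curve is negative at bin ", bad[1] - 1L,
         " (", format(expected[bad[1]]), "); cannot Poisson-sample")
  }
  counts <- withr::with_seed(as.integer(seed),
                             stats::rpois(length(expected), expected))
  decay_histogram(counts, settings, channel = channel)
}

#' Simulate a magic-angle decay histogram
#'
#' Scales the decay so its noise-free, background-free total equals the
#' photon budget, reconvolves with the IRF, adds the background and draws
#' Poisson counts.
#'
#' @param params decay parameters; `amplitude` is overridden by the budget.
#' @param settings an [acquisition_settings()] object (supplies
#'   `photon_budget`).
#' @param irf an `irf_kernel`.
#' @param seed integer seed.
#' @return A [decay_histogram()] with attribute `"truth"` holding the
#'   budget-scaled generating parameters.
#' @export
#' @examples
#' s <- acquisition_settings(photon_budget = 1e5)
#' irf <- gaussian_irf(s, fwhm = 200)
#' h <- simulate_decay(multiexp_params(c(266, 781), c(0.793, 0.207)),
#'                     s, irf, seed = 1)
simulate_decay <- function(params, settings, irf, seed) {
  params <- scale_to_budget(params, settings, settings$photon_budget)
  shape <- multiexp_curve(params, settings) - params$background
  expected <- clamp_roundoff(reconvolve(shape, irf)) + params$background
  h <- sample_histogram(expected, settings, seed, channel = "magic")
  attr(h, "truth") <- params
  h
}

#' Simulate a polarised channel triplet
#'
#' Simulates parallel, perpendicular and magic-angle histograms of the same
#' emitter under identical integration. The photon budget fixes the
#' expected total of the magic-angle channel; the parallel and perpendicular
#' totals then follow from the anisotropy.
#'
#' @inheritParams simulate_decay
#' @param aniso anisotropy parameters ([aniso_params()]).
#' @return A [polarized_measurement()] with attribute `"truth"` (list of
#'   budget-scaled decay and anisotropy parameters). Channel seeds are
#'   `seed`, `seed + 1`, `seed + 2` for parallel/perpendicular/magic.
#' @export
simulate_polarized <- function(params, aniso, settings, irf, seed) {
  # magic = total/3, so total must integrate to 3x the per-channel budget
  params <- scale_to_budget(params, settings, 3 * settings$photon_budget)
  ch <- lapply(expected_polarized(params, aniso, settings, irf),
               clamp_roundoff)
  seed <- as.integer(seed)
  m <- polarized_measurement(
    parallel = sample_histogram(ch$parallel, settings, seed, "parallel"),
    perpendicular = sample_histogram(ch$perpendicular, settings, seed + 1L,
                                     "perpendicular"),
    magic = sample_histogram(ch$magic, settings, seed + 2L, "magic"),
    g_factor = aniso$g_factor
  )
  attr(m, "truth") <- list(params = params, aniso = aniso)
  m
}
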