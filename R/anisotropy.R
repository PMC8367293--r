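#' Polarised measurement triplet
#'
#' Parallel and perpendicular decay histograms (plus an optional
#' magic-angle channel) recorded under vertically polarised excitation,
#' together with the instrumental G-factor.
#'
#' @param parallel,perpendicular [decay_histogram()] objects on the same
#'   axis.
#' @param magic optional magic-angle [decay_histogram()].
#' @param g_factor instrumental polarisation bias G (> 0).
#' @return An object of class `polarized_measurement`.
#' @export
polarized_measurement <- function(parallel, perpendicular, magic = NULL,
                                  g_factor = 1) {
  stopifnot(inherits(parallel, "decay_histogram"),
            inherits(perpendicular, "decay_histogram"))
  check_same_axis(length(parallel$counts), length(perpendicular$counts),
                  "parallel/perpendicular")
  if (!is.null(magic)) {
    stopifnot(inherits(magic, "decay_histogram"))
    check_same_axis(length(parallel$counts), length(magic$counts),
                    "parallel/magic")
  }
  if (g_factor <= 0) stop("`g_factor` must be > 0")
  structure(list(parallel = parallel, perpendicular = perpendicular,
                 magic = magic, g_factor = g_factor),
            class = "polarized_measurement")
}

#' G-factor from a horizontally excited sample
#'
#' Under horizontally polarised excitation both emission polarisations see
#' the same photoselected population, so the ratio of recorded steady-state
#' intensities \eqn{G = I'_\parallel / I'_\perp} isolates the instrument's
#' polarisation bias.
#'
#' @param par_hexc total recorded counts, parallel (vertical) analyser.
#' @param perp_hexc total recorded counts, perpendicular (horizontal)
#'   analyser (> 0).
#' @return The scalar G.
#' @export
g_factor <- function(par_hexc, perp_hexc) {
  if (perp_hexc <= 0) stop("`perp_hexc` must be > 0")
  par_hexc / perp_hexc
}

#' Steady-state fluorescence anisotropy
#'
#' \deqn{r = \frac{I_\parallel - G I_\perp}{I_\parallel + 2 G I_\perp}}
#' from steady-state (summed) channel intensities, with the G-factor
#' correcting the recorded perpendicular intensity.
#'
#' @param i_par parallel intensity (counts).
#' @param i_perp recorded perpendicular intensity (counts).
#' @param g G-factor.
#' @return The anisotropy r (in [-0.5, 1] for non-negative intensities).
#' @export
#' @examples
#' steady_state_anisotropy(2, 1, 1) # 0.25
steady_state_anisotropy <- function(i_par, i_perp, g = 1) {
  denom <- i_par + 2 * g * i_perp
  if (denom <= 0) stop("total intensity is zero; anisotropy undefined")
  (i_par - g * i_perp) / denom
}

#' Steady-state anisotropy of a polarised measurement
#'
#' Sums each channel over the analysis window (the same window convention
#' as the lifetime fits) and applies [steady_state_anisotropy()].
#'
#' @param meas a [polarized_measurement()].
#' @param window `c(start_ps, end_ps)` or `NULL` for the default window.
#' @return The anisotropy r.
#' @export
measurement_anisotropy <- function(meas, window = NULL) {
  stopifnot(inherits(meas, "polarized_measurement"))
  win <- resolve_window(meas$parallel$counts, meas$parallel$settings, window)
  steady_state_anisotropy(sum(meas$parallel$counts[win]),
                          sum(meas$perpendicular$counts[win]),
                          meas$g_factor)
}

#' 1/e rotational correlation time
#'
#' For the single-exponential anisotropy model
#' \eqn{r(t) = r_0 e^{-t/\theta}}, the time at which the anisotropy has
#' decayed to 1/e of its initial value is exactly \eqn{\theta}.
#'
#' @param aniso an [aniso_params()] object.
#' @return The correlation time in ps.
#' @export
correlation_time_1e <- function(aniso) {
  stopifnot(inherits(aniso, "aniso_params"))
  aniso$theta
}

#' Closed-form steady-state anisotropy of a model
#'
#' Integrating \eqn{I(t) r(t)} and \eqn{I(t)} over all time for a
#' multi-exponential intensity decay and single-exponential anisotropy
#' decay gives
#' \deqn{r_{ss} = r_0 \frac{\sum_i \alpha_i \tau_i \theta / (\tau_i +
#'   \theta)}{\sum_i \alpha_i \tau_i},}
#' a cross-check linking the time-resolved parameters to the steady-state
#' anisotropy.
#'
#' @param decay a [multiexp_params()] object.
#' @param aniso an [aniso_params()] object.
#' @return The model steady-state anisotropy.
#' @export
#' @examples
#' bound <- multiexp_params(c(804, 2503), c(0.851, 0.149))
#' steady_state_from_model(bound, aniso_params(0.35, 15900)) # ~0.322
steady_state_from_model <- function(decay, aniso) {
  stopifnot(inherits(decay, "multiexp_params"),
            inherits(aniso, "aniso_params"))
  a <- decay$fractions
  tau <- decay$lifetimes
  th <- aniso$theta
  aniso$r0 * sum(a * tau * th / (tau + th)) / sum(a * tau)
}

#' Global time-resolved anisotropy fit
#'
#' Joint weighted least-squares fit of the parallel and perpendicular
#' channels with the decay parameters fixed from a prior magic-angle fit,
#' estimating the total amplitude, the initial anisotropy r0 and the
#' rotational correlation time theta of a single-exponential anisotropy
#' decay. The channel models are
#' \deqn{I_\parallel(t) = \tfrac{1}{3} I(t) (1 + 2 r_0 e^{-t/\theta}),
#'   \quad I_\perp^{rec}(t) = \tfrac{1}{3} I(t) (1 - r_0 e^{-t/\theta})/G,}
#' each reconvolved with the IRF, with the periodic wrap applied to every
#' exponential term. Multi-start Levenberg-Marquardt over a fixed theta
#' grid keeps the fit deterministic.
#'
#' @param meas a [polarized_measurement()] (supplies G).
#' @param fixed_decay [multiexp_params()] from the magic-angle fit
#'   (lifetimes and fractions are held fixed; amplitude/background are
#'   re-estimated for the channel pair).
#' @param irf an `irf_kernel`.
#' @param window `c(start_ps, end_ps)` or `NULL` for the default window
#'   (taken from the parallel channel).
#' @param t0 fixed IRF shift in ps, carried over from the magic-angle fit.
#' @param fit_background fit a shared per-channel constant background
#'   (default: fixed 0).
#' @return A list with `r0`, `theta`, `stderr` (named, for r0 and theta),
#'   `chi2_reduced`, `converged`, `flags` and the raw optimiser record
#'   `fit`. A fit pinned at an r0 bound, or with r0 consistent with zero
#'   (theta unidentifiable), is flagged.
#' @export
fit_anisotropy_decay <- function(meas, fixed_decay, irf, window = NULL,
                                 t0 = 0, fit_background = FALSE) {
  stopifnot(inherits(meas, "polarized_measurement"),
            inherits(fixed_decay, "multiexp_params"),
            inherits(irf, "irf_kernel"))
  settings <- meas$parallel$settings
  tt <- time_axis(settings)
  G <- meas$g_factor
  win <- resolve_window(meas$parallel$counts, settings, window)
  irf_fft <- stats::fft(irf$values)
  shift <- t0 / settings$bin_width

  y_par <- meas$parallel$counts[win]
  y_perp <- meas$perpendicular$counts[win]
  sw_par <- sqrt(1 / pmax(y_par, 1))
  sw_perp <- sqrt(1 / pmax(y_perp, 1))

  taus <- fixed_decay$lifetimes
  alphas <- fixed_decay$fractions
  tot_shape <- numeric(settings$n_bins)
  for (i in seq_along(taus)) {
    tot_shape <- tot_shape +
      alphas[i] * wrapped_exp(tt, taus[i], settings$rep_period)
  }
  cross_shape <- function(theta) {
    y <- numeric(settings$n_bins)
    for (i in seq_along(taus)) {
      tau_c <- 1 / (1 / taus[i] + 1 / theta)
      y <- y + alphas[i] * wrapped_exp(tt, tau_c, settings$rep_period)
    }
    y
  }

  # p = [log A, r0, log theta, (C)]
  resid_fn <- function(p) {
    A <- exp(p[1]); r0 <- p[2]; theta <- exp(p[3])
    C <- if (fit_background) p[4] else 0
    cr <- r0 * cross_shape(theta)
    m_par <- conv_shift(A * (tot_shape + 2 * cr) / 3, irf_fft, shift) + C
    m_perp <- conv_shift(A * (tot_shape - cr) / (3 * G), irf_fft, shift) + C
    c((m_par[win] - y_par) * sw_par, (m_perp[win] - y_perp) * sw_perp)
  }

  A0 <- log(max((sum(y_par) + 2 * G * sum(y_perp)) /
                  max(sum(tot_shape[win]), 1e-12), 1e-9))
  lower <- c(-30, -0.2, log(10))
  upper <- c(60, 0.4, log(1e6))
  if (fit_background) {
    lower <- c(lower, 0)
    upper <- c(upper, max(max(y_par), 1))
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-13,
                                     ptol = 1e-13, gtol = 1e-14,
                                     maxfev = 2000)
  starts <- list(c(0.30, 1000), c(0.30, 8000), c(0.30, 30000),
                 c(0.10, 4000), c(0.35, 16000))
  best <- NULL
  for (st in starts) {
    p0 <- c(A0, st[1], log(st[2]))
    if (fit_background) p0 <- c(p0, 1e-3)
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn, control = ctrl),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop("optimizer failed from every start")

  # IRLS refinement with model-based Poisson weights (see fit_decay)
  channel_models <- function(p) {
    A <- exp(p[1]); r0 <- p[2]; theta <- exp(p[3])
    C <- if (fit_background) p[4] else 0
    cr <- r0 * cross_shape(theta)
    list(par = conv_shift(A * (tot_shape + 2 * cr) / 3, irf_fft, shift) + C,
         perp = conv_shift(A * (tot_shape - cr) / (3 * G), irf_fft,
                           shift) + C)
  }
  for (pass in 1:2) {
    mm <- channel_models(best$par)
    sw_par <- sqrt(1 / pmax(mm$par[win], 1))
    sw_perp <- sqrt(1 / pmax(mm$perp[win], 1))
    res <- tryCatch(
      minpack.lm::nls.lm(par = best$par, lower = lower, upper = upper,
                         fn = resid_fn, control = ctrl),
      error = function(e) NULL
    )
    if (!is.null(res)) best <- res
  }

  r0_hat <- best$par[2]
  theta_hat <- exp(best$par[3])
  dof <- 2L * length(win) - length(best$par)
  chi2_red <- best$deviance / max(dof, 1L)
  se <- c(r0 = NA_real_, theta = NA_real_)
  cov_p <- tryCatch(chi2_red * solve(best$hessian), error = function(e) NULL)
  if (!is.null(cov_p)) {
    se["r0"] <- sqrt(max(cov_p[2, 2], 0))
    se["theta"] <- theta_hat * sqrt(max(cov_p[3, 3], 0))
  }

  flags <- character(0)
  if (r0_hat <= lower[2] + 1e-9 || r0_hat >= upper[2] - 1e-9) {
    flags <- c(flags, "r0_at_bound")
  }
  if (is.finite(se["r0"]) && abs(r0_hat) < 2 * se["r0"]) {
    flags <- c(flags, "theta_unidentifiable")
  }
  converged <- best$info %in% c(1:4, 6:8)
  if (!converged) flags <- c(flags, "not_converged")
  list(r0 = r0_hat, theta = theta_hat, amplitude = exp(best$par[1]),
       stderr = se, chi2_reduced = chi2_red, converged = converged,
       n_iterations = best$niter, window = win, flags = flags, fit = best)
}
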