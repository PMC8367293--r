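#' Acquisition settings for a TCSPC measurement
#'
#' Describes the time axis and photon budget of a time-correlated single
#' photon counting (TCSPC) acquisition. The default axis is 4096 bins of
#' 6.1035 ps, spanning one repetition period of a 40 MHz pulsed laser
#' (25 ns), so that the recorded histogram covers the full excitation
#' period and the periodic (incomplete-decay) wrap is exact under circular
#' convolution.
#'
#' @param n_bins number of histogram bins (positive integer).
#' @param bin_width width of one bin in ps.
#' @param rep_period laser repetition period in ps (40 MHz gives 25,000 ps).
#' @param photon_budget expected total number of detected photons in the
#'   histogram (counts). For polarised triplets this is the expected count
#'   in the magic-angle channel.
#' @param integration_time acquisition duration in seconds (metadata only;
#'   used when scaling control subtractions).
#'
#' @return An object of class `acquisition_settings`.
#' @export
#' @examples
#' s <- acquisition_settings()
#' s$n_bins * s$bin_width # ~ one 25 ns period
acquisition_settings <- function(n_bins = 4096L,
                                 bin_width = 6.1035,
                                 rep_period = 25000,
                                 photon_budget = 1e6,
                                 integration_time = 2) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L, bin_width > 0, rep_period > 0, photon_budget >= 0,
            integration_time > 0)
  structure(
    list(n_bins = n_bins, bin_width = bin_width, rep_period = rep_period,
         photon_budget = photon_budget, integration_time = integration_time),
    class = "acquisition_settings"
  )
}

#' Time axis of an acquisition
#'
#' Bin-centre times in ps (0-based bins; bin i covers
#' `[i*bin_width, (i+1)*bin_width)`).
#'
#' @param settings an [acquisition_settings()] object.
#' @return Numeric vector of length `n_bins`.
#' @export
time_axis <- function(settings) {
  (seq_len(settings$n_bins) - 0.5) * settings$bin_width
}

#' Gaussian instrument response function
#'
#' Builds a discrete Gaussian instrument response function (IRF) on the
#' acquisition time axis, evaluated at bin centres and renormalised to unit
#' sum. The experimental IRF of a TCSPC detector is characterised here only
#' by its full width at half maximum; a Gaussian shape is used for the two
#' detector classes modelled (fast hybrid PMT, FWHM ~35 ps; cooled PMT,
#' FWHM ~200 ps).
#'
#' @param settings an [acquisition_settings()] object.
#' @param center position of the IRF maximum (ps). Defaults to 1000 ps so
#'   the rising edge of the convolved decay is fully sampled.
#' @param fwhm full width at half maximum (ps).
#'
#' @return An object of class `irf_kernel` with fields `center`, `fwhm`
#'   and `values` (per-bin weights summing to 1).
#' @export
#' @examples
#' irf <- gaussian_irf(acquisition_settings(), fwhm = 200)
#' sum(irf$values)
gaussian_irf <- function(settings, center = 1000, fwhm = 200) {
  stopifnot(inherits(settings, "acquisition_settings"))
  if (fwhm <= 0) stop("`fwhm` must be > 0")
  if (fwhm < settings$bin_width / 10) {
    stop("degenerate IRF kernel: `fwhm` (", fwhm,
         " ps) is below bin_width/10; use a delta kernel or coarser axis")
  }
  t_max <- settings$n_bins * settings$bin_width
  if (center < 0 || center >= t_max) {
    stop("`center` must lie within [0, ", t_max, ") ps")
  }
  tt <- time_axis(settings)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- exp(-0.5 * ((tt - center) / sigma)^2)
  w <- w / sum(w)
  structure(list(center = center, fwhm = fwhm, values = w),
            class = "irf_kernel")
}

#' Delta (identity) instrument response function
#'
#' IRF with all weight in a single bin; convolving with it shifts the curve
#' to that bin. Useful for tests and for analysing data that need no
#' reconvolution.
#'
#' @param settings an [acquisition_settings()] object.
#' @param bin 0-based index of the bin carrying the unit weight.
#' @return An `irf_kernel`.
#' @export
delta_irf <- function(settings, bin = 0L) {
  stopifnot(inherits(settings, "acquisition_settings"))
  bin <- as.integer(bin)
  stopifnot(bin >= 0L, bin < settings$n_bins)
  w <- numeric(settings$n_bins)
  w[bin + 1L] <- 1
  structure(list(center = (bin + 0.5) * settings$bin_width,
                 fwhm = 0, values = w),
            class = "irf_kernel")
}

#' @export
print.acquisition_settings <- function(x, ...) {
  cat("TCSPC acquisition settings\n")
  cat(sprintf("  %d bins x %.4f ps = %.1f ns window; period %.1f ns\n",
              x$n_bins, x$bin_width, x$n_bins * x$bin_width / 1000,
              x$rep_period / 1000))
  cat(sprintf("  photon budget %.3g counts, integration %.3g s\n",
              x$photon_budget, x$integration_time))
  invisible(x)
}

#' @export
print.irf_kernel <- function(x, ...) {
  cat(sprintf("IRF kernel: center %.1f ps, FWHM %.1f ps, %d bins (unit sum)\n",
              x$center, x$fwhm, length(x$values)))
  invisible(x)
}

# Zero out sub-epsilon negatives introduced by FFT round-off; genuinely
# negative curves still error downstream.
clamp_roundoff <- function(x) {
  tol <- 1e-9 * max(abs(x), 1)
  x[x < 0 & x > -tol] <- 0
  x
}

# Internal: check two objects share a time axis.
check_same_axis <- function(n_a, n_b, what = "inputs") {
  if (n_a != n_b) {
    stop("time axis mismatch: ", what, " have ", n_a, " and ", n_b, " bins")
  }
  invisible(TRUE)
}
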