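#' Normalise series intensities to their maximum
#'
#' Per-experiment normalisation: intensities are divided by the series
#' maximum, so values lie in (0, 1] with the maximum exactly 1. Series are
#' never normalised across datasets.
#'
#' @param intensities numeric vector of total signals (one per condition).
#' @return Normalised intensities.
#' @export
normalize_intensity <- function(intensities) {
  m <- max(intensities)
  if (m <= 0) stop("all intensities are <= 0; cannot normalise")
  intensities / m
}

#' Trend slope over a condition range
#'
#' Average slope of a response over a condition range, by ordinary least
#' squares (default) or as the mean of all pairwise slopes (a sensitivity
#' variant).
#'
#' @param x condition values (at least 2 distinct).
#' @param y responses, same length.
#' @param method `"ols"` or `"pairwise"`.
#' @return A list with `slope`, `intercept` and `stderr` (of the slope).
#' @export
#' @examples
#' trend_slope(c(25, 35, 45), c(1.00, 0.78, 0.56))$slope # -0.022 per degC
trend_slope <- function(x, y, method = c("ols", "pairwise")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 2) stop("need at least 2 distinct x values")
  if (method == "ols") {
    fit <- stats::lm(y ~ x)
    # summary.lm warns on exactly collinear input; the zero stderr is valid
    co <- suppressWarnings(summary(fit)$coefficients)
    list(slope = unname(co["x", "Estimate"]),
         intercept = unname(co["(Intercept)", "Estimate"]),
         stderr = unname(co["x", "Std. Error"]))
  } else {
    pairs <- utils::combn(length(x), 2)
    dx <- x[pairs[2, ]] - x[pairs[1, ]]
    keep <- dx != 0
    s <- (y[pairs[2, ]] - y[pairs[1, ]])[keep] / dx[keep]
    slope <- mean(s)
    list(slope = slope, intercept = mean(y) - slope * mean(x),
         stderr = if (length(s) > 1) stats::sd(s) / sqrt(length(s))
                  else NA_real_)
  }
}

# Flatten one fit_result into a named parameter vector.
fit_param_vector <- function(fr) {
  p <- fr$params
  k <- length(p$lifetimes)
  v <- c(p$lifetimes, p$fractions, p$amplitude, p$background, fr$t0,
         mean_lifetime(p))
  names(v) <- c(paste0("tau", seq_len(k)), paste0("alpha", seq_len(k)),
                "I0", "C", "t0", "taum")
  v
}

#' Aggregate replicate fit results
#'
#' Per-parameter sample mean and standard deviation (n-1 denominator)
#' across independent replicate fits of the same model order; the
#' intensity-weighted mean lifetime is aggregated alongside the raw
#' parameters.
#'
#' @param results non-empty list of `fit_result` objects with the same
#'   number of components.
#' @return An object of class `replicate_summary` with named `mean` and
#'   `std` vectors and the replicate count `n` (`std` is 0 when n = 1).
#' @export
aggregate_replicates <- function(results) {
  if (length(results) == 0) stop("`results` must be non-empty")
  orders <- vapply(results, function(f) length(f$params$lifetimes),
                   integer(1))
  if (length(unique(orders)) != 1L) {
    stop("mixed model orders: ", paste(unique(orders), collapse = ", "))
  }
  mat <- t(vapply(results, fit_param_vector,
                  fit_param_vector(results[[1]])))
  n <- nrow(mat)
  m <- colMeans(mat)
  s <- if (n == 1L) {
    stats::setNames(rep(0, ncol(mat)), colnames(mat))
  } else {
    apply(mat, 2, stats::sd)
  }
  structure(list(mean = m, std = s, n = n), class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("replicate summary (n = %d):\n", x$n))
  for (nm in names(x$mean)) {
    cat(sprintf("  %-6s %10.4g +/- %.4g\n", nm, x$mean[nm], x$std[nm]))
  }
  invisible(x)
}

#' Titration curve vs binding model
#'
#' Compares fitted bound-intensity fractions against the quadratic
#' binding-model prediction, condition by condition, reporting residuals
#' and the Spearman rank correlation (the binding model is expected to
#' track the fitted trend, not its exact values).
#'
#' @param conditions list of [binding_condition()] objects, one per
#'   titration point.
#' @param estimates fitted intensity fractions `f_int` (same length).
#' @return A `data.frame` with columns `ratio`, `f_theory`, `f_fitted`,
#'   `residual`, carrying the Spearman correlation in attribute
#'   `"spearman"`.
#' @export
binding_curve <- function(conditions, estimates) {
  if (length(conditions) != length(estimates)) {
    stop("`conditions` and `estimates` must have the same length")
  }
  ratio <- vapply(conditions, function(cc) {
    if (cc$nadh_total > 0) cc$ldh_total / cc$nadh_total else NA_real_
  }, numeric(1))
  f_theory <- vapply(conditions, function(cc) bound_fractions(cc)$f_int,
                     numeric(1))
  out <- data.frame(ratio = ratio, f_theory = f_theory,
                    f_fitted = as.numeric(estimates),
                    residual = as.numeric(estimates) - f_theory)
  rho <- if (stats::sd(f_theory) == 0 || stats::sd(out$f_fitted) == 0) {
    if (max(abs(out$residual)) < 1e-12) 1 else NA_real_
  } else {
    stats::cor(f_theory, out$f_fitted, method = "spearman")
  }
  attr(out, "spearman") <- rho
  out
}

#' Emission-spectrum peak wavelength
#'
#' Locates the emission maximum by fitting a parabola through the largest
#' sample and its two neighbours (three-point quadratic interpolation),
#' giving sub-grid resolution on smooth spectra; used to quantify the
#' blue shift of NADH emission on protein binding.
#'
#' @param wavelengths wavelength grid in nm (at least 3 points,
#'   increasing).
#' @param intensities spectral intensities (arbitrary units).
#' @return Peak wavelength in nm (within the grid range). If the maximum
#'   sits on a grid edge the edge wavelength is returned with a warning.
#' @export
spectral_peak <- function(wavelengths, intensities) {
  n <- length(wavelengths)
  stopifnot(n >= 3, length(intensities) == n)
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("`wavelengths` must be strictly increasing")
  }
  i <- which.max(intensities)
  if (i == 1L || i == n) {
    warning("spectrum maximum at grid edge; returning the edge wavelength")
    return(wavelengths[i])
  }
  x <- wavelengths[(i - 1):(i + 1)]
  y <- intensities[(i - 1):(i + 1)]
  # vertex of the quadratic through three (possibly non-uniform) points
  d21 <- (y[2] - y[1]) / (x[2] - x[1])
  d32 <- (y[3] - y[2]) / (x[3] - x[2])
  a <- (d32 - d21) / (x[3] - x[1])
  if (a >= 0) return(wavelengths[i]) # flat/degenerate: keep the sample max
  b <- d21 - a * (x[1] + x[2])
  vx <- -b / (2 * a)
  min(max(vx, x[1]), x[3])
}

#' Build a condition-series table
#'
#' Fits every histogram of a simulated (or loaded) condition series and
#' assembles the series-level table: condition value, fitted parameters,
#' mean lifetime, total and normalised intensity, and (for polarised
#' series) the steady-state anisotropy.
#'
#' @param series a `condition_series_sim` from
#'   [simulate_condition_series()].
#' @param irf the `irf_kernel` used for fitting.
#' @param spec a [fit_spec()] applied to each condition (default
#'   2-component).
#' @return A `data.frame`, one row per condition, with the per-condition
#'   `fit_result`s attached as attribute `"fits"`.
#' @export
analyze_condition_series <- function(series, irf, spec = fit_spec()) {
  stopifnot(inherits(series, "condition_series_sim"))
  rows <- vector("list", length(series))
  fits <- vector("list", length(series))
  for (i in seq_along(series)) {
    el <- series[[i]]
    meas <- el$measurement
    polar <- inherits(meas, "polarized_measurement")
    hist <- if (polar) meas$magic else meas
    fr <- fit_decay(hist, irf, spec)
    fits[[i]] <- fr
    rows[[i]] <- data.frame(
      condition = el$condition,
      t(fit_param_vector(fr)),
      total_signal = total_signal(hist),
      anisotropy = if (polar) measurement_anisotropy(meas) else NA_real_,
      chi2_reduced = fr$chi2_reduced,
      converged = fr$converged
    )
  }
  out <- do.call(rbind, rows)
  out$norm_intensity <- normalize_intensity(out$total_signal)
  attr(out, "fits") <- fits
  attr(out, "condition_name") <- attr(series, "condition_name")
  out
}
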