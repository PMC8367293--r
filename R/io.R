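#' Write a decay histogram to CSV
#'
#' Plain-text histogram format: comment header lines
#' `# rep_period_ps=`, `# bin_width_ps=`, `# channel=`,
#' `# integration_time_s=`, then a `time_ps,counts` table with bin-centre
#' times. `write_histogram()` followed by [read_histogram()] is the
#' identity on counts and metadata.
#'
#' @param hist a [decay_histogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  s <- hist$settings
  header <- c(
    sprintf("# rep_period_ps=%.10g", s$rep_period),
    sprintf("# bin_width_ps=%.10g", s$bin_width),
    sprintf("# channel=%s", hist$channel),
    sprintf("# integration_time_s=%.10g", s$integration_time),
    "time_ps,counts"
  )
  body <- sprintf("%.10g,%d", time_axis(s), as.integer(round(hist$counts)))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a decay histogram from CSV
#'
#' Parses the format written by [write_histogram()]. LF and CRLF line
#' endings are both accepted. Malformed inputs raise specific errors: a
#' missing header key names the key, non-integer counts and a non-uniform
#' time grid are rejected.
#'
#' @param path file path.
#' @param photon_budget optional photon budget to record in the settings
#'   (defaults to the histogram total).
#' @return A [decay_histogram()].
#' @export
read_histogram <- function(path, photon_budget = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  head_idx <- grep("^#", lines)
  meta <- list()
  for (ln in lines[head_idx]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
    }
  }
  for (key in c("rep_period_ps", "bin_width_ps", "channel",
                "integration_time_s")) {
    if (is.null(meta[[key]])) {
      stop("malformed histogram header: missing key `", key, "`")
    }
  }
  body <- lines[setdiff(seq_along(lines), head_idx)]
  if (length(body) < 2 || body[1] != "time_ps,counts") {
    stop("malformed histogram: expected `time_ps,counts` column header")
  }
  tab <- utils::read.csv(text = body, header = TRUE)
  if (!all(c("time_ps", "counts") %in% names(tab))) {
    stop("malformed histogram: need columns time_ps, counts")
  }
  counts <- tab$counts
  if (any(!is.finite(counts)) || any(abs(counts - round(counts)) > 1e-9)) {
    stop("malformed histogram: counts must be non-negative integers")
  }
  bw <- as.numeric(meta$bin_width_ps)
  dt <- diff(tab$time_ps)
  if (length(dt) > 0 && (max(dt) - min(dt) > 1e-6 * bw ||
                         abs(dt[1] - bw) > 1e-6 * bw)) {
    stop("malformed histogram: time grid is not uniform with the stated ",
         "bin width")
  }
  settings <- acquisition_settings(
    n_bins = nrow(tab), bin_width = bw,
    rep_period = as.numeric(meta$rep_period_ps),
    photon_budget = if (is.null(photon_budget)) sum(counts)
                    else photon_budget,
    integration_time = as.numeric(meta$integration_time_s)
  )
  decay_histogram(counts, settings, channel = meta$channel)
}

#' Serialise a fit result to JSON
#'
#' Writes parameters, standard errors, goodness of fit, window and t0 to a
#' JSON file that [read_fit_json()] restores losslessly (unknown keys in
#' the file are rejected on read).
#'
#' @param fit a `fit_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  obj <- list(
    lifetimes_ps = fit$params$lifetimes,
    fractions = fit$params$fractions,
    amplitude = fit$params$amplitude,
    background = fit$params$background,
    t0_ps = fit$t0,
    mean_lifetime_ps = mean_lifetime(fit$params),
    chi2_reduced = fit$chi2_reduced,
    stderr = as.list(fit$stderr),
    converged = fit$converged,
    n_iterations = fit$n_iterations,
    window_bins = range(fit$window),
    flags = fit$flags
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "list")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("lifetimes_ps", "fractions", "amplitude", "background",
             "t0_ps", "mean_lifetime_ps", "chi2_reduced", "stderr",
             "converged", "n_iterations", "window_bins", "flags")
  extra <- setdiff(names(obj), known)
  if (length(extra) > 0) {
    stop("unknown keys in fit JSON: ", paste(extra, collapse = ", "))
  }
  obj
}

#' Generate the canonical synthetic dataset bundle
#'
#' Writes a deterministic bundle of simulated measurements covering the
#' modelled study conditions: free NADH at 25 and 37 degC, fully LDH-bound
#' NADH, a polarised triplet of the bound species, an LDH titration at
#' ratios 0-4 and a 25-45 degC temperature series. Every histogram is a
#' [write_histogram()] CSV with a JSON ground-truth sidecar recording the
#' generating parameters and the master seed; two invocations with the
#' same seed produce byte-identical bundles.
#'
#' @param dir output directory (created if needed).
#' @param master_seed integer master seed.
#' @param photon_budget photon budget per histogram (default 1e5: enough
#'   for meaningful fits while keeping the bundle quick to build).
#' @param n_bins,bin_width time axis (default 1024 x 24.414 ps = one 25 ns
#'   period at reduced resolution).
#' @param kd titration dissociation constant (uM). The default 10 uM is on
#'   the literature low-micromolar scale for the LDH-NADH complex and
#'   spreads the bound fraction across the 0-4 titration ratios.
#' @return Invisibly, a character vector of the files written.
#' @export
make_fixtures <- function(dir, master_seed = 1L, photon_budget = 1e5,
                          n_bins = 1024L, bin_width = 24.414, kd = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(master_seed)
  s <- acquisition_settings(n_bins = n_bins, bin_width = bin_width,
                            photon_budget = photon_budget)
  irf_slow <- gaussian_irf(s, fwhm = 200)
  irf_fast <- gaussian_irf(s, fwhm = 35)
  free25 <- multiexp_params(c(266, 781), c(0.793, 0.207))
  free37 <- multiexp_params(c(252, 683), c(0.81, 0.19))
  bound <- multiexp_params(c(804, 2503), c(0.851, 0.149))
  files <- character(0)
  truth_of <- function(p) list(lifetimes_ps = p$lifetimes,
                               fractions = p$fractions,
                               amplitude = p$amplitude,
                               background = p$background,
                               mean_lifetime_ps = mean_lifetime(p))
  emit <- function(hist, truth, stem) {
    csv <- file.path(dir, paste0(stem, ".csv"))
    js <- file.path(dir, paste0(stem, ".json"))
    write_histogram(hist, csv)
    jsonlite::write_json(c(truth, list(master_seed = seed)), js,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, csv, js)
  }

  h <- simulate_decay(free25, s, irf_slow, seed)
  emit(h, truth_of(attr(h, "truth")), "free_nadh_25C_magic")
  h <- simulate_decay(free37, s, irf_slow, seed + 100L)
  emit(h, truth_of(attr(h, "truth")), "free_nadh_37C_magic")
  h <- simulate_decay(bound, s, irf_fast, seed + 200L)
  emit(h, truth_of(attr(h, "truth")), "bound_nadh_magic")

  an <- aniso_params(r0 = 0.35, theta = 15900, g_factor = 1)
  trip <- simulate_polarized(bound, an, s, irf_fast, seed + 300L)
  tr <- attr(trip, "truth")
  truth <- c(truth_of(tr$params),
             list(r0 = an$r0, theta_ps = an$theta, g_factor = an$g_factor))
  for (ch in c("parallel", "perpendicular", "magic")) {
    emit(trip[[ch]], truth, paste0("bound_nadh_", ch))
  }

  tit <- titration_spec(free37, bound, nadh_total = 12.5, kd = kd)
  ratios <- c(0, 0.25, 0.5, 1, 2, 4)
  ser <- simulate_condition_series(tit, ratios, s, irf_fast, seed + 400L)
  for (el in ser) {
    truth <- c(truth_of(el$truth$params),
               list(ldh_ratio = el$condition, f_conc = el$truth$f_conc,
                    f_int = el$truth$f_int))
    emit(el$measurement, truth,
         sprintf("titration_ratio_%s", gsub("\\.", "p", el$condition)))
  }

  env <- environment_model(free25)
  temps <- c(25, 30, 35, 40, 45)
  ser <- simulate_condition_series(env, temps, s, irf_slow, seed + 500L)
  for (el in ser) {
    truth <- c(truth_of(el$truth$params),
               list(temperature_C = el$condition,
                    rel_intensity = el$truth$rel_intensity))
    emit(el$measurement, truth, sprintf("temperature_%gC", el$condition))
  }
  invisible(files)
}
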