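#' Microenvironmental response model
#'
#' Linear response of the free-NADH decay to a condition variable
#' (temperature by default), anchored at a reference parameter set. The
#' default slopes are the dataset-averaged rates for aqueous NADH:
#' intensity -2.2 %/degC, intensity-weighted mean lifetime -8 ps/degC and
#' steady-state anisotropy -9.9e-4 /degC. A per-condition parameter table
#' (e.g. for pH, where no linear model applies) overrides the slopes.
#'
#' @param reference_params [multiexp_params()] at the reference condition
#'   (25 degC, pH 7.4 by default).
#' @param taum_slope mean-lifetime change per unit condition (ps/degC).
#' @param intensity_slope normalised-intensity change per unit condition
#'   (fraction/degC).
#' @param anisotropy_slope steady-state anisotropy change per unit
#'   condition (1/degC).
#' @param reference_condition condition value at which `reference_params`
#'   hold (degC for temperature).
#' @param condition_name label: `"temperature"` or `"pH"`.
#' @param valid_range range outside which simulation warns (the modelled
#'   temperature range is 25-45 degC).
#' @param per_condition_table optional `data.frame` with columns
#'   `condition`, `tau1`, `tau2`, `alpha1` and optionally `rel_intensity`;
#'   required for pH series.
#' @param aniso optional [aniso_params()] at the reference condition; when
#'   present, condition series are simulated as polarised triplets.
#' @return An object of class `environment_model`.
#' @export
environment_model <- function(reference_params,
                              taum_slope = -8,
                              intensity_slope = -0.022,
                              anisotropy_slope = -9.9e-4,
                              reference_condition = 25,
                              condition_name = "temperature",
                              valid_range = c(25, 45),
                              per_condition_table = NULL,
                              aniso = NULL) {
  stopifnot(inherits(reference_params, "multiexp_params"),
            is.finite(taum_slope), is.finite(intensity_slope),
            is.finite(anisotropy_slope))
  if (!is.null(per_condition_table)) {
    need <- c("condition", "tau1", "tau2", "alpha1")
    if (!all(need %in% names(per_condition_table))) {
      stop("`per_condition_table` needs columns: ",
           paste(need, collapse = ", "))
    }
  }
  if (identical(condition_name, "pH") && is.null(per_condition_table)) {
    stop("pH series have no parametric default; supply `per_condition_table`")
  }
  if (!is.null(aniso)) stopifnot(inherits(aniso, "aniso_params"))
  structure(list(reference_params = reference_params,
                 taum_slope = taum_slope,
                 intensity_slope = intensity_slope,
                 anisotropy_slope = anisotropy_slope,
                 reference_condition = reference_condition,
                 condition_name = condition_name,
                 valid_range = valid_range,
                 per_condition_table = per_condition_table,
                 aniso = aniso),
            class = "environment_model")
}

#' Titration specification for free/bound NADH mixtures
#'
#' Fixes the free and fully-bound two-component decay shapes and the
#' binding-model constants of an LDH titration; conditions are given as
#' [LDH]:[NADH] ratios.
#'
#' @param free_shape,bound_shape two-component [multiexp_params()] for the
#'   free and fully LDH-bound species.
#' @param nadh_total total NADH concentration (uM).
#' @param kd per-site dissociation constant (uM); required, no default.
#' @param sites_per_protein binding sites per protein (4 for LDH).
#' @param brightness_ratio bound/free quantum-yield ratio (3.3 for LDH).
#' @return An object of class `titration_spec`.
#' @export
titration_spec <- function(free_shape, bound_shape, nadh_total, kd,
                           sites_per_protein = 4L, brightness_ratio = 3.3) {
  stopifnot(inherits(free_shape, "multiexp_params"),
            inherits(bound_shape, "multiexp_params"),
            length(free_shape$lifetimes) == 2L,
            length(bound_shape$lifetimes) == 2L)
  structure(list(free_shape = free_shape, bound_shape = bound_shape,
                 nadh_total = nadh_total, kd = kd,
                 sites_per_protein = as.integer(sites_per_protein),
                 brightness_ratio = brightness_ratio),
            class = "titration_spec")
}

# Pre-exponential fractions of the 4-component mixture whose *intensity*
# is (1 - f_int) * free + f_int * bound. Amplitude of component i is
# proportional to (intensity share) / tau_i.
mixture_params <- function(free_shape, bound_shape, f_int) {
  wf <- free_shape$fractions * free_shape$lifetimes
  wb <- bound_shape$fractions * bound_shape$lifetimes
  a_free <- (1 - f_int) * (wf / sum(wf)) / free_shape$lifetimes
  a_bound <- f_int * (wb / sum(wb)) / bound_shape$lifetimes
  taus <- c(free_shape$lifetimes, bound_shape$lifetimes)
  amps <- c(a_free, a_bound)
  ord <- order(taus)
  multiexp_params(taus[ord], amps[ord] / sum(amps))
}

#' Simulate a condition series with known ground truth
#'
#' Generates one seeded histogram (or polarised triplet) per condition
#' value, recording the generating parameters alongside for recovery tests.
#' Per-condition seeds are `seed + 10 * (index - 1)` so channel sub-seeds
#' never collide.
#'
#' For an [environment_model()], a mean-lifetime slope is mapped onto the
#' components by scaling both lifetimes by the common factor
#' `taum_target / taum_reference` with the fractions held fixed (the
#' intensity-weighted mean is homogeneous of degree one in the lifetimes,
#' so this hits the target exactly); the photon budget is scaled by the
#' intensity slope, and, when anisotropy is simulated, `r0` is scaled so
#' the closed-form steady-state anisotropy follows the anisotropy slope at
#' fixed rotational correlation time.
#'
#' For a [titration_spec()], each ratio is converted to bound fractions via
#' [bound_fractions()]; the decay is the quadruple-exponential mixture of
#' the fixed free and bound shapes weighted by the intensity fraction, and
#' the photon budget is scaled by the brightness enhancement
#' `1 + f_conc * (brightness_ratio - 1)`.
#'
#' @param model an [environment_model()] or [titration_spec()].
#' @param conditions condition values, sorted ascending (degC, pH, or
#'   [LDH]:[NADH] ratios).
#' @param settings an [acquisition_settings()] object; `photon_budget` is
#'   the reference-condition budget.
#' @param irf an `irf_kernel`.
#' @param seed integer master seed for the series.
#' @return A list of class `condition_series_sim`; each element has
#'   `condition`, `measurement` (a [decay_histogram()] or
#'   [polarized_measurement()]) and `truth` (generating parameters).
#' @export
simulate_condition_series <- function(model, conditions, settings, irf,
                                      seed) {
  UseMethod("simulate_condition_series")
}

#' @export
simulate_condition_series.environment_model <- function(model, conditions,
                                                        settings, irf, seed) {
  if (length(conditions) == 0) stop("`conditions` must be non-empty")
  if (is.unsorted(conditions)) stop("`conditions` must be sorted ascending")
  out <- vector("list", length(conditions))
  ref <- model$reference_params
  taum_ref <- mean_lifetime(ref)
  if (!is.null(model$aniso)) {
    rss_ref <- steady_state_from_model(ref, model$aniso)
  }
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    if (cond < model$valid_range[1] || cond > model$valid_range[2]) {
      warning("condition ", cond, " outside the modelled range [",
              model$valid_range[1], ", ", model$valid_range[2], "]")
    }
    delta <- cond - model$reference_condition
    if (!is.null(model$per_condition_table)) {
      tab <- model$per_condition_table
      row <- which(abs(tab$condition - cond) < 1e-9)
      if (length(row) != 1L) {
        stop("condition ", cond, " not found in `per_condition_table`")
      }
      params <- multiexp_params(c(tab$tau1[row], tab$tau2[row]),
                                c(tab$alpha1[row], 1 - tab$alpha1[row]),
                                background = ref$background)
      rel_int <- if ("rel_intensity" %in% names(tab)) tab$rel_intensity[row]
                 else 1
    } else {
      scale <- (taum_ref + model$taum_slope * delta) / taum_ref
      if (scale <= 0) stop("taum slope drives the mean lifetime below zero")
      params <- multiexp_params(ref$lifetimes * scale, ref$fractions,
                                background = ref$background)
      rel_int <- 1 + model$intensity_slope * delta
    }
    if (rel_int <= 0) stop("intensity slope drives the budget below zero")
    st <- settings
    st$photon_budget <- settings$photon_budget * rel_int
    cond_seed <- as.integer(seed) + 10L * (i - 1L)
    truth <- list(condition = cond, params = params,
                  taum = mean_lifetime(params),
                  photon_budget = st$photon_budget, rel_intensity = rel_int)
    if (is.null(model$aniso)) {
      meas <- simulate_decay(params, st, irf, cond_seed)
      truth$params <- attr(meas, "truth")
    } else {
      rss_target <- rss_ref + model$anisotropy_slope * delta
      ratio <- steady_state_from_model(params, model$aniso) / model$aniso$r0
      an <- aniso_params(r0 = rss_target / ratio, theta = model$aniso$theta,
                         g_factor = model$aniso$g_factor)
      meas <- simulate_polarized(params, an, st, irf, cond_seed)
      truth$params <- attr(meas, "truth")$params
      truth$aniso <- an
      truth$r_ss <- rss_target
    }
    out[[i]] <- list(condition = cond, measurement = meas, truth = truth)
  }
  structure(out, class = "condition_series_sim",
            condition_name = model$condition_name, seed = as.integer(seed))
}

#' @export
simulate_condition_series.titration_spec <- function(model, conditions,
                                                     settings, irf, seed) {
  if (length(conditions) == 0) stop("`conditions` must be non-empty")
  if (is.unsorted(conditions)) stop("`conditions` must be sorted ascending")
  out <- vector("list", length(conditions))
  for (i in seq_along(conditions)) {
    ratio <- conditions[i]
    cond <- binding_condition(nadh_total = model$nadh_total,
                              ldh_total = ratio * model$nadh_total,
                              kd = model$kd,
                              sites_per_protein = model$sites_per_protein,
                              brightness_ratio = model$brightness_ratio)
    fr <- bound_fractions(cond)
    params <- if (fr$f_int == 0) model$free_shape
              else mixture_params(model$free_shape, model$bound_shape,
                                  fr$f_int)
    st <- settings
    enhancement <- 1 + fr$f_conc * (model$brightness_ratio - 1)
    st$photon_budget <- settings$photon_budget * enhancement
    cond_seed <- as.integer(seed) + 10L * (i - 1L)
    meas <- simulate_decay(params, st, irf, cond_seed)
    out[[i]] <- list(condition = ratio, measurement = meas,
                     truth = list(condition = ratio, binding = cond,
                                  f_conc = fr$f_conc, f_int = fr$f_int,
                                  params = attr(meas, "truth"),
                                  photon_budget = st$photon_budget))
  }
  structure(out, class = "condition_series_sim",
            condition_name = "ldh_ratio", seed = as.integer(seed))
}
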