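#' Enzyme-binding titration condition
#'
#' One point of an NADH / lactate dehydrogenase (LDH) titration. Binding
#' sites are treated as independent and identical, with total site
#' concentration `sites_per_protein * ldh_total`.
#'
#' @param nadh_total total NADH concentration (uM, >= 0).
#' @param ldh_total total protein concentration (uM, >= 0).
#' @param kd per-site dissociation constant (uM, > 0). No default: it must
#'   be supplied by the user.
#' @param sites_per_protein binding sites per protein (LDH is a tetramer:
#'   4).
#' @param brightness_ratio bound/free fluorescence quantum-yield ratio
#'   (default 3.3 for LDH-bound NADH).
#' @return An object of class `binding_condition`.
#' @export
binding_condition <- function(nadh_total, ldh_total, kd,
                              sites_per_protein = 4L,
                              brightness_ratio = 3.3) {
  stopifnot(nadh_total >= 0, ldh_total >= 0)
  if (kd <= 0) stop("`kd` must be > 0")
  sites_per_protein <- as.integer(sites_per_protein)
  if (sites_per_protein < 1L) stop("`sites_per_protein` must be >= 1")
  if (brightness_ratio <= 0) stop("`brightness_ratio` must be > 0")
  structure(list(nadh_total = nadh_total, ldh_total = ldh_total, kd = kd,
                 sites_per_protein = sites_per_protein,
                 brightness_ratio = brightness_ratio),
            class = "binding_condition")
}

#' Bound fractions from the quadratic binding equation
#'
#' For total ligand N (NADH), total sites S and per-site dissociation
#' constant Kd, the bound ligand concentration is the physical root of the
#' quadratic mass-action balance,
#' \deqn{B = \frac{(S + N + K_d) - \sqrt{(S + N + K_d)^2 - 4 S N}}{2}.}
#' The concentration fraction bound is \eqn{f_c = B/N}; because bound NADH
#' is brighter, its share of the detected intensity is
#' \deqn{f_I = \frac{f_c\, b}{f_c\, b + (1 - f_c)}}
#' with brightness ratio \eqn{b}.
#'
#' @param cond a [binding_condition()].
#' @return A list with `f_conc` (fraction of NADH molecules bound) and
#'   `f_int` (fraction of detected intensity from the bound species).
#' @export
#' @examples
#' bound_fractions(binding_condition(nadh_total = 12.5, ldh_total = 12.5,
#'                                   kd = 1, sites_per_protein = 4))
bound_fractions <- function(cond) {
  stopifnot(inherits(cond, "binding_condition"))
  N <- cond$nadh_total
  if (N == 0) stop("`nadh_total` is zero: bound fraction undefined")
  S <- cond$sites_per_protein * cond$ldh_total
  K <- cond$kd
  disc <- (S + N + K)^2 - 4 * S * N
  B <- ((S + N + K) - sqrt(max(disc, 0))) / 2
  f_conc <- min(max(B / N, 0), 1)
  b <- cond$brightness_ratio
  f_int <- f_conc * b / (f_conc * b + (1 - f_conc))
  list(f_conc = f_conc, f_int = f_int)
}
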