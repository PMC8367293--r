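# Canonical parameter sets and small axes shared across tests.

free_25 <- function() multiexp_params(c(266, 781), c(0.793, 0.207))
free_37 <- function() multiexp_params(c(252, 683), c(0.81, 0.19))
bound_ldh <- function() multiexp_params(c(804, 2503), c(0.851, 0.149))

# Full-resolution axis (one 25 ns period at 40 MHz).
full_settings <- function(budget = 1e6) {
  acquisition_settings(photon_budget = budget)
}

# Coarse axis for cheap tests: same 25 ns span, 1024 bins.
coarse_settings <- function(budget = 1e5) {
  acquisition_settings(n_bins = 1024L, bin_width = 25000 / 1024,
                       photon_budget = budget)
}

# Noise-free "histogram": expected reconvolved curve stored as counts.
noisefree_hist <- function(params, settings, irf) {
  p <- nadhlife:::scale_to_budget(params, settings, settings$photon_budget)
  shape <- multiexp_curve(p, settings) - p$background
  expected <- reconvolve(shape, irf) + p$background
  decay_histogram(pmax(expected, 0), settings, channel = "magic")
}
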