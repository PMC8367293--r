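test_that("reconvolution is exact against a direct convolution oracle", {
  s <- acquisition_settings(n_bins = 256L, bin_width = 100,
                            rep_period = 25600, photon_budget = 1e4)
  irf <- gaussian_irf(s, center = 2000, fwhm = 400)
  curve <- multiexp_curve(multiexp_params(c(1000, 5000), c(0.6, 0.4),
                                          amplitude = 50), s)

  # identity kernel
  expect_equal(reconvolve(curve, delta_irf(s, bin = 0L)), curve,
               tolerance = 1e-10)

  # conservation under a unit-sum kernel
  out <- reconvolve(curve, irf)
  expect_equal(sum(out), sum(curve), tolerance = 1e-9)

  # brute-force circular convolution oracle
  n <- s$n_bins
  brute <- vapply(seq_len(n), function(i) {
    sum(curve * irf$values[((i - seq_len(n)) %% n) + 1L])
  }, numeric(1))
  expect_equal(out, brute, tolerance = 1e-10)

  # a 266 ps decay convolved with a 200 ps FWHM IRF peaks after the IRF center
  s2 <- full_settings()
  irf2 <- gaussian_irf(s2, center = 1000, fwhm = 200)
  dec <- multiexp_curve(multiexp_params(266, 1), s2)
  conv <- reconvolve(dec, irf2)
  expect_gt(time_axis(s2)[which.max(conv)], 1000)

  expect_error(reconvolve(curve[-1], irf), "axis mismatch")
})

test_that("noise-free reconvolved decays are recovered to 1e-4 relative", {
  s <- full_settings()
  cases <- list(
    list(p = free_25(), fwhm = 200),
    list(p = free_37(), fwhm = 200),
    list(p = bound_ldh(), fwhm = 35)
  )
  for (cs in cases) {
    irf <- gaussian_irf(s, fwhm = cs$fwhm)
    h <- noisefree_hist(cs$p, s, irf)
    fit <- fit_decay(h, irf, fit_spec(2))
    expect_true(fit$converged)
    expect_equal(fit$params$lifetimes, cs$p$lifetimes, tolerance = 1e-4)
    expect_equal(fit$params$fractions, cs$p$fractions, tolerance = 1e-4)
    expect_lt(abs(fit$t0), 0.5)
    expect_lt(abs(mean_lifetime(fit$params) / mean_lifetime(cs$p) - 1), 1e-4)
  }
})

test_that("a single-exponential decay fitted with two components keeps its mean", {
  s <- full_settings()
  irf <- gaussian_irf(s, fwhm = 200)
  true_tau <- 500
  h <- simulate_decay(multiexp_params(true_tau, 1), s, irf, seed = 5)
  fit <- fit_decay(h, irf, fit_spec(2))
  taus <- fit$params$lifetimes
  expect_true(taus[1] <= true_tau * 1.02 && taus[2] >= true_tau * 0.98)
  expect_lt(abs(mean_lifetime(fit$params) / true_tau - 1), 0.01)
})

test_that("fitted lifetimes are ordered and fractions sum to one", {
  s <- coarse_settings(budget = 2e5)
  irf <- gaussian_irf(s, fwhm = 200)
  for (seed in 1:4) {
    h <- simulate_decay(free_25(), s, irf, seed)
    fit <- fit_decay(h, irf, fit_spec(2))
    expect_true(all(diff(fit$params$lifetimes) > 0))
    expect_equal(sum(fit$params$fractions), 1, tolerance = 1e-12)
  }
})

test_that("model scaling is linear through reconvolution", {
  s <- coarse_settings()
  irf <- gaussian_irf(s, fwhm = 200)
  p <- free_25()
  p$amplitude <- 3
  expect_equal(reconvolve(multiexp_curve(p, s), irf),
               3 * reconvolve(multiexp_curve(
                 multiexp_params(p$lifetimes, p$fractions), s), irf),
               tolerance = 1e-12)
})

test_that("total signal is the bin sum and permutation invariant", {
  s <- acquisition_settings(n_bins = 3L, photon_budget = 6)
  h <- decay_histogram(c(1, 2, 3), s)
  expect_equal(total_signal(h), 6)
  expect_equal(total_signal(decay_histogram(c(3, 1, 2), s)), 6)
  expect_equal(total_signal(decay_histogram(numeric(3), s)), 0)
})

test_that("control subtraction corrects a scatter background without bias", {
  s <- full_settings(budget = 1e6)
  irf <- gaussian_irf(s, fwhm = 200)
  p <- free_25()

  z <- acquisition_settings(n_bins = 4L, photon_budget = 1)
  ctl0 <- decay_histogram(numeric(4), z)
  smp <- decay_histogram(c(4, 0, 2, 1), z)
  expect_equal(subtract_control(smp, ctl0)$counts, smp$counts)
  dbl <- decay_histogram(2 * smp$counts, z)
  expect_equal(subtract_control(dbl, smp, scale = 1)$counts, smp$counts)

  # end-to-end: decay + IRF-shaped scatter, subtract the simulated control
  scatter <- 3e4 * gaussian_irf(s, center = 1000, fwhm = 200)$values
  pb <- nadhlife:::scale_to_budget(p, s, s$photon_budget)
  clean_exp <- reconvolve(multiexp_curve(pb, s), irf)
  h_clean <- sample_histogram(clean_exp, s, seed = 21)
  h_mixed <- sample_histogram(clean_exp + scatter, s, seed = 21)
  h_ctl <- sample_histogram(scatter, s, seed = 22)
  corrected <- subtract_control(h_mixed, h_ctl, scale = 1)
  f_clean <- fit_decay(h_clean, irf, fit_spec(2))
  f_corr <- fit_decay(corrected, irf, fit_spec(2))
  expect_lt(abs(mean_lifetime(f_corr$params) /
                  mean_lifetime(f_clean$params) - 1), 0.01)
})

test_that("constrained free/bound decomposition recovers the mixing fraction", {
  s <- full_settings(budget = 1e6)
  irf <- gaussian_irf(s, fwhm = 35)
  free_shape <- free_37()
  bound_shape <- bound_ldh()

  unit <- function(sh) {
    y <- multiexp_curve(multiexp_params(sh$lifetimes, sh$fractions), s)
    y / sum(y)
  }
  mix_expected <- function(f, total) {
    pmax(reconvolve(total * ((1 - f) * unit(free_shape) +
                               f * unit(bound_shape)), irf), 0)
  }

  # noise-free mixture at f = 0.5
  h <- decay_histogram(mix_expected(0.5, 1e6), s)
  est <- fit_bound_fraction(h, irf, free_shape, bound_shape)
  expect_equal(est$f_int, 0.5, tolerance = 1e-4)

  # pure free decay at 1e6 photons: fitted fraction stays near zero
  h0 <- sample_histogram(mix_expected(0, 1e6), s, seed = 31)
  est0 <- fit_bound_fraction(h0, irf, free_shape, bound_shape)
  expect_lte(est0$f_int, 0.02)

  near_free <- multiexp_params(free_shape$lifetimes * (1 + 1e-8),
                               free_shape$fractions)
  expect_warning(
    fit_bound_fraction(h, irf, free_shape, near_free),
    "ill-conditioned"
  )
})

test_that("fit guards reject unusable inputs", {
  s <- coarse_settings()
  irf <- gaussian_irf(s, fwhm = 200)
  h0 <- decay_histogram(numeric(s$n_bins), s)
  expect_error(fit_decay(h0, irf, fit_spec(2)), "zero counts")
  h <- simulate_decay(free_25(), s, irf, seed = 1)
  expect_error(fit_decay(h, irf, fit_spec(2, window = c(900, 1100))),
               "at least 10")
})
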