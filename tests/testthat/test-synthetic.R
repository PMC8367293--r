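test_that("gaussian IRF is normalised, symmetric, and sharper at smaller FWHM", {
  s <- full_settings()
  center <- time_axis(s)[165] # exactly on a bin centre
  irf <- gaussian_irf(s, center = center, fwhm = 200)
  expect_equal(sum(irf$values), 1, tolerance = 1e-12)
  expect_true(all(irf$values >= 0))

  # peak at the bin nearest the center, weights symmetric about it
  peak <- which.max(irf$values)
  expect_equal(peak, 165L)
  k <- 30
  expect_equal(irf$values[peak + seq_len(k)], irf$values[peak - seq_len(k)],
               tolerance = 1e-9)

  irf35 <- gaussian_irf(s, center = center, fwhm = 35)
  expect_gt(max(irf35$values), max(irf$values))

  expect_error(gaussian_irf(s, fwhm = s$bin_width / 20), "degenerate")
  expect_error(gaussian_irf(s, center = -5, fwhm = 200), "center")
})

test_that("multi-exponential curve applies the closed-form periodic wrap", {
  s <- full_settings()
  # scalar oracle: wrap multiplier at tau = 2503 ps, T = 25000 ps
  expect_equal(1 / (1 - exp(-25000 / 2503)), 1.000046, tolerance = 1e-6)

  p1 <- multiexp_params(500, 1)
  y <- multiexp_curve(p1, s)
  tt <- time_axis(s)
  expect_equal(y / y[1], exp(-tt / 500) / exp(-tt[1] / 500),
               tolerance = 1e-12)

  # linearity: doubling I0 doubles every bin when C = 0
  p2 <- multiexp_params(c(266, 781), c(0.793, 0.207), amplitude = 2)
  expect_equal(multiexp_curve(p2, s),
               2 * multiexp_curve(multiexp_params(c(266, 781),
                                                  c(0.793, 0.207)), s),
               tolerance = 1e-14)

  expect_warning(
    multiexp_curve(multiexp_params(3e5, 1), s), "wrap factor"
  )
})

test_that("closed-form wrap matches brute-force summation over 50 periods", {
  s <- coarse_settings()
  tt <- time_axis(s)
  for (tau in c(100, 266, 781, 2503, 5000)) {
    closed <- nadhlife:::wrapped_exp(tt, tau, s$rep_period)
    brute <- Reduce(`+`, lapply(0:49, function(k) {
      exp(-(tt + k * s$rep_period) / tau)
    }))
    expect_equal(closed, brute, tolerance = 1e-10)
  }
})

test_that("Poisson sampling is seeded, exact on zeros, and unbiased", {
  s <- coarse_settings()
  zero <- sample_histogram(numeric(s$n_bins), s, seed = 1)
  expect_true(all(zero$counts == 0))

  expected <- rep(100, s$n_bins)
  h1 <- sample_histogram(expected, s, seed = 42)
  h2 <- sample_histogram(expected, s, seed = 42)
  expect_identical(h1$counts, h2$counts)

  # 1000 seeded draws of a bin with expectation 100: mean within 3 sigma
  draws <- vapply(1:1000, function(sd) {
    sample_histogram(100, acquisition_settings(n_bins = 1L,
                                               photon_budget = 100),
                     seed = sd)$counts
  }, numeric(1))
  expect_lt(abs(mean(draws) - 100), 3 * 10 / sqrt(1000))

  bad <- expected
  bad[7] <- -1
  expect_error(sample_histogram(bad, s, seed = 1), "bin 6")
})

test_that("sampled totals track the photon budget", {
  s <- coarse_settings(budget = 1e5)
  irf <- gaussian_irf(s, fwhm = 200)
  p <- free_25()
  totals <- vapply(1:20, function(sd) {
    total_signal(simulate_decay(p, s, irf, seed = sd))
  }, numeric(1))
  expect_true(all(abs(totals - 1e5) <= 4 * sqrt(1e5)))
})

test_that("polarised channels obey photoselection identities", {
  s <- coarse_settings()
  irf <- gaussian_irf(s, fwhm = 35)
  p <- bound_ldh()
  p$amplitude <- 1e4

  # isotropic limit: all channels proportional
  iso <- expected_polarized(p, aniso_params(r0 = 0, theta = 1000), s, irf)
  expect_equal(iso$parallel / iso$magic, rep(1, s$n_bins), tolerance = 1e-9)
  expect_equal(iso$perpendicular / iso$magic, rep(1, s$n_bins),
               tolerance = 1e-9)

  # frozen rotor, pre-IRF: I_par / I_perp = (1 + 2 r0)/(1 - r0) = 3 at r0 = 0.4
  frozen <- expected_polarized(p, aniso_params(r0 = 0.4, theta = 1e12),
                               s, irf = NULL)
  expect_equal(frozen$parallel / frozen$perpendicular, rep(3, s$n_bins),
               tolerance = 1e-6)

  # conservation: par + 2 perp = 3 magic at G = 1 (with IRF and wrap)
  ch <- expected_polarized(p, aniso_params(r0 = 0.35, theta = 15900), s, irf)
  lhs <- ch$parallel + 2 * ch$perpendicular
  expect_equal(lhs, 3 * ch$magic, tolerance = 1e-9)
  expect_lt(abs(sum(lhs - 3 * ch$magic)) / sum(lhs), 1e-6)
})

test_that("bound fractions follow the quadratic binding equation", {
  # stoichiometric limit Kd -> 0: f_conc = min(S, N)/N
  lim <- bound_fractions(binding_condition(10, 1, kd = 1e-10,
                                           sites_per_protein = 4))
  expect_equal(lim$f_conc, 0.4, tolerance = 1e-6)

  # S = N = Kd: quadratic-formula oracle (3 - sqrt(5))/2
  eq <- bound_fractions(binding_condition(5, 1.25, kd = 5,
                                          sites_per_protein = 4))
  expect_equal(eq$f_conc, (3 - sqrt(5)) / 2, tolerance = 1e-12)

  # brightness 1: intensity fraction equals concentration fraction
  b1 <- bound_fractions(binding_condition(5, 2, kd = 3,
                                          brightness_ratio = 1))
  expect_equal(b1$f_int, b1$f_conc, tolerance = 1e-12)

  expect_error(bound_fractions(binding_condition(0, 1, kd = 1)),
               "nadh_total")

  # monotone non-decreasing in ldh_total, non-increasing in kd
  f_ldh <- vapply(seq(0, 60, by = 2.5), function(L) {
    bound_fractions(binding_condition(12.5, L, kd = 10))$f_conc
  }, numeric(1))
  expect_true(all(diff(f_ldh) >= -1e-12))
  f_kd <- vapply(c(0.1, 1, 5, 10, 50, 200), function(K) {
    bound_fractions(binding_condition(12.5, 6, kd = K))$f_conc
  }, numeric(1))
  expect_true(all(diff(f_kd) <= 1e-12))
})

test_that("temperature series carry exact linear ground truth", {
  s <- coarse_settings(budget = 2e4)
  irf <- gaussian_irf(s, fwhm = 200)

  # zero slopes: parameters equal the reference set
  env0 <- environment_model(free_25(), taum_slope = 0, intensity_slope = 0,
                            anisotropy_slope = 0)
  ser0 <- simulate_condition_series(env0, 25, s, irf, seed = 1)
  expect_equal(ser0[[1]]$truth$params$lifetimes, free_25()$lifetimes)
  expect_equal(ser0[[1]]$truth$taum, mean_lifetime(free_25()))

  # default -8 ps/degC: ground-truth taum drops 80 ps per 10 degC
  env <- environment_model(free_25())
  ser <- simulate_condition_series(env, c(25, 35, 45), s, irf, seed = 1)
  taums <- vapply(ser, function(el) el$truth$taum, numeric(1))
  expect_equal(diff(taums), c(-80, -80), tolerance = 1e-9)
  rel <- vapply(ser, function(el) el$truth$rel_intensity, numeric(1))
  expect_equal(rel, 1 - 0.022 * c(0, 10, 20), tolerance = 1e-12)

  expect_warning(simulate_condition_series(env, 50, s, irf, seed = 1),
                 "outside the modelled range")
  expect_error(simulate_condition_series(env, c(35, 25), s, irf, seed = 1),
               "sorted")
  expect_error(environment_model(free_25(), condition_name = "pH"),
               "per_condition_table")
})

test_that("titration ratio zero reduces to the pure free decay", {
  s <- coarse_settings(budget = 2e4)
  irf <- gaussian_irf(s, fwhm = 35)
  tit <- titration_spec(free_37(), bound_ldh(), nadh_total = 12.5, kd = 10)
  ser <- simulate_condition_series(tit, c(0, 1), s, irf, seed = 3)
  expect_equal(ser[[1]]$truth$f_int, 0)
  truth0 <- ser[[1]]$truth$params
  expect_equal(truth0$lifetimes, free_37()$lifetimes)
  expect_gt(ser[[2]]$truth$f_int, 0.5)
  # seeded reproducibility of the whole series
  ser2 <- simulate_condition_series(tit, c(0, 1), s, irf, seed = 3)
  expect_identical(ser[[2]]$measurement$counts, ser2[[2]]$measurement$counts)
})
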