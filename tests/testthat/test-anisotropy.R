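test_that("G-factor and steady-state anisotropy follow their definitions", {
  expect_equal(g_factor(100, 100), 1)
  expect_equal(g_factor(1.1, 1.0), 1.1)
  expect_error(g_factor(1, 0), "perp_hexc")

  expect_equal(steady_state_anisotropy(2, 1, 1), 0.25)
  expect_equal(steady_state_anisotropy(3, 3 / 1.2, 1.2), 0)
  expect_equal(steady_state_anisotropy(5, 0, 1), 1)
  expect_error(steady_state_anisotropy(0, 0, 1), "undefined")
})

test_that("a simulated unbiased instrument measures G = 1", {
  # horizontally polarised excitation: both analyser settings see the same
  # population, emulated by an isotropic (r0 = 0) emitter
  s <- full_settings(budget = 1e6)
  irf <- gaussian_irf(s, fwhm = 35)
  m <- simulate_polarized(bound_ldh(), aniso_params(r0 = 0, theta = 1000),
                          s, irf, seed = 8)
  G <- g_factor(total_signal(m$parallel), total_signal(m$perpendicular))
  expect_equal(G, 1, tolerance = 0.005)
})

test_that("1/e correlation time equals theta for the single-exponential model", {
  expect_equal(correlation_time_1e(aniso_params(0.3, 409)), 409)
  expect_equal(correlation_time_1e(aniso_params(0.35, 15900)), 15900)
  a <- aniso_params(0.3, 1234)
  r_at <- function(t) a$r0 * exp(-t / a$theta)
  expect_equal(r_at(correlation_time_1e(a)) / r_at(0), exp(-1),
               tolerance = 1e-12)
})

test_that("closed-form steady-state anisotropy has the right limits and value", {
  decay <- bound_ldh()
  # frozen rotor
  expect_equal(steady_state_from_model(decay, aniso_params(0.35, 1e12)),
               0.35, tolerance = 1e-6)
  # fast rotor
  expect_lt(steady_state_from_model(decay, aniso_params(0.35, 1e-3)), 1e-5)

  # independent arithmetic for the fully bound parameter set
  a <- c(0.851, 0.149); tau <- c(804, 2503); th <- 15900
  oracle <- 0.35 * sum(a * tau * th / (tau + th)) / sum(a * tau)
  expect_equal(steady_state_from_model(decay, aniso_params(0.35, th)),
               oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.322, tolerance = 1e-3)
})

test_that("global anisotropy fit recovers noise-free channels", {
  s <- full_settings(budget = 1e6)
  irf <- gaussian_irf(s, fwhm = 35)
  p <- nadhlife:::scale_to_budget(bound_ldh(), s, 3e6)
  an <- aniso_params(r0 = 0.35, theta = 15900)
  ch <- expected_polarized(p, an, s, irf)
  meas <- polarized_measurement(
    decay_histogram(pmax(ch$parallel, 0), s, "parallel"),
    decay_histogram(pmax(ch$perpendicular, 0), s, "perpendicular"),
    decay_histogram(pmax(ch$magic, 0), s, "magic"),
    g_factor = 1
  )
  mf <- fit_decay(meas$magic, irf, fit_spec(2))
  af <- fit_anisotropy_decay(meas, mf$params, irf, t0 = mf$t0)
  expect_true(af$converged)
  expect_equal(af$r0, 0.35, tolerance = 1e-3)
  expect_equal(af$theta, 15900, tolerance = 1e-3)
})

test_that("an isotropic emitter leaves theta unidentifiable and is flagged", {
  s <- full_settings(budget = 2e5)
  irf <- gaussian_irf(s, fwhm = 35)
  m <- simulate_polarized(bound_ldh(), aniso_params(r0 = 0, theta = 15900),
                          s, irf, seed = 17)
  mf <- fit_decay(m$magic, irf, fit_spec(2))
  af <- fit_anisotropy_decay(m, mf$params, irf, t0 = mf$t0)
  expect_lt(abs(af$r0), 0.02)
  expect_true(length(af$flags) > 0)
})

test_that("windowed channel sums agree with the closed-form steady state", {
  # theta >> IRF width so IRF and wrap distortions are negligible
  s <- full_settings(budget = 1e6)
  irf <- gaussian_irf(s, fwhm = 35)
  an <- aniso_params(r0 = 0.35, theta = 15900)
  m <- simulate_polarized(bound_ldh(), an, s, irf, seed = 23)
  r_meas <- measurement_anisotropy(m)
  r_model <- steady_state_from_model(bound_ldh(), an)
  expect_equal(r_meas, r_model, tolerance = 0.02)
})
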