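# nadhlife

Simulation and analysis of NADH time-resolved fluorescence (TCSPC) data.

NADH is the principal autofluorescent metabolic coenzyme, and its
fluorescence lifetime, intensity and anisotropy all shift with the
microenvironment — temperature, pH, and binding to enzymes such as lactate
dehydrogenase (LDH). Quantifying those shifts requires a chain of careful
numerics: instrument-response (IRF) reconvolution fitting of
multi-exponential decays with incomplete-decay correction at 40 MHz
repetition rates, polarisation-resolved (anisotropy) analysis, and
constrained decompositions of mixed free/bound decays. `nadhlife`
implements that chain for R users, together with a synthetic TCSPC
instrument so every estimator can be validated against known ground truth.

## The models at the core

* **Decay**: $I(t) = I_0 \sum_i \alpha_i e^{-t/\tau_i} + C$ with
  $\sum \alpha_i = 1$; each term carries the periodic wrap
  $e^{-t/\tau}/(1 - e^{-T/\tau})$ for repetition period $T$, and the model
  is circularly convolved with the IRF during fitting. The
  intensity-weighted mean lifetime is
  $\tau_m = \sum \alpha_i \tau_i^2 / \sum \alpha_i \tau_i$.
* **Anisotropy**: $r(t) = r_0 e^{-t/\theta}$ with
  $I_\parallel = \tfrac13 I(1 + 2r)$, $I_\perp = \tfrac13 I(1 - r)/G$;
  steady-state $r = (I_\parallel - G I_\perp)/(I_\parallel + 2 G I_\perp)$.
* **Binding**: bound NADH concentration from the mass-action quadratic
  $B = \tfrac12[(S+N+K_d) - \sqrt{(S+N+K_d)^2 - 4SN}]$ over $S$ identical
  sites, converted to an intensity fraction with the 3.3× brightness gain
  of LDH-bound NADH.

Fits are weighted Levenberg–Marquardt least squares (`minpack.lm`) with
model-based Poisson weights, deterministic multi-starts, box constraints
and log-scale lifetimes.

## Worked example

Simulate a free-NADH decay at the 25 °C reference parameters
(τ₁ = 266 ps, τ₂ = 781 ps, α₁ = 0.793) with 10⁶ photons and a 200 ps FWHM
IRF, then fit it blind:

```r
library(nadhlife)

s        <- acquisition_settings(photon_budget = 1e6)   # 4096 bins, 25 ns
irf      <- gaussian_irf(s, fwhm = 200)
free_nadh <- multiexp_params(c(266, 781), c(0.793, 0.207))

h   <- simulate_decay(free_nadh, s, irf, seed = 42)
fit <- fit_decay(h, irf, fit_spec(n_components = 2))
fit
#> reconvolution fit (converged, chi2_red = 0.554, 7 iterations)
#> 2-exponential decay: I0 = 1.636e+04, C = 0.002999
#>   tau1 =    267.5 ps  alpha1 = 0.7975
#>   tau2 =    786.6 ps  alpha2 = 0.2025
#>   intensity-weighted mean lifetime: 489.4 ps
#>   t0 = -0.08 ps; window 2048 bins
```

The fitted lifetimes land within a few ps of the generating values and
the mean lifetime within 1 ps of the exact composition value
(489.4 ps). The same round trip for the polarised channels of fully
LDH-bound NADH (θ = 15,900 ps, r₀ = 0.35):

```r
bound <- multiexp_params(c(804, 2503), c(0.851, 0.149))
an    <- aniso_params(r0 = 0.35, theta = 15900)
irf35 <- gaussian_irf(s, fwhm = 35)

m  <- simulate_polarized(bound, an, s, irf35, seed = 42)
mf <- fit_decay(m$magic, irf35, fit_spec(2))      # magic-angle decay fit
af <- fit_anisotropy_decay(m, mf$params, irf35, t0 = mf$t0)

measurement_anisotropy(m)   # steady-state r from windowed channel sums
#> 0.322
c(af$r0, af$theta)          # global time-resolved fit
#> 0.349  15900
```

The steady-state value 0.322 matches the closed form
`steady_state_from_model(bound, an)` — the consistency check between the
time-resolved parameters and the steady-state anisotropy.

Other entry points: `simulate_condition_series()` +
`analyze_condition_series()` for temperature/pH/titration series,
`fit_bound_fraction()` and `binding_curve()` for free/bound
decompositions, `trend_slope()` / `aggregate_replicates()` /
`spectral_peak()` for series statistics, `read_histogram()` /
`write_histogram()` / `make_fixtures()` for plain-text data exchange, and
a thin CLI in `inst/cli/nadhlife.R` (`simulate`, `fit`, `anisotropy`,
`bind`, `trends`, `fixtures`). The methods vignette
(`vignettes/nadh-tcspc-methods.Rmd`) documents the models, defaults and
numerical choices in detail.

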