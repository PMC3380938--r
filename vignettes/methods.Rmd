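---
title: "Model and methods: larval abundance from CPR-style count surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: larval abundance from CPR-style count surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(cprlgcp)
```

## The model

Counts of fish larvae from towed plankton samplers are sparse, heavily
overdispersed, and structured in space, season and year.  `cprlgcp` models a
count $N_i$ at position $s_i$, day-of-year $d_i$, thermocline depth $t_i$ and
year $y_i$ as a log-Gaussian Cox process observed through small samples:

$$N_i \mid \eta_i \sim \mathrm{Poisson}(e^{\eta_i}),$$

with log-intensity

$$\eta_i = \mu_0 + u(c_i, y_i) + w_{y_i}
  + (a_{s1} d_i - a_{s2} d_i^2)
  + (a_{t1} t_i - a_{t2} t_i^2)
  [+ \mu(h_i)] + \varepsilon_i.$$

The latent components are:

* **Space–time field** $u$: defined on grid cells $\times$ years, mean zero,
  with the separable exponential covariance
  $\mathrm{cov} = \sigma^2 \exp(-\alpha\,\Delta_{km})\exp(-\beta\,\Delta_{yr})$.
  With the field stored as a $C \times Y$ matrix, the covariance of its
  vectorization is the Kronecker product $\sigma^2\, T \otimes S$ — the key to
  fast linear algebra.
* **Year level** $w_y$: a random annual offset with variance $\sigma_y^2$ and
  the same temporal correlation $T$, capturing domain-wide abundance swings.
* **Nugget** $\varepsilon_i$: independent $N(0, \sigma_0^2)$ per sample,
  absorbing patchiness below the cell scale.  Marginally each count is
  Poisson-lognormal, which is what produces the long right tail seen in real
  plankton series.

The fixed effects are a concave quadratic in day-of-year (the spawning
curve, peaking in summer), a concave quadratic in thermocline depth
(a *catchability* effect: a fixed-depth sampler catches more larvae when they
are concentrated just above a shallow thermocline), and optionally 24
hour-of-day offsets under a sum-to-zero constraint.  Catchability describes
the gear, not the fish: maps and the annual index therefore hold the
thermocline term at its maximum (reference level) rather than integrating
over it.

## Likelihood and estimation

The marginal likelihood integrates $(u, w, \varepsilon)$ out of the joint
density.  `lgcp_fit()` does this with a Laplace approximation: an inner
Newton solver finds the joint latent mode, and the marginal negative
log-likelihood is the joint value at the mode plus half the log-determinant
of the inner Hessian.  For a Gaussian observation family the approximation
is exact — the test suite uses that as a closed-form oracle, alongside
adaptive Gauss–Hermite quadrature for the Poisson family.

Numerical choices worth knowing about:

* **Schur elimination of the nugget.**  The inner Hessian is (block
  diagonal latent precision) + (diagonal observation curvature).  The
  $n$-dimensional nugget block is diagonal and is eliminated analytically,
  leaving a dense symmetric system of size $CY + Y$ (about 1,300 at the
  default domain) whose Cholesky factor also supplies the log-determinant
  and the Laplace posterior covariance.
* **Analytic outer gradients**, including the implicit dependence of mode
  and Hessian on the parameters, make one outer iteration cost roughly two
  inner solves; the gradient is verified against numerical differentiation
  in the tests.
* **Internal covariate scaling.**  Day-of-year is centred at 183 and scaled
  by 100; thermocline depth centred at 30 m and scaled by 25.  Raw
  quadratic columns span 1 to $3.6\times10^4$ and make the outer Hessian
  numerically singular.  All reported estimates and standard errors are
  mapped back to raw per-day / per-metre scales (exact linear maps; delta
  method for the standard errors).
* **Variances on the log scale**, bounded at $e^{-12}$ — effectively zero
  — so boundary estimates are representable; decay parameters as
  $\log\alpha$, $\log\beta$.
* **Jitter** of $10^{-8}$ on the correlation matrices before factorization.
* **Overflow handling**: a trial parameter that drives $e^\eta$ past
  floating-point range returns $+\infty$ with a zero gradient, so the outer
  optimizer shortens the step instead of crashing.

```{r fit-demo}
g <- grid_spec(nlat = 3, nlon = 3, dlat = 10/3, dlon = 13/3)
cfg <- sim_config(grid = g, years = 1998:2005, samples_per_year = 50, seed = 101)
sim <- simulate_cpr(cfg)
fit <- lgcp_fit(sim$samples, g, 1998:2005)
summary(fit)
```

## Worked example: correlation ranges

The decay parameters translate directly into correlation at a given
separation, a more interpretable quantity:

```{r correlations}
p <- lgcp_params(log_alpha = -5.45, log_beta = -1.22)
correlation_at(p, dx_km = 100, dt_years = 0)   # ~0.65 at 100 km
correlation_at(p, dx_km = 0, dt_years = 1)     # ~0.74 between adjacent years
```

## Inference products

* `posterior_latent()` / `predict()` / `intensity_map()`: the Laplace
  posterior of field and year levels; per-cell posterior mean intensity
  uses the lognormal formula $e^{m + v/2}$.
* `annual_index()`: cell areas (spherical, so northern cells are smaller)
  times posterior mean intensity, summed over the domain and the seasonal
  curve.  Interval bounds come from seeded draws of the Laplace-Gaussian
  posterior, because the exponential transform makes the index skewed.
* `period_shift_test()`: adds a period offset to the mean year level —
  0 before the early cut, the estimated shift after the late cut, a linear
  ramp between (intermediate years are otherwise carried by the random
  year level) — and compares by a likelihood-ratio test on 1 degree of
  freedom.  The shift parameter is unbounded, so the usual $\chi^2_1$
  reference applies; tests that instead drop a *variance* to its boundary
  (for instance `include = list(yeareff = FALSE)`) are conservative under
  that reference, which `lr_test()` documents.

## The synthetic generator

`simulate_cpr()` reproduces the survey's structure rather than any real
measurement: ship-track transects with 10-nautical-mile sample spacing (or
a uniform design), sampling dates spread over the whole year (routes are
re-run monthly, so date is independent of position), a smooth seasonal
thermocline field (shallow in summer, deeper in winter, with optional
masked fully-mixed nodes), and counts drawn from the exact model above.

Two generator knobs are not part of the estimated parameter set and were
calibrated for realism: the intercept (set so that a few percent of samples
are positive — sparse but informative, as in real plankton series) and the
year-level variance (0.25, so that multi-year abundance swings are visible
against sampling noise).  The default domain is 51–61°N, 3.5°W–9.5°E in
8 × 8 cells: at the default spatial decay, correlation falls to ~0.2 across
this domain, which is what separates the field from the year effect.  On a
much smaller domain the two are confounded — an identifiability property of
the design, not of the estimator.

## Drift back-tracking

`backtrack()` releases passive particles at capture positions and
integrates them backward through a gridded velocity field with a
vectorized fixed-step 4th-order Runge–Kutta scheme (default step 1 h) and
bilinear interpolation; optional seeded random-walk mixing emulates
unresolved turbulence.  The default duration comes from growth arithmetic:
egg phase (6.7 days) plus growth from 3 mm at hatch to 4.8 mm at capture at
0.75 mm/day gives 9.1 days, rounded up to 10.  `displacement_summary()`
pools per-observation median great-circle displacements and reports
quantiles by linear interpolation of the empirical distribution function
(`type = 4`), so that, e.g., pooled medians of 10, 20, …, 100 km give a
0.90 quantile of exactly 90 km.

```{r drift}
f <- make_velocity_field("uniform", seq(51, 61, 0.5), seq(-3.5, 9.5, 0.5),
                         params = list(u = 0.1, v = 0))
tr <- backtrack(data.frame(lat = 56, lon = 5), f, duration_days = 10,
                n_particles = 1)
displacement_summary(tr)   # 0.1 m/s for 10 days = 86.4 km
```

## Limits

The generator and analytic velocity fields are structural stand-ins: they
support method validation at desk scale, not oceanographic conclusions.
Results from multi-decade real surveys depend on the actual sampling
history and external hydrography and are out of scope here.
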