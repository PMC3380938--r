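# cprlgcp

Log-Gaussian Cox process analysis of Continuous Plankton Recorder (CPR)
style larval count surveys: model fitting by Laplace maximum likelihood,
abundance indices and shift tests, a matching synthetic-survey generator,
and Lagrangian drift back-tracking.

## The science

Plankton recorders towed behind ships of opportunity catch fish larvae in
tiny filtered volumes: most samples contain nothing, a few contain many.
Turning such counts into an interannual *abundance index* requires a model
that separates

* genuine spatial structure (larvae are patchy on scales of tens to
  hundreds of kilometres),
* the seasonal spawning curve (a concave quadratic in day-of-year),
* *catchability* — the gear samples at fixed depth, so how many of the
  larvae present it catches depends on where they sit in the water column,
  summarized by thermocline depth (and, optionally, hour of day),
* domain-wide year-to-year swings, and
* residual small-scale patchiness (a per-sample nugget).

`cprlgcp` implements this as a log-Gaussian Cox process: Poisson counts
whose log-intensity is a latent Gaussian space-time field with separable
exponential covariance `sigma^2 * exp(-alpha*dist_km) * exp(-beta*dyears)`,
plus random year levels, fixed quadratic effects, and a nugget.  All latent
components are integrated out with a Laplace approximation (exact in the
Gaussian-observation case, verified against quadrature oracles in the
Poisson case), with analytic outer gradients and Kronecker/Schur linear
algebra so a 64-cell x 20-year x 3,000-sample fit takes well under a minute
on one CPU.

From a fitted model you get posterior intensity maps, a yearly spatially
and seasonally integrated abundance index with Monte-Carlo intervals, and a
likelihood-ratio test for a step change in abundance between two periods.
A separate module back-tracks passive particles through gridded velocity
fields to ask where sampled larvae were spawned; with the default growth
arithmetic (egg phase 6.7 d; 3 mm at hatch to 4.8 mm at capture at
0.75 mm/day) the tracking window is 10 days.

## Worked example

Simulate a survey at the default truth (8 x 8 cells over 51-61N /
3.5W-9.5E, 20 years, 150 samples per year — sparse, zero-dominated counts
like the real thing) and fit it:

```r
library(cprlgcp)
g   <- grid_spec()
cfg <- sim_config(grid = g, years = 1986:2005, samples_per_year = 150, seed = 1)
sim <- simulate_cpr(cfg)
fit <- lgcp_fit(sim$samples, g, 1986:2005)
summary(fit)
```

```
Larval log-Gaussian Cox process -- parameter estimates

             estimate        se
sigma0_sq   2.137e+00 2.157e-01
sigma_sq    6.549e+00 1.283e+00
sigma_y_sq  1.539e-01 5.973e-01
log_alpha  -5.255e+00 2.649e-01
log_beta   -1.170e+00 2.092e-01
a_spawn1    1.844e-01 3.561e-02
a_spawn2    4.769e-04 8.981e-05
a_thc1      4.948e-02 7.120e-02
a_thc2      2.803e-03 1.393e-03
intercept  -1.894e+01 7.396e-01

negative marginal log-likelihood: 1995.0175
spatial correlation at 100 km: 0.59
temporal correlation, adjacent years: 0.73
seasonal peak: day 193.3
catchability peak: 8.8 m thermocline
```

The decay estimates are best read as correlations at interpretable
separations:

```r
p <- lgcp_params(log_alpha = -5.45, log_beta = -1.22)
correlation_at(p, dx_km = 100, dt_years = 0)  # 0.6507495
correlation_at(p, dx_km = 0,   dt_years = 1)  # 0.7443602
```

Inference products:

```r
annual_index(fit, ndraws = 500, seed = 1)   # year, index, lo, hi
predict(fit, year = 1995)                   # posterior intensity map
period_shift_test(sim$samples, g, cut_before = 1995, cut_after = 1996)
```

Drift back-tracking with an analytic current:

```r
f  <- make_velocity_field("uniform", seq(51, 61, 0.5), seq(-3.5, 9.5, 0.5),
                          params = list(u = 0.1, v = 0))
tr <- backtrack(data.frame(lat = 56, lon = 5), f, duration_days = 10)
displacement_summary(tr)                    # median displacement 86.4 km
```

An end-to-end pipeline (simulate or read data, fit, index, shift test,
back-track, manifest with per-stage seeds and status) is driven by a YAML
configuration:

```sh
Rscript inst/scripts/run-pipeline.R --config config.yaml --out out/ --seed 1
```

See `vignettes/methods.Rmd` for the model, the numerical choices, and the
generator's calibration rationale.

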