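test_that("the generator is exactly reproducible from its seed", {
  t1 <- toy_survey(seed = 5)
  t2 <- toy_survey(seed = 5)
  t3 <- toy_survey(seed = 6)
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$latent$u, t2$latent$u)
  expect_false(identical(t1$samples$count, t3$samples$count))
})

test_that("latent field draws have the configured marginal variance", {
  ## many replicate draws of a small field; empirical marginal variance of
  ## each cell-year entry should match sigma^2 within Monte-Carlo error
  g <- grid_spec(nlat = 2, nlon = 2, dlat = 5, dlon = 6.5)
  p <- lgcp_params(sigma_sq = 3, sigma_y_sq = 0.5, sigma0_sq = 1)
  nrep <- 2000
  us <- vapply(seq_len(nrep), function(r) {
    lat <- cprlgcp:::simulate_latent_state(p, g, 2000:2001, 1, seed = r)
    as.vector(lat$u)
  }, numeric(8))
  v <- mean(apply(us, 1, var))
  ## se of a variance estimate: sigma^2 * sqrt(2/(n-1)) (averaging 8 slots
  ## that share draws is not independent, so keep the single-slot se)
  se <- 3 * sqrt(2 / (nrep - 1))
  expect_lt(abs(v - 3), 3 * se)
})

test_that("latent draws decorrelate in the large-decay limit", {
  g <- grid_spec(nlat = 2, nlon = 2, dlat = 5, dlon = 6.5)
  ## decay so fast that distinct cells are independent
  p <- lgcp_params(sigma_sq = 1, log_alpha = 2, log_beta = 3)
  us <- vapply(1:800, function(r) {
    cprlgcp:::simulate_latent_state(p, g, 2000, 1, seed = r)$u[1:2]
  }, numeric(2))
  expect_lt(abs(cor(us[1, ], us[2, ])), 0.1)
})

test_that("counts are Poisson-lognormal: doubling exp(intercept) doubles the mean", {
  p1 <- lgcp_params()
  p2 <- lgcp_params(intercept = p1$intercept + log(2))
  g <- grid_spec(nlat = 3, nlon = 3, dlat = 10 / 3, dlon = 13 / 3)
  n_mean <- function(p) {
    cfg <- sim_config(grid = g, years = 2000:2003, samples_per_year = 400,
                      params = p, seed = 77)
    mean(simulate_cpr(cfg)$samples$count)
  }
  m1 <- n_mean(p1); m2 <- n_mean(p2)
  ## same seed, same latents: ratio is exactly governed by thinning noise
  expect_gt(m2 / m1, 1.6)
  expect_lt(m2 / m1, 2.4)
})

test_that("transect and uniform designs both fill the domain and the year", {
  g <- grid_spec(nlat = 4, nlon = 4, dlat = 2.5, dlon = 3.25)
  for (des in c("transect", "uniform")) {
    cfg <- sim_config(grid = g, years = 2000:2001, samples_per_year = 200,
                      seed = 3, design = des)
    s <- simulate_cpr(cfg)$samples
    expect_equal(nrow(s), 400L)
    expect_true(all(s$lat >= 51 & s$lat <= 61))
    expect_true(all(s$lon >= -3.5 & s$lon <= 9.5))
    expect_gt(length(unique(s$cell_id)), 8)
    expect_gt(length(unique(s$day_of_year)), 100)
    expect_false(anyNA(s$thermocline_depth_m))
  }
})

test_that("an abundance shift multiplies late-period counts", {
  g <- grid_spec(nlat = 3, nlon = 3, dlat = 10 / 3, dlon = 13 / 3)
  cfg0 <- sim_config(grid = g, years = 1998:2005, samples_per_year = 300, seed = 4)
  cfgs <- sim_config(grid = g, years = 1998:2005, samples_per_year = 300, seed = 4,
                     shift = list(year = 2002, size = -log(4)))
  s0 <- simulate_cpr(cfg0)$samples
  ss <- simulate_cpr(cfgs)$samples
  early0 <- sum(s0$count[s0$year < 2002]); late0 <- sum(s0$count[s0$year >= 2002])
  expect_equal(sum(ss$count[ss$year < 2002]), early0)  # early years untouched
  expect_lt(sum(ss$count[ss$year >= 2002]), late0)
})
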