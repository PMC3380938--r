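test_that("with no data the latent posterior recovers the prior", {
  g <- grid_spec(nlat = 2, nlon = 2, dlat = 5, dlon = 6.5)
  p <- lgcp_params(sigma_sq = 2, sigma_y_sq = 0.4, sigma0_sq = 1,
                   intercept = -1)
  empty <- data.frame(lat = numeric(0), lon = numeric(0), year = integer(0),
                      day_of_year = integer(0), hour = integer(0),
                      count = integer(0))
  post <- posterior_latent(lgcp_posterior(p, empty, g, 2000:2002))
  expect_equal(post$u_mean, matrix(0, 4, 3))
  expect_equal(post$w_mean, rep(0, 3))
  expect_equal(as.vector(post$u_var), rep(2, 12), tolerance = 1e-6)
  expect_equal(post$w_var, rep(0.4, 3), tolerance = 1e-6)
})

test_that("data never inflate the latent posterior variance", {
  toy <- toy_survey(seed = 41, nlat = 2, nlon = 2, years = 2000:2002,
                    samples_per_year = 30)
  p <- toy$config$params
  empty <- toy$samples[0, ]
  v_prior <- posterior_latent(lgcp_posterior(p, empty, toy$grid, 2000:2002))
  v_data <- posterior_latent(lgcp_posterior(p, toy$samples, toy$grid, 2000:2002))
  expect_true(all(v_data$u_var <= v_prior$u_var + 1e-8))
  expect_true(all(v_data$w_var <= v_prior$w_var + 1e-8))
})

test_that("the annual index scales exactly with the baseline intensity", {
  fit <- shared_fit()$fit
  idx1 <- annual_index(fit, ndraws = 200, seed = 3)
  fit3 <- fit
  fit3$params$intercept <- fit$params$intercept + log(3)
  idx3 <- annual_index(fit3, ndraws = 200, seed = 3)
  expect_equal(idx3$index, 3 * idx1$index, tolerance = 1e-10)
  expect_equal(idx3$lo, 3 * idx1$lo, tolerance = 1e-10)
  expect_equal(idx3$hi, 3 * idx1$hi, tolerance = 1e-10)
  expect_true(all(idx1$index > 0))
  expect_true(all(idx1$lo < idx1$hi))
  ## without draws the interval collapses onto the point index
  idx0 <- annual_index(fit, ndraws = 0)
  expect_equal(idx0$lo, idx0$index)
})

test_that("intensity maps are invariant to the ordering of the samples", {
  toy <- toy_survey(seed = 42, nlat = 2, nlon = 2, years = 2000:2001,
                    samples_per_year = 40)
  p <- toy$config$params
  f1 <- lgcp_posterior(p, toy$samples, toy$grid, 2000:2001)
  set.seed(2); ord <- sample(nrow(toy$samples))
  f2 <- lgcp_posterior(p, toy$samples[ord, ], toy$grid, 2000:2001)
  m1 <- intensity_map(f1, 2001)
  m2 <- intensity_map(f2, 2001)
  expect_equal(m1$mean, m2$mean, tolerance = 1e-6)
  expect_error(intensity_map(f1, 1990), "1990")
  ## a fixed day rescales the whole map by the seasonal factor
  md <- intensity_map(f1, 2001, day = 150)
  expect_equal(md$mean / m1$mean,
               rep(exp(seasonal_effect(p, 150)) /
                     sum(exp(seasonal_effect(p, 1:365))), 4),
               tolerance = 1e-10)
})

test_that("the period-shift test detects a strong simulated decline", {
  g <- grid_spec(nlat = 4, nlon = 4, dlat = 2.5, dlon = 3.25)
  p <- lgcp_params(sigma_sq = 0.5, log_alpha = -4.5, sigma_y_sq = 0.04,
                   sigma0_sq = 1, intercept = -20.3)
  cfg <- sim_config(grid = g, years = 1996:2005, samples_per_year = 60,
                    params = p, seed = 7,
                    shift = list(year = 2001, size = -log(6)))
  s <- simulate_cpr(cfg)$samples
  tst <- period_shift_test(s, g, cut_before = 2000, cut_after = 2001,
                           control = lgcp_control(se = FALSE, outer_tol = 1e-4),
                           index_draws = 50)
  expect_equal(tst$df, 1)
  expect_gte(tst$p_value, 0); expect_lte(tst$p_value, 1)
  expect_lt(tst$shift, 0)
  expect_gt(tst$period_means[["early"]], tst$period_means[["late"]])
  expect_lt(tst$p_value, 0.05)
})
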