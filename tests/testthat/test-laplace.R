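test_that("the Laplace marginal is exact for Gaussian observations", {
  toy <- toy_survey(seed = 21, nlat = 2, nlon = 2, years = 2000:2002,
                    samples_per_year = 20)
  p <- lgcp_params(sigma_sq = 2, sigma_y_sq = 0.3, sigma0_sq = 0.5,
                   intercept = -1, log_alpha = -5.45, log_beta = -1.22)
  for (osd in c(0.4, 1)) {
    got <- laplace_nll(p, toy$samples, toy$grid, 2000:2002,
                       family = "gaussian", obs_sd = osd)
    want <- gaussian_marginal_nll(p, toy$samples, toy$grid, 2000:2002,
                                  obs_sd = osd)
    expect_equal(as.numeric(got), want, tolerance = 1e-7)
  }
})

test_that("structured and dense Laplace paths agree", {
  toy <- toy_survey(seed = 22, nlat = 2, nlon = 2, years = 1999:2001,
                    samples_per_year = 25)
  p <- lgcp_params(sigma_sq = 1.5, sigma_y_sq = 0.2, sigma0_sq = 0.8,
                   intercept = -0.5)
  f_str <- laplace_nll(p, toy$samples, toy$grid, 1999:2001, method = "structured")
  f_den <- laplace_nll(p, toy$samples, toy$grid, 1999:2001, method = "dense")
  expect_equal(as.numeric(f_str), as.numeric(f_den), tolerance = 1e-8)
})

test_that("nugget-only Poisson marginal matches 61-node Gauss-Hermite", {
  toy <- toy_survey(seed = 23, nlat = 2, nlon = 2, years = 2000:2001,
                    samples_per_year = 40)
  s <- toy$samples
  p <- lgcp_params(sigma_sq = 0, sigma_y_sq = 0, sigma0_sq = 1.5,
                   intercept = -0.8)
  got <- as.numeric(laplace_nll(p, s, toy$grid, 2000:2001))
  mu <- p$intercept + seasonal_effect(p, s$day_of_year) +
    catchability_effect(p, s$thermocline_depth_m)
  want <- gh_poisson_lognormal_nll(s$count, mu, rep(1.5, nrow(s)))
  expect_lt(abs(got - want) / abs(want), 0.01)
})

test_that("correlated three-year Poisson marginal matches tensor Gauss-Hermite", {
  g <- grid_spec(nlat = 1, nlon = 1, dlat = 10, dlon = 13)
  years <- 2000:2002
  set.seed(31)
  n <- 30
  s <- data.frame(sample_id = sprintf("S%02d", 1:n),
                  lat = runif(n, 51, 61), lon = runif(n, -3.5, 9.5),
                  year = sample(years, n, replace = TRUE),
                  day_of_year = sample(120:260, n, replace = TRUE),
                  hour = sample(0:23, n, replace = TRUE),
                  count = rpois(n, 1.2))
  p <- lgcp_params(sigma_sq = 1.2, sigma_y_sq = 0, sigma0_sq = 0,
                   intercept = -0.5, log_beta = -1.22)
  got <- as.numeric(laplace_nll(p, s, g, years))
  mu <- p$intercept + seasonal_effect(p, s$day_of_year)
  T_ <- exp(-exp(p$log_beta) * abs(outer(years, years, "-"))) + 1e-8 * diag(3)
  want <- gh_mvn_poisson_nll(s$count, mu, match(s$year, years),
                             p$sigma_sq * T_)
  expect_lt(abs(got - want) / abs(want), 0.01)
})

test_that("with every variance zero the marginal is the Poisson regression likelihood", {
  toy <- toy_survey(seed = 24, nlat = 2, nlon = 2, years = 2000:2001,
                    samples_per_year = 30)
  s <- toy$samples
  p <- lgcp_params(sigma_sq = 0, sigma_y_sq = 0, sigma0_sq = 0,
                   intercept = -0.6)
  got <- as.numeric(laplace_nll(p, s, toy$grid, 2000:2001))
  eta <- p$intercept + seasonal_effect(p, s$day_of_year) +
    catchability_effect(p, s$thermocline_depth_m)
  want <- sum(exp(eta) - s$count * eta + lgamma(s$count + 1))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("the analytic outer gradient matches numerical differentiation", {
  toy <- toy_survey(seed = 25, nlat = 2, nlon = 2, years = 2000:2002,
                    samples_per_year = 25)
  p <- lgcp_params(sigma_sq = 1.5, sigma_y_sq = 0.2, sigma0_sq = 0.8,
                   intercept = -0.5)
  ms <- cprlgcp:::lgcp_model_frame(toy$samples, toy$grid, 2000:2002)
  theta <- cprlgcp:::params_to_theta(p, ms)
  g_an <- cprlgcp:::laplace_eval(theta, ms, want = c("value", "gradient"),
                                 inner_tol = 1e-11)$gradient
  g_num <- numDeriv::grad(function(th)
    cprlgcp:::laplace_eval(th, ms, inner_tol = 1e-11)$value, theta)
  expect_equal(as.numeric(g_an), g_num, tolerance = 1e-5)
})

test_that("parameter vectors round-trip through the internal parameterization", {
  toy <- toy_survey(seed = 26, nlat = 2, nlon = 2, years = 2000:2001,
                    samples_per_year = 10)
  ms <- cprlgcp:::lgcp_model_frame(toy$samples, toy$grid, 2000:2001)
  p <- lgcp_params(sigma_sq = 1.3, sigma_y_sq = 0.4, sigma0_sq = 0.6,
                   intercept = -2, a_spawn1 = 0.1, a_spawn2 = 3e-4,
                   a_thc1 = 0.05, a_thc2 = 1.5e-3)
  back <- cprlgcp:::theta_to_params(cprlgcp:::params_to_theta(p, ms), ms)
  for (nm in c("sigma_sq", "sigma_y_sq", "sigma0_sq", "intercept",
               "a_spawn1", "a_spawn2", "a_thc1", "a_thc2",
               "log_alpha", "log_beta"))
    expect_equal(back[[nm]], p[[nm]], tolerance = 1e-12, label = nm)
})
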