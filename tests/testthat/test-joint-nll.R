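test_that("joint likelihood with all-zero counts reduces to sum(exp(eta)) plus priors", {
  toy <- toy_survey(seed = 11, nlat = 2, nlon = 2, years = 2000:2001,
                    samples_per_year = 15)
  s <- toy$samples
  s$count <- 0L
  lat <- toy$latent
  p <- toy$config$params

  eta <- linear_predictor(p, lat, s)
  jit <- 1e-8
  Dx <- centroid_distances_km(toy$grid)
  Dt <- abs(outer(2000:2001, 2000:2001, "-"))
  S <- exp(-exp(p$log_alpha) * Dx) + jit * diag(4)
  T_ <- exp(-exp(p$log_beta) * Dt) + jit * diag(2)
  cc <- rep(1:4, 2); yy <- rep(1:2, each = 4)
  manual <- sum(exp(eta)) -
    mvtnorm::dmvnorm(as.vector(lat$u), sigma = p$sigma_sq * S[cc, cc] * T_[yy, yy],
                     log = TRUE) -
    mvtnorm::dmvnorm(lat$w, sigma = p$sigma_y_sq * T_, log = TRUE) -
    sum(stats::dnorm(lat$eps, sd = sqrt(p$sigma0_sq), log = TRUE))
  expect_equal(joint_nll(p, lat, s), manual, tolerance = 1e-8)
})

test_that("joint likelihood is invariant under sample reordering", {
  toy <- toy_survey(seed = 12, nlat = 2, nlon = 2, years = 2000:2002,
                    samples_per_year = 20)
  s <- toy$samples; lat <- toy$latent; p <- toy$config$params
  f0 <- joint_nll(p, lat, s)
  set.seed(1); ord <- sample(nrow(s))
  lat2 <- lat; lat2$eps <- lat$eps[ord]
  expect_equal(joint_nll(p, lat2, s[ord, ]), f0, tolerance = 1e-10)
})

test_that("structured and dense joint likelihoods agree", {
  toy <- toy_survey(seed = 13, nlat = 2, nlon = 2, years = 1999:2001,
                    samples_per_year = 25)
  s <- toy$samples; lat <- toy$latent; p <- toy$config$params
  f_str <- joint_nll(p, lat, s, method = "structured")
  f_den <- joint_nll(p, lat, s, method = "dense")
  expect_equal(f_str, f_den, tolerance = 1e-8)
})

test_that("linear predictor assembles every term", {
  g <- grid_spec(nlat = 2, nlon = 2, dlat = 5, dlon = 6.5)
  p <- lgcp_params(intercept = -1, mu_hour = c(0.5, rep(-0.5 / 23, 23)))
  lat <- structure(list(u = matrix(1:8 / 10, 4, 2), w = c(0.2, -0.2),
                        eps = c(0.05, -0.05), grid = g, years = 2000:2001),
                   class = "lgcp_latent")
  s <- data.frame(lat = c(52, 59), lon = c(-2, 8), year = c(2000L, 2001L),
                  day_of_year = c(183L, 100L), hour = c(0L, 5L),
                  thermocline_depth_m = c(30, 10), count = c(0L, 1L))
  eta <- linear_predictor(p, lat, s)
  ## first sample: SW cell (1), year 1
  e1 <- -1 + seasonal_effect(p, 183) + catchability_effect(p, 30) +
    p$mu_hour[1] + lat$u[1, 1] + lat$w[1] + 0.05
  e2 <- -1 + seasonal_effect(p, 100) + catchability_effect(p, 10) +
    p$mu_hour[6] + lat$u[4, 2] + lat$w[2] - 0.05
  expect_equal(eta, c(e1, e2))
  ## missing thermocline values must be resolved before evaluation
  s$thermocline_depth_m[1] <- NA
  expect_error(linear_predictor(p, lat, s), "policy")
})
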