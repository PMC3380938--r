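test_that("maximum-likelihood fitting converges and beats the truth likelihood", {
  sf <- shared_fit()
  fit <- sf$fit; toy <- sf$toy
  expect_s3_class(fit, "lgcp_fit")
  expect_true(fit$convergence$converged)
  ## the optimum cannot be worse than the generating parameters
  nll_truth <- as.numeric(laplace_nll(toy$config$params, toy$samples,
                                      toy$grid, 1998:2005))
  expect_lte(fit$nll, nll_truth + 1e-6)
  expect_lt(fit$convergence$outer_grad_norm, 1e-2)
})

test_that("accessor methods expose the fit on the reported scale", {
  sf <- shared_fit()
  fit <- sf$fit
  cf <- coef(fit)
  expect_true(all(c("sigma_sq", "log_alpha", "log_beta", "a_spawn1",
                    "a_spawn2", "a_thc1", "a_thc2", "intercept") %in% names(cf)))
  expect_equal(as.numeric(logLik(fit)), -fit$nll)
  expect_equal(attr(logLik(fit), "df"), length(fit$theta))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.lgcp_fit")
  expect_true(all(is.finite(sm$table$estimate)))
  expect_true(all(is.finite(sm$table$se)))
  expect_equal(sm$table["sigma_sq", "estimate"], cf[["sigma_sq"]])
  ## derived worked examples are consistent with the estimates
  expect_equal(sm$corr_100km,
               exp(-exp(cf[["log_alpha"]]) * 100), tolerance = 1e-12)
  expect_equal(sm$corr_1yr, exp(-exp(cf[["log_beta"]])), tolerance = 1e-12)
  expect_output(print(fit), "Cox process fit")
  expect_output(print(sm), "parameter estimates")
})

test_that("fitted values and residuals are coherent at the latent mode", {
  fit <- shared_fit()$fit
  mu <- fitted(fit)
  expect_true(all(mu > 0))
  r <- residuals(fit)
  expect_equal(r, (fit$ms$N - mu) / sqrt(mu))
  ## Pearson residuals should be roughly centred
  expect_lt(abs(mean(r)), 0.5)
})

test_that("simulate() reproduces the design and respects the seed", {
  fit <- shared_fit()$fit
  s1 <- simulate(fit, nsim = 2, seed = 9)
  s2 <- simulate(fit, nsim = 2, seed = 9)
  expect_length(s1, 2)
  expect_identical(s1[[1]]$count, s2[[1]]$count)
  expect_false(identical(s1[[1]]$count, s1[[2]]$count))
  expect_identical(s1[[1]]$lat, fit$ms$samples$lat)
  expect_identical(s1[[1]]$day_of_year, fit$ms$samples$day_of_year)
})

test_that("likelihood-ratio machinery compares nested fits", {
  sf <- shared_fit()
  fit_red <- lgcp_fit(sf$toy$samples, sf$toy$grid, 1998:2005,
                      include = list(yeareff = FALSE),
                      control = lgcp_control(outer_tol = 1e-8, se = FALSE))
  lt <- lr_test(sf$fit, fit_red)
  expect_gte(lt$statistic, 0)
  expect_equal(lt$df, 1)
  expect_gte(lt$p_value, 0); expect_lte(lt$p_value, 1)
  av <- anova(fit_red, sf$fit)
  expect_s3_class(av, "anova")
  expect_equal(av$Chisq[2], lt$statistic)
  ## an inconsistent pair (reduced beating full) is refused
  bad_full <- structure(list(nll = 10, theta = 1:3), class = "lgcp_fit")
  bad_red <- structure(list(nll = 5, theta = 1:2), class = "lgcp_fit")
  expect_error(lr_test(bad_full, bad_red), "negative LR")
})

test_that("effect plots render without error", {
  fit <- shared_fit()$fit
  path <- tempfile(fileext = ".pdf")
  grDevices::pdf(path)
  expect_no_error(plot(fit, which = 1:3, year = 2001))
  grDevices::dev.off()
  expect_true(file.exists(path))
})
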