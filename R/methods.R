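# S3 methods for fitted models.

#' @export
print.lgcp_fit <- function(x, ...) {
  cat("Log-Gaussian Cox process fit (Laplace maximum likelihood)\n")
  cat(sprintf("  %d samples, %d x %d-cell grid, %d year(s); nll = %.4f\n",
              x$ms$n, x$ms$grid$nlat, x$ms$grid$nlon, x$ms$Y, x$nll))
  cat(sprintf("  latent components: %s\n",
              paste(names(Filter(isTRUE, x$ms$include)), collapse = ", ")))
  print(x$params)
  invisible(x)
}

#' Summarize a fitted larval Cox process
#'
#' @param object An `lgcp_fit`.
#' @param ... Unused.
#' @return A `summary.lgcp_fit`: the parameter table on the reported (raw)
#'   scale with delta-method standard errors, correlation worked examples
#'   (100 km, 1 year), and peak locations of the quadratic effects.
#' @export
summary.lgcp_fit <- function(object, ...) {
  p <- object$params
  est <- c(sigma0_sq = p$sigma0_sq, sigma_sq = p$sigma_sq,
           sigma_y_sq = p$sigma_y_sq, log_alpha = p$log_alpha,
           log_beta = p$log_beta, a_spawn1 = p$a_spawn1, a_spawn2 = p$a_spawn2,
           a_thc1 = p$a_thc1, a_thc2 = p$a_thc2, intercept = p$intercept)
  if (!is.null(p$period_shift)) est <- c(est, period_shift = p$period_shift)
  se <- object$se
  tab <- data.frame(estimate = est,
                    se = if (is.null(se)) NA_real_ else se[names(est)])
  keep <- !(names(est) %in% c("sigma_sq", "log_alpha") & !object$ms$include$field) &
          !(names(est) == "sigma_y_sq" & !object$ms$include$yeareff) &
          !(names(est) == "sigma0_sq" & !object$ms$include$nugget)
  tab <- tab[keep, , drop = FALSE]
  out <- list(table = tab, nll = object$nll,
              corr_100km = if (object$ms$include$field)
                correlation_at(p, 100, 0) else NA,
              corr_1yr = if (object$ms$include$field || object$ms$include$yeareff)
                exp(-exp(p$log_beta)) else NA,
              peak_day = if (p$a_spawn2 > 0) seasonal_peak_day(p) else NA,
              peak_thc = if (object$ms$effects$thermocline && p$a_thc2 > 0)
                catchability_peak_m(p) else NA,
              convergence = object$convergence)
  class(out) <- "summary.lgcp_fit"
  out
}

#' @export
print.summary.lgcp_fit <- function(x, ...) {
  cat("Larval log-Gaussian Cox process -- parameter estimates\n\n")
  print(signif(x$table, 4))
  cat(sprintf("\nnegative marginal log-likelihood: %.4f\n", x$nll))
  if (is.finite(x$corr_100km))
    cat(sprintf("spatial correlation at 100 km: %.2f\n", x$corr_100km))
  if (is.finite(x$corr_1yr))
    cat(sprintf("temporal correlation, adjacent years: %.2f\n", x$corr_1yr))
  if (is.finite(x$peak_day))
    cat(sprintf("seasonal peak: day %.1f\n", x$peak_day))
  if (is.finite(x$peak_thc))
    cat(sprintf("catchability peak: %.1f m thermocline\n", x$peak_thc))
  invisible(x)
}

#' @export
coef.lgcp_fit <- function(object, ...) {
  p <- object$params
  out <- c(sigma0_sq = p$sigma0_sq, sigma_sq = p$sigma_sq,
           sigma_y_sq = p$sigma_y_sq, log_alpha = p$log_alpha,
           log_beta = p$log_beta, a_spawn1 = p$a_spawn1, a_spawn2 = p$a_spawn2,
           a_thc1 = p$a_thc1, a_thc2 = p$a_thc2, intercept = p$intercept)
  if (!is.null(p$period_shift)) out <- c(out, period_shift = p$period_shift)
  out
}

#' @export
vcov.lgcp_fit <- function(object, ...) object$vcov_theta

#' @export
logLik.lgcp_fit <- function(object, ...) {
  structure(-object$nll, df = length(object$theta), class = "logLik")
}

#' @export
fitted.lgcp_fit <- function(object, ...) {
  eta <- as.vector(object$ms$X %*% object$theta[colnames(object$ms$X)])
  md <- object$mode
  if (object$ms$include$field) eta <- eta + md$u[object$ms$kk]
  if (object$ms$include$yeareff) eta <- eta + md$w[object$ms$yy]
  if (object$ms$include$nugget) eta <- eta + md$eps
  exp(eta)
}

#' Pearson residuals at the posterior latent mode
#' @param object An `lgcp_fit`.
#' @param ... Unused.
#' @export
residuals.lgcp_fit <- function(object, ...) {
  mu <- fitted(object)
  (object$ms$N - mu) / sqrt(mu)
}

#' Simulate survey count tables from a fitted model
#'
#' Draws new latent states and Poisson counts at the fitted parameters, on
#' the design (positions, dates, covariates) of the original samples.
#'
#' @param object An `lgcp_fit`.
#' @param nsim Number of replicate tables.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` sample data frames.
#' @export
simulate.lgcp_fit <- function(object, nsim = 1, seed = 1, ...) {
  ms <- object$ms
  seeds <- split_seed(seed, nsim)
  lapply(seq_len(nsim), function(r) {
    lat <- simulate_latent_state(object$params, ms$grid, ms$years, ms$n, seeds[r])
    smp <- ms$samples
    eta <- linear_predictor(object$params, lat, smp)
    check(max(eta) < 30, "simulated log-intensity exceeds 30")
    smp$count <- with_seed(seeds[r] + 1, stats::rpois(ms$n, exp(eta)))
    smp
  })
}

#' Predict posterior intensity surfaces from a fitted model
#'
#' @param object An `lgcp_fit`.
#' @param year Calendar year to map.
#' @param day Optional day of year; omitted, the seasonal curve is integrated
#'   over the year.
#' @param ... Unused.
#' @return An [intensity_map()] object.
#' @export
predict.lgcp_fit <- function(object, year, day = NULL, ...) {
  intensity_map(object, year = year, day = day)
}

#' Diagnostic and effect plots for a fitted model
#'
#' `which = 1` seasonal curve, `2` thermocline catchability curve, `3` map of
#' the posterior mean field for a year.
#'
#' @param x An `lgcp_fit`.
#' @param which Plots to draw.
#' @param year Year for the map panel.
#' @param ... Passed to the underlying plot functions.
#' @export
plot.lgcp_fit <- function(x, which = 1:2, year = NULL, ...) {
  p <- x$params
  if (1 %in% which) {
    d <- 1:365
    graphics::plot(d, exp(seasonal_effect(p, d) - max(seasonal_effect(p, d))),
                   type = "l", xlab = "day of year",
                   ylab = "relative seasonal intensity",
                   main = "Seasonal spawning curve", ...)
    if (p$a_spawn2 > 0) graphics::abline(v = seasonal_peak_day(p), lty = 2)
  }
  if (2 %in% which && x$ms$effects$thermocline) {
    t <- seq(0, 80, by = 0.5)
    graphics::plot(t, exp(catchability_effect(p, t) - max(catchability_effect(p, t))),
                   type = "l", xlab = "thermocline depth (m)",
                   ylab = "relative catchability",
                   main = "Thermocline catchability", ...)
    if (p$a_thc2 > 0) graphics::abline(v = catchability_peak_m(p), lty = 2)
  }
  if (3 %in% which) {
    if (is.null(year)) year <- x$ms$years[1]
    plot(intensity_map(x, year = year), ...)
  }
  invisible(x)
}
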