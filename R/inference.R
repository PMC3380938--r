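# Inference products: Laplace posterior of the latent state, intensity maps,
# the annual abundance index, and the period-shift test.

## joint Laplace posterior over (u, w): mean, covariance pieces
posterior_joint <- function(fit) {
  ms <- fit$ms
  inc <- ms$include
  nu <- if (inc$field) ms$C * ms$Y else 0L
  nw <- if (inc$yeareff) ms$Y else 0L
  J <- if (nu + nw > 0) chol2inv(fit$cholH) else matrix(0, 0, 0)
  list(nu = nu, nw = nw, J = J,
       u_mean = if (inc$field) matrix(fit$mode$u, ms$C, ms$Y) else
         matrix(0, ms$C, ms$Y),
       w_mean = if (inc$yeareff) fit$mode$w else numeric(ms$Y))
}

#' Laplace posterior of the latent field and year levels
#'
#' The Gaussian approximation to the conditional distribution of the latent
#' space-time field and year levels given all data: posterior mean (the joint
#' mode -- the conditional-expectation "best guess") and marginal variances.
#'
#' @param fit An `lgcp_fit`.
#' @return A list with `u_mean`, `u_var` (cell x year matrices), `w_mean`,
#'   `w_var` (per year), and the grid/years.
#' @export
posterior_latent <- function(fit) {
  ms <- fit$ms
  pj <- posterior_joint(fit)
  u_var <- if (pj$nu > 0) matrix(diag(pj$J)[seq_len(pj$nu)], ms$C, ms$Y)
           else matrix(0, ms$C, ms$Y)
  w_var <- if (pj$nw > 0) diag(pj$J)[pj$nu + seq_len(pj$nw)] else numeric(ms$Y)
  list(u_mean = pj$u_mean, u_var = u_var,
       w_mean = pj$w_mean, w_var = w_var,
       grid = ms$grid, years = ms$years)
}

#' Evaluate a posterior at fixed parameters
#'
#' Runs the inner (latent-mode) computation only, at user-supplied
#' parameters, and returns a minimal fit-like object usable with
#' [posterior_latent()], [intensity_map()] and [annual_index()].  With an
#' empty sample table this recovers the prior (mean zero, prior variances).
#'
#' @param params An [lgcp_params()].
#' @param samples Sample data frame (may have zero rows).
#' @param grid A [grid_spec()].
#' @param years Modelled years.
#' @param control An [lgcp_control()].
#' @return An object of class `lgcp_fit` (without standard errors).
#' @export
lgcp_posterior <- function(params, samples, grid, years,
                           control = lgcp_control()) {
  ms <- lgcp_model_frame(samples, grid, years,
                         effects = effects_from_params(params, samples),
                         include = include_from_params(params),
                         thermocline_policy = control$thermocline_policy,
                         jitter = control$jitter)
  theta <- params_to_theta(params, ms)
  ev <- laplace_eval(theta, ms, inner_tol = control$inner_tol,
                     inner_maxit = control$inner_maxit)
  structure(list(params = params, theta = theta, nll = ev$value,
                 mode = ev$mode, cholH = ev$cholH, ms = ms,
                 control = control, se = NULL, vcov_theta = NULL,
                 convergence = list(converged = TRUE)),
            class = "lgcp_fit")
}

## reference catchability level: quadratic maximum of the thermocline curve
## (hour offsets are sum-zero, reference 0); catchability models observation
## efficiency, not abundance, so maps and the index hold it at this reference
catchability_reference <- function(fit) {
  p <- fit$params
  if (!fit$ms$effects$thermocline) return(0)
  if (p$a_thc2 > 0) catchability_effect(p, catchability_peak_m(p))
  else max(catchability_effect(p, c(0, 60)))
}

period_offset_by_year <- function(fit) {
  ms <- fit$ms
  if (!ms$effects$period || is.null(fit$params$period_shift)) return(numeric(ms$Y))
  cb <- ms$period_cuts[1]; ca <- ms$period_cuts[2]
  z <- pmin(1, pmax(0, (ms$years - cb) / max(1, ca - cb)))
  fit$params$period_shift * z
}

#' Posterior mean intensity map for one year
#'
#' Per-cell posterior mean of the intensity \eqn{E[e^\eta] = e^{m + v/2}}
#' (and its lognormal standard deviation), with the latent field and year
#' level at their Laplace posterior, the seasonal curve at the requested day
#' (or integrated over the year), and catchability held at its reference.
#'
#' @param fit An `lgcp_fit`.
#' @param year Calendar year within the fitted range.
#' @param day Optional day of year; `NULL` integrates the seasonal curve
#'   over days 1..365.
#' @return An `intensity_map`: list with `mean` and `sd` vectors over cells,
#'   the grid, year and day.
#' @export
intensity_map <- function(fit, year, day = NULL) {
  ms <- fit$ms
  yi <- match(year, ms$years)
  check(!is.na(yi), sprintf("year %s outside the fitted range", year))
  pj <- posterior_joint(fit)
  v <- numeric(ms$C)
  if (pj$nu > 0) {
    iu <- (yi - 1) * ms$C + seq_len(ms$C)
    v <- v + diag(pj$J)[iu]
    if (pj$nw > 0) v <- v + pj$J[pj$nu + yi, pj$nu + yi] +
        2 * pj$J[cbind(iu, pj$nu + yi)]
  } else if (pj$nw > 0) v <- v + pj$J[pj$nu + yi, pj$nu + yi]
  m <- fit$params$intercept + pj$u_mean[, yi] + pj$w_mean[yi] +
    catchability_reference(fit) + period_offset_by_year(fit)[yi]
  seas <- if (is.null(day)) {
    log(sum(exp(seasonal_effect(fit$params, 1:365))))
  } else seasonal_effect(fit$params, day)
  mean_int <- exp(m + seas + v / 2)
  sd_int <- mean_int * sqrt(pmax(exp(v) - 1, 0))
  structure(list(year = year, day = day, grid = ms$grid,
                 mean = mean_int, sd = sd_int), class = "intensity_map")
}

#' @export
print.intensity_map <- function(x, ...) {
  cat(sprintf("intensity_map: year %d%s, %d cells, mean intensity %.3g\n",
              x$year, if (is.null(x$day)) " (season-integrated)"
              else sprintf(", day %d", x$day),
              x$grid$ncell, mean(x$mean)))
  invisible(x)
}

#' Plot an intensity map with decile colour bins
#'
#' Cells are coloured by the decile of their posterior mean intensity
#' (white = lowest 10 percent, dark red = highest), which preserves the rank
#' order of the raw posterior means.
#'
#' @param x An [intensity_map()].
#' @param ... Passed to [graphics::image()].
#' @export
plot.intensity_map <- function(x, ...) {
  g <- x$grid
  M <- matrix(x$mean, g$nlat, g$nlon)
  br <- unique(stats::quantile(x$mean, probs = seq(0, 1, 0.1)))
  cols <- grDevices::colorRampPalette(c("white", "orange", "red", "darkred"))(length(br) - 1)
  graphics::image(x = g$lon0 + (seq_len(g$nlon) - 0.5) * g$dlon,
                  y = g$lat0 + (seq_len(g$nlat) - 0.5) * g$dlat,
                  z = t(M), breaks = br, col = cols,
                  xlab = "longitude", ylab = "latitude",
                  main = sprintf("Posterior mean intensity, %d", x$year), ...)
  invisible(x)
}

#' Annual abundance index with Monte-Carlo confidence intervals
#'
#' For each year, the posterior mean of the spatially integrated intensity:
#' cell areas (km^2, spherical) times \eqn{E[e^\eta]}, summed over cells and
#' integrated over the seasonal curve (days 1..365 by direct summation), with
#' catchability held at its reference level.  Interval bounds come from
#' seeded Monte-Carlo draws of the Laplace-Gaussian posterior of the latent
#' field and year levels, propagated through the same sum (the exp-transform
#' makes the index distribution skewed, so sampling is preferred over the
#' delta method).
#'
#' @param fit An `lgcp_fit`.
#' @param ndraws Number of posterior draws for the interval (default 1000).
#' @param seed Integer seed for the draws.
#' @param level Interval coverage (default 0.95).
#' @param seasonal `"integrate"` (default) sums the seasonal curve over the
#'   year; `"peak"` evaluates it at the peak day only.
#' @return An `lgcp_index` data frame: `year`, `index`, `lo`, `hi`.
#' @export
annual_index <- function(fit, ndraws = 1000, seed = 1, level = 0.95,
                         seasonal = c("integrate", "peak")) {
  seasonal <- match.arg(seasonal)
  ms <- fit$ms
  pj <- posterior_joint(fit)
  area <- cell_areas_km2(ms$grid)
  seas <- if (seasonal == "integrate")
    sum(exp(seasonal_effect(fit$params, 1:365)))
  else exp(seasonal_effect(fit$params, seasonal_peak_day(fit$params)))
  const <- fit$params$intercept + catchability_reference(fit)
  poy <- period_offset_by_year(fit)

  ## analytic posterior mean via the lognormal formula
  v_u <- if (pj$nu > 0) matrix(diag(pj$J)[seq_len(pj$nu)], ms$C, ms$Y)
         else matrix(0, ms$C, ms$Y)
  v_w <- if (pj$nw > 0) diag(pj$J)[pj$nu + seq_len(pj$nw)] else numeric(ms$Y)
  v_uw <- matrix(0, ms$C, ms$Y)
  if (pj$nu > 0 && pj$nw > 0)
    for (y in seq_len(ms$Y)) {
      iu <- (y - 1) * ms$C + seq_len(ms$C)
      v_uw[, y] <- pj$J[cbind(iu, pj$nu + y)]
    }
  m_cy <- sweep(pj$u_mean, 2, pj$w_mean + poy, "+")
  v_cy <- sweep(v_u + 2 * v_uw, 2, v_w, "+")
  index <- seas * exp(const) *
    as.vector(colSums(area * exp(m_cy + v_cy / 2)))

  ## Monte-Carlo interval
  lo <- hi <- rep(NA_real_, ms$Y)
  nx <- pj$nu + pj$nw
  if (nx > 0 && ndraws > 0) {
    Z <- with_seed(seed, matrix(stats::rnorm(nx * ndraws), nx, ndraws))
    Xd <- backsolve(fit$cholH, Z)       # cov = (R'R)^{-1} = H^{-1}
    draws <- matrix(NA_real_, ndraws, ms$Y)
    mode_x <- c(if (pj$nu > 0) as.vector(pj$u_mean) else numeric(0),
                if (pj$nw > 0) pj$w_mean else numeric(0))
    for (s in seq_len(ndraws)) {
      xs <- mode_x + Xd[, s]
      us <- if (pj$nu > 0) matrix(xs[seq_len(pj$nu)], ms$C, ms$Y)
            else matrix(0, ms$C, ms$Y)
      ws <- if (pj$nw > 0) xs[pj$nu + seq_len(pj$nw)] else numeric(ms$Y)
      draws[s, ] <- seas * exp(const) *
        colSums(area * exp(sweep(us, 2, ws + poy, "+")))
    }
    qs <- apply(draws, 2, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2))
    lo <- qs[1, ]; hi <- qs[2, ]
  } else { lo <- hi <- index }
  structure(data.frame(year = ms$years, index = index, lo = lo, hi = hi),
            class = c("lgcp_index", "data.frame"), level = level)
}

#' @export
plot.lgcp_index <- function(x, ...) {
  graphics::plot(x$year, x$index, type = "n",
                 ylim = range(c(x$lo, x$hi), finite = TRUE),
                 xlab = "year", ylab = "abundance index",
                 main = "Annual larval abundance index", ...)
  graphics::polygon(c(x$year, rev(x$year)), c(x$lo, rev(x$hi)),
                    col = "grey85", border = NA)
  graphics::lines(x$year, x$index, lwd = 2)
  invisible(x)
}

#' Test for a shift in mean abundance between two periods
#'
#' Fits the model with and without a period offset on the mean log year
#' level: offset 0 for years before `cut_before`, the estimated shift for
#' years after `cut_after`, and a linear ramp in between (intermediate years
#' are otherwise carried by the random year level).  The two fits are
#' compared by a likelihood-ratio test on one degree of freedom, and the mean
#' annual index over each period is reported.
#'
#' @param samples Sample data frame.
#' @param grid A [grid_spec()].
#' @param cut_before,cut_after Years delimiting the early (`< cut_before`)
#'   and late (`> cut_after`) periods.
#' @param years Modelled years (default: sample range).
#' @param effects,control Passed to [lgcp_fit()].
#' @param index_draws Posterior draws for the period-mean indices.
#' @return A list: `statistic`, `df`, `p_value`, `period_means` (named early
#'   /late), `shift` (estimated offset, log scale), and both fits.
#' @export
period_shift_test <- function(samples, grid, cut_before, cut_after,
                              years = NULL, effects = list(),
                              control = lgcp_control(), index_draws = 200) {
  if (is.null(years)) years <- seq(min(samples$year), max(samples$year))
  check(any(samples$year < cut_before), "no samples in the early period")
  check(any(samples$year > cut_after), "no samples in the late period")
  eff_red <- modifyList(effects, list(period = FALSE))
  eff_full <- modifyList(effects, list(period = TRUE))
  fit_red <- lgcp_fit(samples, grid, years, effects = eff_red, control = control)
  start_full <- c(fit_red$theta, period = 0)
  fit_full <- lgcp_fit(samples, grid, years, effects = eff_full,
                       control = control, period_cuts = c(cut_before, cut_after),
                       start = start_full)
  lt <- lr_test(fit_full, fit_red, df = 1)
  idx <- annual_index(fit_full, ndraws = index_draws)
  early <- idx$year < cut_before; late <- idx$year > cut_after
  list(statistic = lt$statistic, df = lt$df, p_value = lt$p_value,
       shift = fit_full$params$period_shift,
       period_means = c(early = mean(idx$index[early]),
                        late = mean(idx$index[late])),
       index = idx, fit_full = fit_full, fit_reduced = fit_red)
}
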