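# Structural model parameters and the quantities derived directly from them.

#' Model parameters of the larval log-Gaussian Cox process
#'
#' Container for all structural parameters of the model.  The latent
#' log-intensity of sample \eqn{i} is
#' \deqn{\eta_i = intercept + field(cell_i, year_i) + yeareff(year_i) +
#'   p_{spawn}(d_i) + p_{thc}(t_i) [+ \mu(h_i)] + nugget_i}
#' with quadratics parameterised as \eqn{p(x) = a_1 x - a_2 x^2} so that
#' positive \eqn{a_1, a_2} give a concave (peaked) curve, and counts Poisson
#' given \eqn{\eta}.
#'
#' The defaults are the package's reference parameter set for North Sea
#' mackerel-larvae CPR series and are the truth used by the synthetic-data
#' generator: nugget variance 2.36, space-time field variance 6.43, spatial
#' decay `log_alpha = -5.45` (e-folding ~233 km), temporal decay
#' `log_beta = -1.22` (adjacent-year correlation 0.74), seasonal quadratic
#' (0.241, 6.21e-4) peaking in mid-July, thermocline catchability quadratic
#' (0.0833, 2.71e-3) peaking just above a ~15 m thermocline.  The year-level
#' variance defaults to 0.25 (interannual abundance swings of roughly a
#' factor e) and the intercept is set so that, with sampling spread over the
#' whole year, the expected catch is a few larvae per hundred samples --
#' a series dominated by zeros, as such surveys are.
#'
#' @param sigma0_sq Nugget (per-sample) variance on the log scale.
#' @param sigma_sq Variance of the separable space-time field.
#' @param sigma_y_sq Variance of the random year level.
#' @param log_alpha Log spatial decay rate (per km).
#' @param log_beta Log temporal decay rate (per year).
#' @param a_spawn1,a_spawn2 Seasonal quadratic coefficients (per day, per day^2).
#' @param a_thc1,a_thc2 Thermocline quadratic coefficients (per m, per m^2).
#' @param intercept Overall log-intensity level.
#' @param mu_hour Optional numeric(24) hour-of-day offsets (sum-to-zero
#'   convention for identifiability), or `NULL` to disable the hour effect.
#' @param period_shift Optional additive offset on the log scale applied to
#'   the late period in the period-shift model, or `NULL`.
#' @return An object of class `lgcp_params` (a named list).
#' @examples
#' p <- lgcp_params()
#' correlation_at(p, dx_km = 100, dt_years = 0)  # ~0.65
#' seasonal_peak_day(p)                          # ~194
#' @export
lgcp_params <- function(sigma0_sq = 2.36, sigma_sq = 6.43, sigma_y_sq = 0.25,
                        log_alpha = -5.45, log_beta = -1.22,
                        a_spawn1 = 2.41e-1, a_spawn2 = 6.21e-4,
                        a_thc1 = 8.33e-2, a_thc2 = 2.71e-3,
                        intercept = -24.5, mu_hour = NULL,
                        period_shift = NULL) {
  p <- list(sigma0_sq = sigma0_sq, sigma_sq = sigma_sq, sigma_y_sq = sigma_y_sq,
            log_alpha = log_alpha, log_beta = log_beta,
            a_spawn1 = a_spawn1, a_spawn2 = a_spawn2,
            a_thc1 = a_thc1, a_thc2 = a_thc2,
            intercept = intercept, mu_hour = mu_hour,
            period_shift = period_shift)
  check(all(c(p$sigma0_sq, p$sigma_sq, p$sigma_y_sq) >= 0),
        "variances must be non-negative")
  check(is.finite(p$log_alpha) && is.finite(p$log_beta),
        "decay rates must be finite on the log scale")
  if (!is.null(mu_hour)) {
    check(length(mu_hour) == 24, "mu_hour must have one offset per hour (24)")
    if (abs(sum(mu_hour)) > 1e-8)
      warning("mu_hour does not sum to zero; the mean level is confounded with the intercept")
  }
  if (p$a_spawn2 <= 0 || p$a_thc2 <= 0)
    warning("a_spawn2/a_thc2 <= 0: quadratic effect is not concave (no interior peak)")
  class(p) <- "lgcp_params"
  p
}

#' @export
print.lgcp_params <- function(x, ...) {
  cat("lgcp_params:\n")
  v <- unlist(x[c("sigma0_sq", "sigma_sq", "sigma_y_sq", "log_alpha", "log_beta",
                  "a_spawn1", "a_spawn2", "a_thc1", "a_thc2", "intercept")])
  print(signif(v, 4))
  if (!is.null(x$mu_hour)) cat("hour effect enabled (24 offsets, sum-zero)\n")
  if (!is.null(x$period_shift)) cat(sprintf("period shift: %.3f\n", x$period_shift))
  invisible(x)
}

#' Space-time correlation of the latent field
#'
#' The separable exponential correlation
#' \eqn{\rho(\Delta x, \Delta t) = \exp(-\alpha \Delta x - \beta \Delta t)}
#' with \eqn{\alpha = e^{log\_alpha}} per km and \eqn{\beta = e^{log\_beta}}
#' per year.
#'
#' @param params An [lgcp_params()].
#' @param dx_km Spatial separation in km (non-negative, vectorised).
#' @param dt_years Temporal separation in whole years (non-negative).
#' @return Correlation value(s) in (0, 1].
#' @export
correlation_at <- function(params, dx_km, dt_years) {
  check(all(dx_km >= 0) && all(dt_years >= 0), "separations must be non-negative")
  exp(-exp(params$log_alpha) * dx_km - exp(params$log_beta) * dt_years)
}

#' Seasonal spawning curve on the log scale
#'
#' \eqn{p_{spawn}(d) = a_1 d - a_2 d^2}, the log of a Gaussian-shaped
#' seasonal abundance pattern in day-of-year.
#'
#' @param params An [lgcp_params()].
#' @param day Day of year.
#' @return Log-scale seasonal effect.
#' @export
seasonal_effect <- function(params, day)
  params$a_spawn1 * day - params$a_spawn2 * day^2

#' Thermocline catchability curve on the log scale
#'
#' \eqn{p_{thc}(t) = a_1 t - a_2 t^2}, the log-scale efficiency of the
#' fixed-depth recorder as a function of thermocline depth in metres.
#'
#' @param params An [lgcp_params()].
#' @param thermocline_m Thermocline depth in metres.
#' @return Log-scale catchability effect.
#' @export
catchability_effect <- function(params, thermocline_m)
  params$a_thc1 * thermocline_m - params$a_thc2 * thermocline_m^2

#' Peak of a concave quadratic a1*x - a2*x^2
#' @param a1,a2 Quadratic coefficients with `a2 > 0`.
#' @return The argmax `a1 / (2 * a2)`.
#' @export
quadratic_peak <- function(a1, a2) {
  check(a2 > 0, "quadratic has no interior maximum (a2 <= 0)")
  a1 / (2 * a2)
}

#' Day of year at which the seasonal spawning curve peaks
#' @param params An [lgcp_params()].
#' @export
seasonal_peak_day <- function(params) quadratic_peak(params$a_spawn1, params$a_spawn2)

#' Thermocline depth (m) of maximum catchability
#' @param params An [lgcp_params()].
#' @export
catchability_peak_m <- function(params) quadratic_peak(params$a_thc1, params$a_thc2)
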