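# Maximum-likelihood fitting of the larval log-Gaussian Cox process.

#' Control settings for [lgcp_fit()]
#'
#' @param inner_tol Gradient tolerance of the inner (latent-mode) Newton
#'   solver.
#' @param inner_maxit Maximum inner Newton iterations.
#' @param outer_tol Relative convergence tolerance of the outer quasi-Newton
#'   optimization over the structural parameters.
#' @param outer_maxit Maximum outer iterations.
#' @param jitter Diagonal jitter added to the spatial and temporal
#'   correlation matrices before factorization.
#' @param se Compute standard errors from the outer numerical Hessian
#'   (central differences of the analytic gradient)?
#' @param thermocline_policy How samples with undefined thermocline (fully
#'   mixed column) enter the catchability term: `"deep60"` treats them as a
#'   deep (60 m) thermocline, `"drop"` removes them, `"error"` refuses.
#' @param trace Print outer optimizer progress (0 = silent).
#' @return A list of control settings.
#' @export
lgcp_control <- function(inner_tol = 1e-8, inner_maxit = 100,
                         outer_tol = 1e-6, outer_maxit = 300,
                         jitter = 1e-8, se = TRUE,
                         thermocline_policy = c("deep60", "drop", "error"),
                         trace = 0) {
  list(inner_tol = inner_tol, inner_maxit = inner_maxit,
       outer_tol = outer_tol, outer_maxit = outer_maxit,
       jitter = jitter, se = se,
       thermocline_policy = match.arg(thermocline_policy), trace = trace)
}

## data-driven starting values: Poisson regression for the fixed effects,
## generic scales for the variance/decay parameters
default_start <- function(ms) {
  th <- stats::setNames(numeric(length(theta_names(ms))), theta_names(ms))
  if (ms$n > 0 && ms$family == "poisson") {
    fit0 <- suppressWarnings(stats::glm.fit(ms$X, ms$N, family = stats::poisson()))
    beta0 <- ifelse(is.finite(fit0$coefficients), fit0$coefficients, 0)
    th[colnames(ms$X)] <- beta0
  }
  if (ms$include$nugget) th["tau0"] <- 0            # nugget variance 1
  if (ms$include$field) { th["tau"] <- 0; th["la"] <- log(1 / 100) }
  if (ms$include$yeareff) th["tauy"] <- log(0.5)
  if ("lb" %in% names(th)) th["lb"] <- -1
  th
}

#' Fit the larval log-Gaussian Cox process by Laplace maximum likelihood
#'
#' Maximizes the Laplace-approximated marginal likelihood over all structural
#' parameters: variances are optimized on the log scale, decay rates as
#' log(alpha) and log(beta), and the seasonal/thermocline quadratics on
#' centered covariates (coefficients are reported back-transformed to the raw
#' day-of-year and metre scales).  Standard errors come from the numerically
#' differentiated outer Hessian; the Laplace-Gaussian posterior of the latent
#' field and year levels at the optimum is retained for prediction.
#'
#' @param samples Sample data frame (see [read_samples()]); `cell_id` is
#'   assigned from `grid` when absent.
#' @param grid A [grid_spec()].
#' @param years Integer vector of modelled years; defaults to the full range
#'   present in `samples`.  Years without samples remain in the latent state
#'   and are integrated out.
#' @param effects List of switches: `thermocline` (default `TRUE`), `hour`
#'   (default `FALSE`; 24 offsets under a sum-to-zero constraint), `period`
#'   (internal, used by [period_shift_test()]).
#' @param include List of latent components to keep: `field`, `yeareff`,
#'   `nugget` (all default `TRUE`); disable one to form a nested null model
#'   for a likelihood-ratio test.
#' @param start Optional named starting vector (internal parameterization) or
#'   an [lgcp_params()] object.
#' @param control An [lgcp_control()] list.
#' @param period_cuts Length-2 year cut points for the period effect.
#' @return An object of class `lgcp_fit` with components `params` (an
#'   [lgcp_params()] on the raw scale), `theta`/`vcov_theta` (internal scale),
#'   `se` (delta-method standard errors on the reported scale), `nll`,
#'   `mode`, `posterior` (Cholesky factor and layout of the Laplace posterior
#'   over field and year levels), and `convergence` diagnostics.
#' @seealso [summary.lgcp_fit()], [predict.lgcp_fit()], [annual_index()],
#'   [anova.lgcp_fit()]
#' @export
lgcp_fit <- function(samples, grid, years = NULL,
                     effects = list(), include = list(),
                     start = NULL, control = lgcp_control(),
                     period_cuts = NULL) {
  check(nrow(samples) > 0, "no samples to fit")
  if (is.null(years)) years <- seq(min(samples$year), max(samples$year))
  ms <- lgcp_model_frame(samples, grid, years, effects = effects,
                         include = include,
                         thermocline_policy = control$thermocline_policy,
                         period_cuts = period_cuts,
                         jitter = control$jitter)
  th0 <- if (is.null(start)) default_start(ms)
         else if (inherits(start, "lgcp_params")) params_to_theta(start, ms)
         else start[theta_names(ms)]

  state <- new.env(parent = emptyenv())
  cache <- new.env(parent = emptyenv()); cache$theta <- NULL
  evalboth <- function(th) {
    if (!is.null(cache$theta) && isTRUE(all.equal(cache$theta, th, tolerance = 0)))
      return(invisible(NULL))
    ev <- laplace_eval(th, ms, state = state, want = "gradient",
                       inner_tol = control$inner_tol,
                       inner_maxit = control$inner_maxit)
    cache$theta <- th; cache$value <- ev$value; cache$grad <- ev$gradient
    cache$ev <- ev
    invisible(NULL)
  }
  obj <- function(th) { evalboth(th); cache$value }
  grd <- function(th) { evalboth(th); cache$grad }

  lower <- rep(-Inf, length(th0)); upper <- rep(Inf, length(th0))
  vn <- intersect(c("tau0", "tau", "tauy"), names(th0))
  lower[match(vn, names(th0))] <- -12   # variances >= ~6e-6: effectively zero
  upper[match(vn, names(th0))] <- 12
  opt <- stats::nlminb(th0, obj, gradient = grd,
                       lower = lower, upper = upper,
                       control = list(rel.tol = control$outer_tol,
                                      iter.max = control$outer_maxit,
                                      eval.max = 4 * control$outer_maxit,
                                      trace = control$trace))
  theta <- stats::setNames(opt$par, names(th0))
  evalboth(theta)
  ev <- cache$ev
  grad_norm <- max(abs(cache$grad))

  vcov_theta <- NULL; se_theta <- NULL
  if (control$se) {
    Hout <- outer_hessian(theta, ms, state, control)
    vcov_theta <- tryCatch(solve(Hout), error = function(e) NULL)
    if (!is.null(vcov_theta)) {
      dv <- diag(vcov_theta)
      se_theta <- stats::setNames(sqrt(pmax(dv, 0)), names(theta))
      if (any(dv <= 0)) warning("outer Hessian not positive definite; some standard errors are unreliable")
    } else warning("outer Hessian is singular; no standard errors")
  }

  params <- theta_to_params(theta, ms)
  fit <- structure(list(
    params = params, theta = theta, vcov_theta = vcov_theta,
    se = report_se(theta, vcov_theta, ms),
    nll = opt$objective, logLik = -opt$objective,
    mode = ev$mode, cholH = ev$cholH,
    ms = ms, control = control,
    convergence = list(code = opt$convergence, message = opt$message,
                       outer_grad_norm = grad_norm,
                       iterations = opt$iterations,
                       converged = opt$convergence == 0)),
    class = "lgcp_fit")
  if (!fit$convergence$converged)
    warning("outer optimizer did not report convergence: ", opt$message)
  fit
}

## central-difference Hessian of the Laplace objective from analytic gradients
outer_hessian <- function(theta, ms, state, control) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    h <- 1e-4 * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    gp <- laplace_eval(tp, ms, state = state, want = "gradient",
                       inner_tol = control$inner_tol,
                       inner_maxit = control$inner_maxit)$gradient
    gm <- laplace_eval(tm, ms, state = state, want = "gradient",
                       inner_tol = control$inner_tol,
                       inner_maxit = control$inner_maxit)$gradient
    H[j, ] <- (gp - gm) / (2 * h)
  }
  (H + t(H)) / 2
}

## delta-method standard errors on the reported (raw) scale
report_se <- function(theta, vcov_theta, ms) {
  if (is.null(vcov_theta)) return(NULL)
  cd <- ms$centers[["day"]]; ct <- ms$centers[["thermocline"]]
  sd_ <- ms$scales[["day"]]; st <- ms$scales[["thermocline"]]
  nm <- names(theta)
  se <- list()
  lin <- function(w) {            # se of w' theta
    wv <- stats::setNames(numeric(length(nm)), nm); wv[names(w)] <- w
    sqrt(max(0, as.numeric(t(wv) %*% vcov_theta %*% wv)))
  }
  pick <- function(x) if (x %in% nm) lin(stats::setNames(1, x)) else NA_real_
  if ("tau0" %in% nm) se$sigma0_sq <- exp(theta[["tau0"]]) * pick("tau0")
  if ("tau" %in% nm) se$sigma_sq <- exp(theta[["tau"]]) * pick("tau")
  if ("tauy" %in% nm) se$sigma_y_sq <- exp(theta[["tauy"]]) * pick("tauy")
  if ("la" %in% nm) se$log_alpha <- pick("la")
  if ("lb" %in% nm) se$log_beta <- pick("lb")
  se$a_spawn1 <- lin(c(spawn1 = 1 / sd_, spawn2 = 2 * cd / sd_^2))
  se$a_spawn2 <- pick("spawn2") / sd_^2
  if ("thc1" %in% nm) {
    se$a_thc1 <- lin(c(thc1 = 1 / st, thc2 = 2 * ct / st^2))
    se$a_thc2 <- pick("thc2") / st^2
  }
  se$intercept <- pick("intercept")
  if ("period" %in% nm) se$period_shift <- pick("period")
  unlist(se)
}

#' Likelihood-ratio test between two nested model fits
#'
#' @param fit_full,fit_reduced Fitted models from [lgcp_fit()]; the reduced
#'   model must be nested in the full one.
#' @param df Degrees of freedom; defaults to the difference in the number of
#'   outer parameters.
#' @return A list with `statistic` (twice the difference in minimized
#'   negative log-likelihood), `df`, and `p_value` from the chi-squared
#'   reference distribution.  Tests of a variance component lying on the
#'   boundary (e.g. nugget = 0) are conservative under this reference.
#' @export
lr_test <- function(fit_full, fit_reduced, df = NULL) {
  if (is.null(df)) df <- length(fit_full$theta) - length(fit_reduced$theta)
  check(df >= 1, "the full model has no extra parameters")
  stat <- 2 * (fit_reduced$nll - fit_full$nll)
  tol <- 1e-4 * (1 + abs(fit_full$nll))
  if (stat < -tol)
    stop(sprintf("negative LR statistic (%.4g): optimizer failure in one of the fits", stat),
         call. = FALSE)
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' @rdname lr_test
#' @param object,... For the `anova` method: the reduced fit, then the full fit.
#' @export
anova.lgcp_fit <- function(object, ...) {
  fits <- c(list(object), list(...))
  check(length(fits) == 2 && inherits(fits[[2]], "lgcp_fit"),
        "anova.lgcp_fit compares exactly two nested fits (reduced, full)")
  red <- fits[[1]]; full <- fits[[2]]
  if (length(red$theta) > length(full$theta)) { tmp <- red; red <- full; full <- tmp }
  lt <- lr_test(full, red)
  out <- data.frame(npar = c(length(red$theta), length(full$theta)),
                    nll = c(red$nll, full$nll),
                    Chisq = c(NA, lt$statistic), Df = c(NA, lt$df),
                    `Pr(>Chisq)` = c(NA, lt$p_value), check.names = FALSE)
  rownames(out) <- c("reduced", "full")
  structure(out, class = c("anova", "data.frame"),
            heading = "Likelihood-ratio test (Laplace marginal likelihood)")
}
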