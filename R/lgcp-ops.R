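# Public likelihood operations: linear predictor, joint negative
# log-likelihood, and the Laplace-approximated marginal likelihood, each with
# a structured (Schur/Kronecker-aware) and a dense brute-force path.  The
# dense path builds the full latent covariance element by element and solves
# it directly; it exists as an internal cross-check for small problems.

effects_from_params <- function(params, samples) {
  list(thermocline = "thermocline_depth_m" %in% names(samples),
       hour = !is.null(params$mu_hour),
       period = !is.null(params$period_shift))
}

include_from_params <- function(params) {
  list(field = params$sigma_sq > 0,
       yeareff = params$sigma_y_sq > 0,
       nugget = params$sigma0_sq > 0)
}

#' Per-sample log-intensity of the larval Cox process
#'
#' Assembles \eqn{\eta_i = intercept + field + yeareffect + p_{spawn}(d_i) +
#' p_{thc}(t_i) [+ \mu(h_i)] + nugget_i} for each sample.
#'
#' @param params An [lgcp_params()].
#' @param latent A latent state as returned by [simulate_latent()]: a list
#'   with `u` (cell x year matrix), `w` (per-year), `eps` (per-sample),
#'   `grid`, `years`.
#' @param samples Sample data frame carrying `cell_id`, `year`,
#'   `day_of_year`, `hour` and (if the thermocline effect applies)
#'   `thermocline_depth_m`.
#' @return Numeric vector of log-intensities, one per sample.
#' @export
linear_predictor <- function(params, latent, samples) {
  if (is.null(samples$cell_id)) samples <- assign_cells(samples, latent$grid)
  yy <- match(samples$year, latent$years)
  check(!anyNA(yy), "sample years not covered by the latent state")
  eta <- params$intercept + seasonal_effect(params, samples$day_of_year)
  if ("thermocline_depth_m" %in% names(samples)) {
    th <- samples$thermocline_depth_m
    if (anyNA(th)) stop("missing thermocline depth; apply a policy first", call. = FALSE)
    eta <- eta + catchability_effect(params, th)
  }
  if (!is.null(params$mu_hour)) eta <- eta + params$mu_hour[samples$hour + 1]
  eps <- if (is.null(latent$eps)) 0 else latent$eps
  eta <- eta + latent$u[cbind(samples$cell_id, yy)] + latent$w[yy] + eps
  unname(eta)
}

## dense brute-force latent covariance blocks (no Kronecker shortcuts)
dense_latent_cov <- function(params, grid, years, jitter = 1e-8) {
  C <- grid$ncell; Y <- length(years)
  Dx <- outer(seq_len(C), seq_len(C), function(i, j)
    haversine_km(grid$lat_mid[i], grid$lon_mid[i], grid$lat_mid[j], grid$lon_mid[j]))
  Dt <- abs(outer(years, years, "-"))
  Su <- exp(-exp(params$log_alpha) * Dx) + jitter * diag(C)
  Tu <- exp(-exp(params$log_beta) * Dt) + jitter * diag(Y)
  cc <- rep(seq_len(C), times = Y); yy <- rep(seq_len(Y), each = C)
  Sig_u <- params$sigma_sq * Su[cc, cc] * Tu[yy, yy]
  Sig_w <- params$sigma_y_sq * Tu
  list(Sig_u = Sig_u, Sig_w = Sig_w)
}

#' Joint negative log-likelihood of data and latent state
#'
#' Minus the log of the product of the Poisson observation densities and the
#' Gaussian densities of the latent components (space-time field, year
#' levels, nuggets), including all normalizing constants.
#'
#' @inheritParams linear_predictor
#' @param method `"structured"` (default) exploits the separable Kronecker
#'   covariance; `"dense"` builds the full latent covariance brute-force
#'   (small problems only; used for validation).
#' @param jitter Diagonal jitter added to the correlation factors.
#' @return The joint negative log-likelihood (scalar).
#' @export
joint_nll <- function(params, latent, samples, method = c("structured", "dense"),
                      jitter = 1e-8) {
  method <- match.arg(method)
  grid <- latent$grid; years <- latent$years
  eta <- linear_predictor(params, latent, samples)
  f <- sum(exp(eta) - samples$count * eta + lgamma(samples$count + 1))
  C <- grid$ncell; Y <- length(years); n <- nrow(samples)
  u <- as.vector(latent$u); w <- latent$w
  if (method == "structured") {
    Dx <- centroid_distances_km(grid)
    Dt <- abs(outer(years, years, "-"))
    Sj <- exp(-exp(params$log_alpha) * Dx) + jitter * diag(C)
    Tj <- exp(-exp(params$log_beta) * Dt) + jitter * diag(Y)
    cS <- chol(Sj); cT <- chol(Tj)
    Sinv <- chol2inv(cS); Tinv <- chol2inv(cT)
    if (params$sigma_sq > 0) {
      U <- matrix(u, C, Y)
      f <- f + 0.5 * sum(U * (Sinv %*% U %*% Tinv)) / params$sigma_sq +
        0.5 * (C * Y * log(params$sigma_sq) + 2 * Y * sum(log(diag(cS))) +
               2 * C * sum(log(diag(cT)))) + 0.5 * C * Y * log(2 * pi)
    }
    if (params$sigma_y_sq > 0)
      f <- f + 0.5 * sum(w * (Tinv %*% w)) / params$sigma_y_sq +
        0.5 * (Y * log(params$sigma_y_sq) + 2 * sum(log(diag(cT)))) +
        0.5 * Y * log(2 * pi)
  } else {
    cv <- dense_latent_cov(params, grid, years, jitter)
    if (params$sigma_sq > 0) {
      cU <- chol(cv$Sig_u)
      f <- f + 0.5 * sum(backsolve(cU, u, transpose = TRUE)^2) +
        sum(log(diag(cU))) + 0.5 * C * Y * log(2 * pi)
    }
    if (params$sigma_y_sq > 0) {
      cW <- chol(cv$Sig_w)
      f <- f + 0.5 * sum(backsolve(cW, w, transpose = TRUE)^2) +
        sum(log(diag(cW))) + 0.5 * Y * log(2 * pi)
    }
  }
  if (params$sigma0_sq > 0)
    f <- f + 0.5 * sum(latent$eps^2) / params$sigma0_sq +
      0.5 * n * log(2 * pi * params$sigma0_sq)
  f
}

#' Laplace-approximated negative marginal log-likelihood
#'
#' Integrates the latent components out of the joint likelihood by a Laplace
#' approximation: the joint negative log-likelihood at the latent mode plus
#' half the log-determinant of the inner Hessian, minus
#' \eqn{(n_{latent}/2)\log 2\pi}.  For the Gaussian observation family the
#' approximation is exact.
#'
#' @param params An [lgcp_params()].  Components with zero variance are
#'   excluded from the latent state (so with all variances zero this reduces
#'   to the fixed-effects Poisson regression likelihood).
#' @param samples Sample data frame (`cell_id` assigned from `grid` if absent).
#' @param grid A [grid_spec()].
#' @param years Integer vector of modelled years (defaults to the sample range).
#' @param family Observation family: `"poisson"` counts (default) or
#'   `"gaussian"` direct noisy observations of \eqn{\eta} (used for validation).
#' @param obs_sd Observation standard deviation for the Gaussian family.
#' @param method `"structured"` or `"dense"` (see [joint_nll()]).
#' @param control An [lgcp_control()] list (inner tolerances, jitter).
#' @return The negative marginal log-likelihood, with the latent mode in
#'   attribute `"mode"`.
#' @export
laplace_nll <- function(params, samples, grid, years = NULL,
                        family = c("poisson", "gaussian"), obs_sd = 1,
                        method = c("structured", "dense"),
                        control = lgcp_control()) {
  family <- match.arg(family); method <- match.arg(method)
  if (is.null(years)) years <- seq(min(samples$year), max(samples$year))
  ms <- lgcp_model_frame(samples, grid, years,
                         effects = effects_from_params(params, samples),
                         include = include_from_params(params),
                         family = family, obs_sd = obs_sd,
                         thermocline_policy = control$thermocline_policy,
                         jitter = control$jitter)
  theta <- params_to_theta(params, ms)
  if (method == "structured") {
    ev <- laplace_eval(theta, ms, inner_tol = control$inner_tol,
                       inner_maxit = control$inner_maxit)
    structure(ev$value, mode = ev$mode)
  } else {
    dense_laplace(theta, ms)
  }
}

## dense-path Laplace: full latent vector, direct solves
dense_laplace <- function(theta, ms) {
  inc <- ms$include
  C <- ms$C; Y <- ms$Y; n <- ms$n
  nu <- if (inc$field) C * Y else 0L
  nw <- if (inc$yeareff) Y else 0L
  ne <- if (inc$nugget) n else 0L
  m <- nu + nw + ne
  params <- theta_to_params(theta, ms)
  cv <- dense_latent_cov(params, ms$grid, ms$years, ms$jitter)
  Q <- matrix(0, m, m)
  logdetSig <- 0
  if (nu > 0) {
    cU <- chol(cv$Sig_u)
    Q[seq_len(nu), seq_len(nu)] <- chol2inv(cU)
    logdetSig <- logdetSig + 2 * sum(log(diag(cU)))
  }
  if (nw > 0) {
    cW <- chol(cv$Sig_w)
    Q[nu + seq_len(nw), nu + seq_len(nw)] <- chol2inv(cW)
    logdetSig <- logdetSig + 2 * sum(log(diag(cW)))
  }
  if (ne > 0) {
    ii <- nu + nw + seq_len(ne)
    Q[cbind(ii, ii)] <- 1 / params$sigma0_sq
    logdetSig <- logdetSig + n * log(params$sigma0_sq)
  }
  ## P: n x m incidence of latents in eta
  P <- matrix(0, n, m)
  if (nu > 0) P[cbind(seq_len(n), ms$kk)] <- 1
  if (nw > 0) P[cbind(seq_len(n), nu + ms$yy)] <- P[cbind(seq_len(n), nu + ms$yy)] + 1
  if (ne > 0) P[cbind(seq_len(n), nu + nw + seq_len(n))] <- 1
  Xb <- as.vector(ms$X %*% theta[colnames(ms$X)])
  z <- numeric(m)
  f_of <- function(z) {
    od <- obs_derivs(ms, Xb + as.vector(P %*% z))
    od$f + 0.5 * sum(z * (Q %*% z)) + 0.5 * logdetSig + 0.5 * m * log(2 * pi)
  }
  f <- f_of(z)
  H <- NULL
  for (it in 1:100) {
    od <- obs_derivs(ms, Xb + as.vector(P %*% z))
    g <- as.vector(crossprod(P, od$d1)) + as.vector(Q %*% z)
    H <- crossprod(P, od$d2 * P) + Q
    if (max(abs(g)) < 1e-10) break
    step <- -solve(H, g)
    alpha <- 1
    repeat {
      fc <- f_of(z + alpha * step)
      if (is.finite(fc) && fc <= f + 1e-12 * abs(f)) { z <- z + alpha * step; f <- fc; break }
      alpha <- alpha / 2
      if (alpha < 1e-10) break
    }
    if (alpha < 1e-10) break
  }
  value <- f + 0.5 * determinant(H, logarithm = TRUE)$modulus - 0.5 * m * log(2 * pi)
  structure(as.numeric(value),
            mode = list(u = if (nu) z[seq_len(nu)] else numeric(0),
                        w = if (nw) z[nu + seq_len(nw)] else numeric(0),
                        eps = if (ne) z[nu + nw + seq_len(ne)] else numeric(0)))
}
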