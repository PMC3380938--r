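# Independent oracles used to validate the likelihood machinery.  These are
# deliberately written with none of the package's internal shortcuts: direct
# dense linear algebra and quadrature only.

## Exact marginal nll for the GAUSSIAN observation family:
## y ~ N(X beta, P Sigma_lat P' + obs_sd^2 I), all pieces dense.
gaussian_marginal_nll <- function(params, samples, grid, years, obs_sd = 1,
                                  jitter = 1e-8) {
  n <- nrow(samples)
  C <- grid$ncell
  Y <- length(years)
  if (is.null(samples$cell_id)) samples <- assign_cells(samples, grid)
  yy <- match(samples$year, years)
  kk <- samples$cell_id + (yy - 1L) * C

  Dx <- outer(seq_len(C), seq_len(C), function(i, j)
    haversine_km(grid$lat_mid[i], grid$lon_mid[i], grid$lat_mid[j], grid$lon_mid[j]))
  Dt <- abs(outer(years, years, "-"))
  S <- exp(-exp(params$log_alpha) * Dx) + jitter * diag(C)
  T_ <- exp(-exp(params$log_beta) * Dt) + jitter * diag(Y)

  Sig <- matrix(0, n, n)
  if (params$sigma_sq > 0) {
    cc <- ((kk - 1L) %% C) + 1L
    Sig <- Sig + params$sigma_sq * S[cc, cc] * T_[yy, yy]
  }
  if (params$sigma_y_sq > 0) Sig <- Sig + params$sigma_y_sq * T_[yy, yy]
  if (params$sigma0_sq > 0) Sig <- Sig + params$sigma0_sq * diag(n)
  Sig <- Sig + obs_sd^2 * diag(n)

  mu <- params$intercept + seasonal_effect(params, samples$day_of_year)
  if ("thermocline_depth_m" %in% names(samples))
    mu <- mu + catchability_effect(params, samples$thermocline_depth_m)
  -mvtnorm::dmvnorm(samples$count, mean = mu, sigma = Sig, log = TRUE)
}

## Adaptive Gauss-Hermite marginal nll for INDEPENDENT 1-D Poisson-lognormal
## observations: count ~ Poisson(exp(mu_i + z_i)), z_i ~ N(0, v_i) iid.
gh_poisson_lognormal_nll <- function(counts, mu, v, nodes = 61) {
  gh <- pracma::gaussHermite(nodes)
  total <- 0
  for (i in seq_along(counts)) {
    f <- function(z) exp(mu[i] + z) - counts[i] * (mu[i] + z) +
      lgamma(counts[i] + 1) + z^2 / (2 * v[i]) + 0.5 * log(2 * pi * v[i])
    zhat <- stats::optimize(f, c(-40, 40))$minimum
    h <- exp(mu[i] + zhat) + 1 / v[i]          # f''(zhat)
    s <- sqrt(2 / h)
    lik <- sum(gh$w * exp(gh$x^2 - f(zhat + s * gh$x))) * s
    total <- total - log(lik)
  }
  total
}

## Adaptive Gauss-Hermite marginal nll for a small CORRELATED Gaussian latent
## block under Poisson observation: counts_i ~ Poisson(exp(mu_i + z_{map(i)})),
## z ~ N(0, Sigma) with dim(Sigma) <= 3 (tensor-product quadrature).
gh_mvn_poisson_nll <- function(counts, mu, map, Sigma, nodes = 61) {
  d <- nrow(Sigma)
  Q <- solve(Sigma)
  f <- function(z) {
    eta <- mu + z[map]
    sum(exp(eta) - counts * eta + lgamma(counts + 1)) +
      0.5 * sum(z * (Q %*% z)) +
      0.5 * determinant(Sigma, logarithm = TRUE)$modulus + 0.5 * d * log(2 * pi)
  }
  opt <- stats::optim(numeric(d), f, method = "BFGS", hessian = TRUE)
  L <- t(chol(solve(opt$hessian)))          # scale of the adapted nodes
  gh <- pracma::gaussHermite(nodes)
  grids <- do.call(expand.grid, rep(list(seq_len(nodes)), d))
  lik <- 0
  for (r in seq_len(nrow(grids))) {
    ix <- as.integer(grids[r, ])
    x <- gh$x[ix]
    z <- opt$par + sqrt(2) * as.vector(L %*% x)
    lik <- lik + prod(gh$w[ix]) * exp(sum(x^2) - f(z))
  }
  -(log(lik) + 0.5 * d * log(2) + determinant(L, logarithm = TRUE)$modulus)
}

## one moderately sized fitted model, shared by several test files (the fit
## is the expensive step; every consumer only reads from it)
.shared <- new.env(parent = emptyenv())
shared_fit <- function() {
  if (is.null(.shared$fit)) {
    .shared$toy <- toy_survey(seed = 101, nlat = 3, nlon = 3,
                              years = 1998:2005, samples_per_year = 50)
    .shared$fit <- lgcp_fit(.shared$toy$samples, .shared$toy$grid,
                            1998:2005, control = lgcp_control(outer_tol = 1e-8))
  }
  list(fit = .shared$fit, toy = .shared$toy)
}

## small ready-made survey for tests that just need plausible data
toy_survey <- function(seed = 42, nlat = 3, nlon = 3, years = 1999:2002,
                       samples_per_year = 40, params = lgcp_params()) {
  g <- grid_spec(nlat = nlat, nlon = nlon,
                 dlat = 10 / nlat, dlon = 13 / nlon)
  cfg <- sim_config(grid = g, years = years,
                    samples_per_year = samples_per_year,
                    params = params, seed = seed)
  sim <- simulate_cpr(cfg)
  list(grid = g, samples = sim$samples, latent = sim$latent,
       thermocline = sim$thermocline, config = cfg)
}
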