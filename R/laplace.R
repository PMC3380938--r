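# Laplace-approximated marginal likelihood of the larval log-Gaussian Cox
# process.
#
# Latent components (any subset may be active):
#   u  : space-time field, vec of a C x Y matrix, prior N(0, sigma^2 T (x) S)
#        with S = exp(-alpha * D_km), T = exp(-beta * |dyear|)  (column y of
#        the matrix holds the field for year y, so vec-cov is T kronecker S)
#   w  : random year level, prior N(0, sigma_y^2 T)
#   eps: per-sample nugget, prior N(0, sigma0^2 I)
# Observation: count_i ~ Poisson(exp(eta_i)) with
#   eta_i = X beta + u[cell_i, year_i] + w[year_i] + eps_i
# (a Gaussian observation family is also provided; for it the Laplace
# approximation is exact, which the tests exploit as a closed-form oracle).
#
# The inner Newton solver eliminates the diagonal nugget block by a Schur
# complement, leaving a dense symmetric system over (u, w) whose Cholesky
# factor also furnishes log det H and the Laplace posterior covariance.
# The outer gradient is fully analytic, including the third-derivative term
# from the dependence of the mode and Hessian on the parameters.

## scatter-add x by integer group idx into a vector of length n
scatter_sum <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x)) {
    r <- rowsum(x, idx)
    out[as.integer(rownames(r))] <- r
  }
  out
}

## ---------------------------------------------------------------------------
## model structure

#' @keywords internal
lgcp_model_frame <- function(samples, grid, years,
                             effects = list(thermocline = TRUE, hour = FALSE,
                                            period = FALSE),
                             include = list(field = TRUE, yeareff = TRUE,
                                            nugget = TRUE),
                             family = c("poisson", "gaussian"), obs_sd = 1,
                             thermocline_policy = c("deep60", "drop", "error"),
                             period_cuts = NULL,
                             centers = c(day = 183, thermocline = 30),
                             scales = c(day = 100, thermocline = 25),
                             jitter = 1e-8) {
  family <- match.arg(family)
  thermocline_policy <- match.arg(thermocline_policy)
  eff <- modifyList(list(thermocline = TRUE, hour = FALSE, period = FALSE), effects)
  inc <- modifyList(list(field = TRUE, yeareff = TRUE, nugget = TRUE), include)
  if (is.null(samples$cell_id) && nrow(samples) > 0)
    samples <- assign_cells(samples, grid)
  if (nrow(samples) > 0) {
    check(is_count(samples$count), "counts must be non-negative integers")
    check(all(samples$year %in% years), "sample years outside the modelled year range")
  }
  if (eff$thermocline && nrow(samples) > 0) {
    th <- samples$thermocline_depth_m
    if (is.null(th)) stop("thermocline effect enabled but samples lack thermocline_depth_m",
                          call. = FALSE)
    if (anyNA(th)) {
      if (thermocline_policy == "error")
        stop("missing thermocline depths and policy = 'error'", call. = FALSE)
      if (thermocline_policy == "drop") samples <- samples[!is.na(th), , drop = FALSE]
      if (thermocline_policy == "deep60")
        samples$thermocline_depth_m[is.na(th)] <- 60
    }
  }
  n <- nrow(samples)
  C <- grid$ncell
  Y <- length(years)
  yy <- match(samples$year, years)
  kk <- samples$cell_id + (yy - 1L) * C      # column-major (cell, yearidx)

  ## fixed-effect design matrix (covariates centered and scaled to O(1) for
  ## conditioning of the outer optimization; the -x^2 column makes the
  ## curvature coefficient positive for peaked curves)
  cols <- list(intercept = rep(1, n))
  if (n > 0) {
    dc <- (samples$day_of_year - centers[["day"]]) / scales[["day"]]
    cols$spawn1 <- dc
    cols$spawn2 <- -dc^2
    if (eff$thermocline) {
      tc <- (samples$thermocline_depth_m - centers[["thermocline"]]) /
        scales[["thermocline"]]
      cols$thc1 <- tc
      cols$thc2 <- -tc^2
    }
    if (eff$hour) {
      hf <- factor(samples$hour, levels = 0:23)
      Mh <- stats::model.matrix(~hf, contrasts.arg = list(hf = "contr.sum"))[, -1, drop = FALSE]
      colnames(Mh) <- paste0("hour", 1:23)
      for (j in seq_len(ncol(Mh))) cols[[colnames(Mh)[j]]] <- Mh[, j]
    }
    if (eff$period) {
      check(!is.null(period_cuts), "period effect needs period_cuts = c(cut_before, cut_after)")
      cb <- period_cuts[1]; ca <- period_cuts[2]
      z <- pmin(1, pmax(0, (samples$year - cb) / max(1, ca - cb)))
      cols$period <- z
    }
  } else {
    cols$spawn1 <- numeric(0); cols$spawn2 <- numeric(0)
    if (eff$thermocline) { cols$thc1 <- numeric(0); cols$thc2 <- numeric(0) }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  list(samples = samples, grid = grid, years = years, n = n, C = C, Y = Y,
       kk = kk, yy = yy, N = as.numeric(samples$count),
       X = X, effects = eff, include = inc, family = family, obs_sd = obs_sd,
       centers = centers, scales = scales, jitter = jitter,
       period_cuts = period_cuts,
       D_x = centroid_distances_km(grid),
       D_t = abs(outer(seq_len(Y), seq_len(Y), "-")))
}

## theta layout: c(beta..., tau0, tau, tauy, la, lb) with entries present only
## for active components
theta_names <- function(ms) {
  nm <- colnames(ms$X)
  if (ms$include$nugget) nm <- c(nm, "tau0")
  if (ms$include$field) nm <- c(nm, "tau", "la")
  if (ms$include$yeareff) nm <- c(nm, "tauy")
  if (ms$include$field || ms$include$yeareff) nm <- c(nm, "lb")
  nm
}

params_to_theta <- function(params, ms) {
  cd <- ms$centers[["day"]]; ct <- ms$centers[["thermocline"]]
  sd_ <- ms$scales[["day"]]; st <- ms$scales[["thermocline"]]
  beta <- c(intercept = params$intercept +
              (params$a_spawn1 * cd - params$a_spawn2 * cd^2) +
              (if (ms$effects$thermocline)
                 params$a_thc1 * ct - params$a_thc2 * ct^2 else 0),
            spawn1 = (params$a_spawn1 - 2 * params$a_spawn2 * cd) * sd_,
            spawn2 = params$a_spawn2 * sd_^2)
  if (ms$effects$thermocline)
    beta <- c(beta, thc1 = (params$a_thc1 - 2 * params$a_thc2 * ct) * st,
              thc2 = params$a_thc2 * st^2)
  if (ms$effects$hour) {
    mu <- if (is.null(params$mu_hour)) numeric(24) else params$mu_hour
    beta <- c(beta, stats::setNames(mu[1:23], paste0("hour", 1:23)))
  }
  if (ms$effects$period)
    beta <- c(beta, period = if (is.null(params$period_shift)) 0 else params$period_shift)
  th <- beta
  if (ms$include$nugget) th <- c(th, tau0 = log(params$sigma0_sq))
  if (ms$include$field) th <- c(th, tau = log(params$sigma_sq), la = params$log_alpha)
  if (ms$include$yeareff) th <- c(th, tauy = log(params$sigma_y_sq))
  if (ms$include$field || ms$include$yeareff) th <- c(th, lb = params$log_beta)
  th[theta_names(ms)]
}

theta_to_params <- function(theta, ms) {
  cd <- ms$centers[["day"]]; ct <- ms$centers[["thermocline"]]
  sd_ <- ms$scales[["day"]]; st <- ms$scales[["thermocline"]]
  g <- function(nm, default = 0) if (nm %in% names(theta)) unname(theta[nm]) else default
  a2 <- g("spawn2") / sd_^2; a1 <- g("spawn1") / sd_ + 2 * a2 * cd
  b2 <- g("thc2") / st^2;    b1 <- g("thc1") / st + 2 * b2 * ct
  intercept <- g("intercept") - (a1 * cd - a2 * cd^2) -
    (if (ms$effects$thermocline) b1 * ct - b2 * ct^2 else 0)
  mu_hour <- NULL
  if (ms$effects$hour) {
    mh <- unname(theta[paste0("hour", 1:23)])
    mu_hour <- c(mh, -sum(mh))
  }
  suppressWarnings(lgcp_params(
    sigma0_sq = if (ms$include$nugget) exp(g("tau0")) else 0,
    sigma_sq = if (ms$include$field) exp(g("tau")) else 0,
    sigma_y_sq = if (ms$include$yeareff) exp(g("tauy")) else 0,
    log_alpha = g("la", NA_real_), log_beta = g("lb", NA_real_),
    a_spawn1 = a1, a_spawn2 = a2, a_thc1 = b1, a_thc2 = b2,
    intercept = intercept, mu_hour = mu_hour,
    period_shift = if (ms$effects$period) g("period") else NULL))
}

## observation-family derivatives of -log p(N | eta) wrt eta
obs_derivs <- function(ms, eta) {
  if (ms$family == "poisson") {
    lam <- exp(eta)
    list(f = sum(lam - ms$N * eta + lgamma(ms$N + 1)),
         d1 = lam - ms$N, d2 = lam, d3 = lam)
  } else {
    s2 <- ms$obs_sd^2
    r <- eta - ms$N
    list(f = sum(r^2) / (2 * s2) + ms$n * 0.5 * log(2 * pi * s2),
         d1 = r / s2, d2 = rep(1 / s2, ms$n), d3 = rep(0, ms$n))
  }
}

## prior pieces for a given theta: precision blocks, log-dets, helpers
prior_build <- function(theta, ms) {
  j <- ms$jitter
  pr <- list()
  if (ms$include$field || ms$include$yeareff) {
    lb <- unname(theta["lb"])
    T0 <- exp(-exp(lb) * ms$D_t)
    Tj <- T0 + j * diag(ms$Y)
    cT <- chol(Tj)
    pr$T0 <- T0; pr$Tj <- Tj
    pr$Tinv <- chol2inv(cT)
    pr$logdetT <- 2 * sum(log(diag(cT)))
    pr$Tb <- -exp(lb) * ms$D_t * T0          # dT/d(log beta)
  }
  if (ms$include$field) {
    la <- unname(theta["la"])
    S0 <- exp(-exp(la) * ms$D_x)
    Sj <- S0 + j * diag(ms$C)
    cS <- chol(Sj)
    pr$S0 <- S0; pr$Sj <- Sj
    pr$Sinv <- chol2inv(cS)
    pr$logdetS <- 2 * sum(log(diag(cS)))
    pr$Sa <- -exp(la) * ms$D_x * S0          # dS/d(log alpha)
    pr$sigma_sq <- exp(unname(theta["tau"]))
  }
  if (ms$include$yeareff) pr$sigma_y_sq <- exp(unname(theta["tauy"]))
  if (ms$include$nugget) pr$sigma0_sq <- exp(unname(theta["tau0"]))
  pr
}

## ---------------------------------------------------------------------------
## structured Laplace evaluation

## Returns list(value, mode, extras...). `state` (an environment) carries the
## warm-started mode between calls.
laplace_eval <- function(theta, ms, state = NULL, want = c("value"),
                         inner_tol = 1e-8, inner_maxit = 100) {
  nmth <- theta_names(ms)
  check(length(theta) == length(nmth), "theta has the wrong length")
  names(theta) <- nmth
  pr <- prior_build(theta, ms)
  inc <- ms$include
  C <- ms$C; Y <- ms$Y; n <- ms$n
  nu <- if (inc$field) C * Y else 0L
  nw <- if (inc$yeareff) Y else 0L
  nx <- nu + nw
  m_lat <- nx + if (inc$nugget) n else 0L

  ## prior precision over x = (u, w)
  Qx <- NULL
  if (nx > 0) {
    Qx <- matrix(0, nx, nx)
    if (inc$field)
      Qx[seq_len(nu), seq_len(nu)] <- kronecker(pr$Tinv, pr$Sinv) / pr$sigma_sq
    if (inc$yeareff)
      Qx[nu + seq_len(nw), nu + seq_len(nw)] <- pr$Tinv / pr$sigma_y_sq
  }

  Xb <- as.vector(ms$X %*% theta[colnames(ms$X)])

  ## initial latent state
  if (!is.null(state) && !is.null(state$mode) && length(state$mode) == m_lat) {
    xz <- state$mode
  } else xz <- numeric(m_lat)
  split_lat <- function(z) list(
    u = if (inc$field) z[seq_len(nu)] else numeric(0),
    w = if (inc$yeareff) z[nu + seq_len(nw)] else numeric(0),
    eps = if (inc$nugget) z[nx + seq_len(n)] else numeric(0))

  eta_of <- function(lt) {
    eta <- Xb
    if (inc$field && n > 0) eta <- eta + lt$u[ms$kk]
    if (inc$yeareff && n > 0) eta <- eta + lt$w[ms$yy]
    if (inc$nugget) eta <- eta + lt$eps
    eta
  }

  fjoint <- function(lt) {
    od <- obs_derivs(ms, eta_of(lt))
    f <- od$f
    if (inc$field) {
      U <- matrix(lt$u, C, Y)
      f <- f + 0.5 * sum(U * (pr$Sinv %*% U %*% pr$Tinv)) / pr$sigma_sq +
        0.5 * (nu * log(pr$sigma_sq) + Y * pr$logdetS + C * pr$logdetT) +
        0.5 * nu * log(2 * pi)
    }
    if (inc$yeareff)
      f <- f + 0.5 * sum(lt$w * (pr$Tinv %*% lt$w)) / pr$sigma_y_sq +
        0.5 * (Y * log(pr$sigma_y_sq) + pr$logdetT) + 0.5 * Y * log(2 * pi)
    if (inc$nugget)
      f <- f + 0.5 * sum(lt$eps^2) / pr$sigma0_sq + 0.5 * n * log(2 * pi * pr$sigma0_sq)
    f
  }

  ## non-finite objective (e.g. exp overflow at an extreme trial theta):
  ## report +Inf so the outer optimizer rejects the step and shortens it
  bail <- function(lt) {
    out <- list(value = Inf, mode = lt, f_joint = Inf, logdetH = NA_real_,
                cholH = NULL, theta = theta, iter = NA_integer_)
    if ("gradient" %in% want)
      out$gradient <- stats::setNames(numeric(length(theta)), names(theta))
    out
  }

  lt <- split_lat(xz)
  f <- fjoint(lt)
  if (!is.finite(f)) { lt <- split_lat(numeric(m_lat)); f <- fjoint(lt) }
  if (!is.finite(f)) return(bail(lt))

  yofk <- if (inc$field) rep(seq_len(Y), each = C) else integer(0)
  cholH <- NULL; dvec <- NULL; od <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    od <- obs_derivs(ms, eta_of(lt))
    ## gradient over active latents
    g_u <- if (inc$field) scatter_sum(od$d1, ms$kk, nu) +
      as.vector(pr$Sinv %*% matrix(lt$u, C, Y) %*% pr$Tinv) / pr$sigma_sq else numeric(0)
    g_w <- if (inc$yeareff) scatter_sum(od$d1, ms$yy, nw) +
      as.vector(pr$Tinv %*% lt$w) / pr$sigma_y_sq else numeric(0)
    g_e <- if (inc$nugget) od$d1 + lt$eps / pr$sigma0_sq else numeric(0)
    gmax <- max(abs(c(g_u, g_w, g_e, 0)))
    if (!is.finite(gmax)) return(bail(lt))

    ## effective per-sample weight after eliminating the nugget
    if (inc$nugget) {
      dvec <- od$d2 + 1 / pr$sigma0_sq
      v <- ifelse(od$d2 > 0, 1 / (1 / pmax(od$d2, 1e-300) + pr$sigma0_sq), 0)
    } else { dvec <- NULL; v <- od$d2 }

    if (nx > 0) {
      H <- Qx
      if (inc$field) {
        Av <- scatter_sum(v, ms$kk, nu)
        idx <- seq_len(nu)
        H[cbind(idx, idx)] <- H[cbind(idx, idx)] + Av
        if (inc$yeareff) {
          H[cbind(idx, nu + yofk)] <- H[cbind(idx, nu + yofk)] + Av
          H[cbind(nu + yofk, idx)] <- H[cbind(nu + yofk, idx)] + Av
        }
      }
      if (inc$yeareff) {
        Aw <- scatter_sum(v, ms$yy, nw)
        idw <- nu + seq_len(nw)
        H[cbind(idw, idw)] <- H[cbind(idw, idw)] + Aw
      }
      cholH <- tryCatch(chol(H), error = function(e) NULL)
      if (is.null(cholH)) return(bail(lt))
    }

    if (gmax < inner_tol || iter > inner_maxit) break

    ## Newton direction via Schur complement on the nugget block
    if (nx > 0) {
      r_x <- -c(g_u, g_w)
      if (inc$nugget) {
        ge_d <- (od$d2 / dvec) * g_e
        if (inc$field) r_x[seq_len(nu)] <- r_x[seq_len(nu)] + scatter_sum(ge_d, ms$kk, nu)
        if (inc$yeareff) r_x[nu + seq_len(nw)] <- r_x[nu + seq_len(nw)] + scatter_sum(ge_d, ms$yy, nw)
      }
      dx <- backsolve(cholH, backsolve(cholH, r_x, transpose = TRUE))
    } else dx <- numeric(0)
    de <- if (inc$nugget) {
      sum_x <- numeric(n)
      if (inc$field) sum_x <- sum_x + dx[seq_len(nu)][ms$kk]
      if (inc$yeareff) sum_x <- sum_x + dx[nu + seq_len(nw)][ms$yy]
      (-g_e - od$d2 * sum_x) / dvec
    } else numeric(0)

    step <- c(dx, de)
    ## line search (step halving on the joint objective)
    alpha <- 1
    repeat {
      cand <- c(lt$u, lt$w, lt$eps) + alpha * step
      ltc <- split_lat(cand)
      fc <- fjoint(ltc)
      if (is.finite(fc) && fc <= f + 1e-12 * abs(f)) { lt <- ltc; f <- fc; break }
      alpha <- alpha / 2
      if (alpha < 1e-10) break
    }
    if (alpha < 1e-10) {
      if (gmax < 1e-4) break
      return(bail(lt))
    }
  }
  if (iter > inner_maxit)
    warning("inner Newton hit the iteration limit before reaching tolerance")

  logdetH <- 0
  if (inc$nugget && n > 0) logdetH <- logdetH + sum(log(dvec))
  if (nx > 0) logdetH <- logdetH + 2 * sum(log(diag(cholH)))
  value <- f + 0.5 * logdetH - 0.5 * m_lat * log(2 * pi)

  if (!is.null(state)) state$mode <- c(lt$u, lt$w, lt$eps)

  out <- list(value = value, mode = lt, f_joint = f, logdetH = logdetH,
              cholH = cholH, theta = theta, iter = iter)

  if ("gradient" %in% want)
    out$gradient <- laplace_gradient(theta, ms, pr, lt, od, cholH, dvec, Qx, nu, nw)
  out
}

## analytic gradient of the Laplace objective; all quantities at the mode
laplace_gradient <- function(theta, ms, pr, lt, od, cholH, dvec, Qx, nu, nw) {
  inc <- ms$include
  C <- ms$C; Y <- ms$Y; n <- ms$n
  nx <- nu + nw
  J <- if (nx > 0) chol2inv(cholH) else NULL
  yofk <- if (inc$field) rep(seq_len(Y), each = C) else integer(0)

  ## q_i = posterior variance of (u_k + w_y); s_i = posterior variance of eta_i
  if (nx > 0 && n > 0) {
    q <- numeric(n)
    if (inc$field) q <- q + J[cbind(ms$kk, ms$kk)]
    if (inc$yeareff) {
      q <- q + J[cbind(nu + ms$yy, nu + ms$yy)]
      if (inc$field) q <- q + 2 * J[cbind(ms$kk, nu + ms$yy)]
    }
  } else q <- numeric(n)
  if (inc$nugget) {
    s <- 1 / dvec + q / (pr$sigma0_sq * dvec)^2
  } else s <- q

  ## G = grad_x of 0.5*logdet H ; h = H^{-1} G (partitioned solve)
  d3s <- od$d3 * s
  G_u <- if (inc$field) 0.5 * scatter_sum(d3s, ms$kk, nu) else numeric(0)
  G_w <- if (inc$yeareff) 0.5 * scatter_sum(d3s, ms$yy, nw) else numeric(0)
  G_e <- if (inc$nugget) 0.5 * d3s else numeric(0)
  solve_H <- function(b_x, b_e) {
    ## solve H [hx; he] = [b_x; b_e] with the same Schur elimination
    if (nx > 0) {
      rhs <- b_x
      if (inc$nugget && n > 0) {
        t1 <- (od$d2 / dvec) * b_e
        if (inc$field) rhs[seq_len(nu)] <- rhs[seq_len(nu)] - scatter_sum(t1, ms$kk, nu)
        if (inc$yeareff) rhs[nu + seq_len(nw)] <- rhs[nu + seq_len(nw)] - scatter_sum(t1, ms$yy, nw)
      }
      hx <- backsolve(cholH, backsolve(cholH, rhs, transpose = TRUE))
    } else hx <- numeric(0)
    he <- if (inc$nugget) {
      sum_x <- numeric(n)
      if (inc$field) sum_x <- sum_x + hx[seq_len(nu)][ms$kk]
      if (inc$yeareff) sum_x <- sum_x + hx[nu + seq_len(nw)][ms$yy]
      (b_e - od$d2 * sum_x) / dvec
    } else numeric(0)
    list(x = hx, e = he)
  }
  h <- solve_H(c(G_u, G_w), G_e)

  gr <- stats::setNames(numeric(length(theta)), names(theta))

  ## fixed effects
  for (j in colnames(ms$X)) {
    xj <- ms$X[, j]
    expl <- sum(od$d1 * xj) + 0.5 * sum(od$d3 * xj * s)
    c_u <- if (inc$field) scatter_sum(od$d2 * xj, ms$kk, nu) else numeric(0)
    c_w <- if (inc$yeareff) scatter_sum(od$d2 * xj, ms$yy, nw) else numeric(0)
    c_e <- if (inc$nugget) od$d2 * xj else numeric(0)
    gr[j] <- expl - (sum(h$x * c(c_u, c_w)) + sum(h$e * c_e))
  }

  U <- if (inc$field) matrix(lt$u, C, Y) else NULL

  if (inc$nugget) {
    diagHee <- 1 / dvec + (od$d2 / dvec)^2 * q
    expl <- -0.5 * sum(lt$eps^2) / pr$sigma0_sq + 0.5 * n -
      0.5 * sum(diagHee) / pr$sigma0_sq
    c_e <- -lt$eps / pr$sigma0_sq
    gr["tau0"] <- expl - sum(h$e * c_e)
  }

  BSinv <- NULL   # block contractions of Ju, shared with the lb term below
  if (inc$field) {
    GS <- pr$Sinv %*% pr$Sa %*% pr$Sinv
    ## trace terms: sum(Ju * (A (x) W)) = sum_{y,y'} A[y,y'] * BW[y,y'] with
    ## BW[y,y'] the contraction of the (y,y') C x C block of Ju against W;
    ## both needed contractions come from one reshape and one crossprod,
    ## avoiding the construction of any nu x nu Kronecker product
    Ju <- if (nw > 0) J[seq_len(nu), seq_len(nu), drop = FALSE] else J
    JuM <- matrix(aperm(array(Ju, c(C, Y, C, Y)), c(1, 3, 2, 4)), C * C, Y * Y)
    BS <- crossprod(cbind(as.vector(pr$Sinv), as.vector(GS)), JuM)
    BSinv <- matrix(BS[1, ], Y, Y)
    BGS <- matrix(BS[2, ], Y, Y)
    Qu_u <- as.vector(pr$Sinv %*% U %*% pr$Tinv) / pr$sigma_sq
    ## tau = log sigma^2
    expl <- -0.5 * sum(lt$u * Qu_u) + 0.5 * nu -
      0.5 * sum(pr$Tinv * BSinv) / pr$sigma_sq
    gr["tau"] <- expl - sum(h$x[seq_len(nu)] * (-Qu_u))
    ## la = log alpha
    dQu_u <- -as.vector(GS %*% U %*% pr$Tinv) / pr$sigma_sq
    expl <- 0.5 * sum(lt$u * dQu_u) + 0.5 * Y * sum(pr$Sinv * pr$Sa) -
      0.5 * sum(pr$Tinv * BGS) / pr$sigma_sq
    gr["la"] <- expl - sum(h$x[seq_len(nu)] * dQu_u)
  }

  if (inc$yeareff) {
    Jw <- J[nu + seq_len(nw), nu + seq_len(nw), drop = FALSE]
    Qw_w <- as.vector(pr$Tinv %*% lt$w) / pr$sigma_y_sq
    expl <- -0.5 * sum(lt$w * Qw_w) + 0.5 * Y -
      0.5 * sum(Jw * pr$Tinv) / pr$sigma_y_sq
    gr["tauy"] <- expl - sum(h$x[nu + seq_len(nw)] * (-Qw_w))
  }

  if (inc$field || inc$yeareff) {
    GT <- pr$Tinv %*% pr$Tb %*% pr$Tinv
    glb <- 0
    c_x <- numeric(nx)
    if (inc$field) {
      dQu_u <- -as.vector(pr$Sinv %*% U %*% GT) / pr$sigma_sq
      glb <- glb + 0.5 * sum(lt$u * dQu_u) + 0.5 * C * sum(pr$Tinv * pr$Tb) -
        0.5 * sum(GT * BSinv) / pr$sigma_sq
      c_x[seq_len(nu)] <- dQu_u
    }
    if (inc$yeareff) {
      Jw <- J[nu + seq_len(nw), nu + seq_len(nw), drop = FALSE]
      dQw_w <- -as.vector(GT %*% lt$w) / pr$sigma_y_sq   # (dQw/dlb) w
      glb <- glb + 0.5 * sum(lt$w * dQw_w) + 0.5 * sum(pr$Tinv * pr$Tb) -
        0.5 * sum(Jw * GT) / pr$sigma_y_sq
      c_x[nu + seq_len(nw)] <- dQw_w
    }
    gr["lb"] <- glb - sum(h$x * c_x)
  }
  gr
}
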