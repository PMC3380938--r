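# Synthetic CPR-like survey generator: latent fields, thermocline covariate
# fields, and designed sample tables, all reproducible from a single seed.

#' Configuration of the synthetic survey generator
#'
#' Bundles everything the generator needs.  The default truth parameters are
#' the package's reference North Sea parameter set ([lgcp_params()]), so
#' simulated surveys have realistic overdispersion, spatial patchiness and
#' seasonality.
#'
#' @param grid A [grid_spec()].
#' @param years Integer vector of survey years.
#' @param samples_per_year Number of silk-band samples per year.
#' @param params Truth parameters, an [lgcp_params()].
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   output exactly.
#' @param design Sampling design: `"transect"` places samples along straight
#'   ship tracks with 10-nautical-mile spacing, mimicking CPR tow
#'   segmentation; `"uniform"` scatters samples uniformly over the domain.
#' @param thermocline Settings list for [simulate_thermocline()].
#' @param shift Optional `list(year = y0, size = s)`: adds `s` to the mean
#'   log year level for all years `>= y0` (a step change in abundance, used
#'   by the period-shift power studies).
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid = grid_spec(), years = 1986:2005,
                       samples_per_year = 150, params = lgcp_params(),
                       seed = 1, design = c("transect", "uniform"),
                       thermocline = list(), shift = NULL) {
  structure(list(grid = grid, years = years,
                 samples_per_year = samples_per_year, params = params,
                 seed = seed, design = match.arg(design),
                 thermocline = thermocline, shift = shift),
            class = "sim_config")
}

## chol with a diagnostic for indefinite covariance
chol_or_explain <- function(M, what) {
  tryCatch(chol(M), error = function(e) {
    ev <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf("%s covariance is not positive definite (smallest eigenvalue %.3g)",
                 what, ev), call. = FALSE)
  })
}

## internal: draw one latent state at given truth
simulate_latent_state <- function(params, grid, years, n_samples, seed,
                                  jitter = 1e-8) {
  check(params$sigma_sq >= 0 && params$sigma_y_sq >= 0 && params$sigma0_sq >= 0,
        "variances must be non-negative")
  C <- grid$ncell; Y <- length(years)
  Dx <- centroid_distances_km(grid)
  Dt <- abs(outer(years, years, "-"))
  S <- exp(-exp(params$log_alpha) * Dx) + jitter * diag(C)
  T_ <- exp(-exp(params$log_beta) * Dt) + jitter * diag(Y)
  LS <- t(chol_or_explain(S, "spatial"))
  LT <- t(chol_or_explain(T_, "temporal"))
  with_seed(seed, {
    u <- sqrt(params$sigma_sq) * (LS %*% matrix(stats::rnorm(C * Y), C, Y) %*% t(LT))
    w <- as.vector(sqrt(params$sigma_y_sq) * (LT %*% stats::rnorm(Y)))
    eps <- stats::rnorm(n_samples, sd = sqrt(params$sigma0_sq))
    structure(list(u = u, w = w, eps = eps, grid = grid, years = years),
              class = "lgcp_latent")
  })
}

#' Draw the latent Gaussian components of the survey model
#'
#' Simulates (i) the space-time field over cells and years with separable
#' exponential covariance, (ii) the random year levels, and (iii) the
#' per-sample nuggets, all mean-zero Gaussian at the truth parameters of the
#' configuration.
#'
#' @param config A [sim_config()].
#' @return An `lgcp_latent` list: `u` (cell x year matrix), `w` (per year),
#'   `eps` (per sample), plus the grid and years.
#' @export
simulate_latent <- function(config) {
  n <- config$samples_per_year * length(config$years)
  simulate_latent_state(config$params, config$grid, config$years, n,
                        split_seed(config$seed, 3)[1])
}

## sample positions along straight ship tracks, 10 nautical miles apart
transect_positions <- function(grid, n_needed) {
  spacing_km <- 10 * 1.852
  lat_rng <- c(grid$lat0, grid$lat0 + grid$nlat * grid$dlat)
  lon_rng <- c(grid$lon0, grid$lon0 + grid$nlon * grid$dlon)
  eps <- 1e-6
  pts <- NULL
  while (is.null(pts) || nrow(pts) < n_needed) {
    ## endpoints on two distinct random edges of the domain box
    edge_pt <- function(e) switch(e,
      cbind(stats::runif(1, lon_rng[1], lon_rng[2] - eps), lat_rng[1]),          # S
      cbind(stats::runif(1, lon_rng[1], lon_rng[2] - eps), lat_rng[2] - eps),    # N
      cbind(lon_rng[1], stats::runif(1, lat_rng[1], lat_rng[2] - eps)),          # W
      cbind(lon_rng[2] - eps, stats::runif(1, lat_rng[1], lat_rng[2] - eps)))    # E
    ed <- sample(4, 2)
    p1 <- edge_pt(ed[1]); p2 <- edge_pt(ed[2])
    d_km <- haversine_km(p1[2], p1[1], p2[2], p2[1])
    np <- floor(d_km / spacing_km)
    if (np < 2) next
    seg <- geosphere::gcIntermediate(p1, p2, n = np, addStartEnd = TRUE)
    new <- cbind(lon = seg[, 1], lat = seg[, 2], track = if (is.null(pts)) 1 else max(pts[, 3]) + 1)
    pts <- rbind(pts, new)
  }
  pts[seq_len(n_needed), , drop = FALSE]
}

#' Generate a survey sample table from a latent state
#'
#' Places samples according to the design, assembles the log-intensity from
#' the truth parameters and latent state, and draws Poisson counts.
#'
#' @param latent An `lgcp_latent` from [simulate_latent()].
#' @param config The same [sim_config()].
#' @param thermocline Optional [covariate_field()]; when supplied, samples
#'   get a `thermocline_depth_m` value and the catchability effect enters the
#'   intensity.
#' @return A sample data frame with the drawn `count` column.
#' @export
simulate_survey <- function(latent, config, thermocline = NULL) {
  grid <- config$grid; years <- config$years
  npy <- config$samples_per_year
  n <- npy * length(years)
  seeds <- split_seed(config$seed, 3)
  smp <- with_seed(seeds[2], {
    if (config$design == "uniform") {
      lat <- stats::runif(n, grid$lat0, grid$lat0 + grid$nlat * grid$dlat - 1e-9)
      lon <- stats::runif(n, grid$lon0, grid$lon0 + grid$nlon * grid$dlon - 1e-9)
    } else {
      pos <- transect_positions(grid, n)
      ## great-circle tracks can bow marginally outside the box; clamp
      lat <- pmin(pmax(pos[, "lat"], grid$lat0),
                  grid$lat0 + grid$nlat * grid$dlat - 1e-9)
      lon <- pmin(pmax(pos[, "lon"], grid$lon0),
                  grid$lon0 + grid$nlon * grid$dlon - 1e-9)
    }
    ## routes are re-run throughout the year, so sampling dates cover the
    ## seasonal cycle independently of position
    day <- sample(365, n, replace = TRUE)
    hour <- sample(0:23, n, replace = TRUE)
    data.frame(sample_id = sprintf("S%06d", seq_len(n)),
               lat = lat, lon = lon,
               year = rep(years, each = npy),
               day_of_year = day, hour = hour, count = 0L)
  })
  smp <- assign_cells(smp, grid)
  if (!is.null(thermocline)) smp <- attach_thermocline(smp, thermocline)
  params <- config$params
  if (!is.null(config$shift)) {
    sh <- numeric(length(years))
    sh[years >= config$shift$year] <- config$shift$size
    latent$w <- latent$w + sh
  }
  if (!is.null(smp$thermocline_depth_m) && anyNA(smp$thermocline_depth_m))
    smp$thermocline_depth_m[is.na(smp$thermocline_depth_m)] <- 60
  eta <- linear_predictor(params, latent, smp)
  if (max(eta) > 30)
    stop(sprintf("log-intensity exceeds 30 for %d sample(s); rescale the intercept or variances",
                 sum(eta > 30)), call. = FALSE)
  smp$count <- with_seed(seeds[3], stats::rpois(n, exp(eta)))
  smp
}

#' Simulate a smooth monthly thermocline-depth field
#'
#' A deterministic seasonal sinusoid (shallow summer thermocline) plus a
#' south-north spatial gradient, plus optional smooth random interannual
#' noise, clamped to 5-80 m.  A random fraction of nodes can be masked to
#' emulate fully mixed water columns with no defined thermocline.
#'
#' @param grid A [grid_spec()] whose domain the node grid covers.
#' @param years Years to cover (all 12 months of each).
#' @param settings List: `dlat`, `dlon` node spacing (default 0.5 degree),
#'   `mean_m` (35), `seasonal_amp_m` (20), `gradient_m_per_deg` (1),
#'   `noise_sd_m` (3), `mask_frac` (0).
#' @param seed Integer seed.
#' @return A [covariate_field()] of monthly thermocline depths in metres.
#' @export
simulate_thermocline <- function(grid, years, settings = list(), seed = 1) {
  s <- modifyList(list(dlat = 0.5, dlon = 0.5, mean_m = 35,
                       seasonal_amp_m = 20, gradient_m_per_deg = 1,
                       noise_sd_m = 3, mask_frac = 0), settings)
  lat <- seq(grid$lat0, grid$lat0 + grid$nlat * grid$dlat, by = s$dlat)
  lon <- seq(grid$lon0, grid$lon0 + grid$nlon * grid$dlon, by = s$dlon)
  time <- expand.grid(month = 1:12, year = years)[, c("year", "month")]
  nt <- nrow(time)
  seas <- s$mean_m + s$seasonal_amp_m * cos(2 * pi * (time$month - 1) / 12)
  ## deterministic part: seasonal cycle + linear south-north gradient
  det <- outer(seas, s$gradient_m_per_deg * (lat - mean(lat)), "+")
  vals <- array(rep(det, length(lon)), c(nt, length(lat), length(lon)))
  with_seed(seed, {
    if (s$noise_sd_m > 0) {
      ## smooth noise: one low-frequency spatial mode per year
      for (y in unique(time$year)) {
        it <- which(time$year == y)
        a <- stats::rnorm(3, sd = s$noise_sd_m)
        mode <- outer(sin(pi * (lat - min(lat)) / diff(range(lat))),
                      cos(pi * (lon - min(lon)) / max(1e-9, diff(range(lon)))))
        vals[it, , ] <- sweep(vals[it, , , drop = FALSE], c(2, 3),
                              a[1] * mode, "+")
      }
    }
    vals <- pmax(pmin(vals, 80), 5)   # vals first so the dim attribute survives
    if (s$mask_frac > 0) {
      nmask <- round(s$mask_frac * length(lat) * length(lon))
      idx <- sample(length(lat) * length(lon), nmask)
      for (ij in idx) {
        i <- (ij - 1) %% length(lat) + 1
        j <- (ij - 1) %/% length(lat) + 1
        vals[, i, j] <- NA
      }
    }
    covariate_field("thermocline_depth_m", lat, lon, time, vals)
  })
}

#' Run the full synthetic survey pipeline
#'
#' Latent draw, thermocline field, designed sample table with Poisson counts.
#'
#' @param config A [sim_config()].
#' @return A list with `samples`, `latent`, `thermocline`, and `truth`
#'   (the parameters used).
#' @export
simulate_cpr <- function(config) {
  latent <- simulate_latent(config)
  thc <- simulate_thermocline(config$grid, config$years, config$thermocline,
                              seed = split_seed(config$seed, 4)[4])
  samples <- simulate_survey(latent, config, thermocline = thc)
  list(samples = samples, latent = latent, thermocline = thc,
       truth = config$params)
}
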