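# Lagrangian particle back-tracking through gridded velocity fields and
# displacement statistics.

#' Days between spawning and capture
#'
#' Time elapsed from spawning to capture at typical larval size: the egg
#' phase plus the larval growth from hatch length to capture length at the
#' given growth rate.  The default values (hatch 3 mm, capture 4.8 mm at
#' 0.75 mm/day, 50 percent egg hatch after 6.7 days at 11 C) give 9.1 days
#' raw; the back-tracking duration uses the value rounded up to whole days
#' (10).
#'
#' @param hatch_mm Typical hatch length (mm).
#' @param capture_mm Typical length at capture (mm).
#' @param growth_mm_per_day Larval growth rate (mm/day).
#' @param egg_days Egg-phase duration (days).
#' @return List with `larval_days`, `raw_days`, and `duration_days`
#'   (`raw_days` rounded up to a whole day).
#' @export
spawn_to_capture_days <- function(hatch_mm = 3, capture_mm = 4.8,
                                  growth_mm_per_day = 0.75, egg_days = 6.7) {
  check(capture_mm >= hatch_mm, "capture length smaller than hatch length")
  check(growth_mm_per_day > 0, "growth rate must be positive")
  larval <- (capture_mm - hatch_mm) / growth_mm_per_day
  raw <- egg_days + larval
  list(larval_days = larval, raw_days = raw, duration_days = ceiling(raw))
}

## one RK4 step of duration dt seconds for positions (lat, lon) in degrees;
## `sgn` = -1 for backward advection
rk4_step <- function(field, lat, lon, dt, sgn) {
  R <- .EARTH_RADIUS_KM * 1000
  deriv <- function(la, lo) {
    vv <- velocity_at(field, la, lo)
    list(dlat = sgn * vv$v / R * 180 / pi,
         dlon = sgn * vv$u / (R * cos(la * pi / 180)) * 180 / pi)
  }
  k1 <- deriv(lat, lon)
  k2 <- deriv(lat + dt / 2 * k1$dlat, lon + dt / 2 * k1$dlon)
  k3 <- deriv(lat + dt / 2 * k2$dlat, lon + dt / 2 * k2$dlon)
  k4 <- deriv(lat + dt * k3$dlat, lon + dt * k3$dlon)
  list(lat = lat + dt / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat),
       lon = lon + dt / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon))
}

#' Back-track passive particles from capture points
#'
#' For each observation, releases `n_particles` passive particles at the
#' capture position and integrates them backward in time through the
#' velocity field for `duration_days`, using a fixed-step 4th-order
#' Runge-Kutta scheme (default step 1 hour) with bilinear velocity
#' interpolation.  Optional random-walk mixing (horizontal diffusivity
#' `mixing` m^2/s, seeded) emulates unresolved turbulence; it is off by
#' default so that the deterministic analytic checks hold exactly.  No
#' active behaviour is applied.  Particles leaving the field domain are
#' clamped at the boundary and flagged.
#'
#' @param observations Data frame with `lat`, `lon` (capture positions);
#'   extra columns are carried into the result.
#' @param field A [make_velocity_field()] (or one read from file).
#' @param duration_days Advection duration (default 10 days).
#' @param n_particles Particles per observation (default 100).
#' @param step_hours Integration step (default 1).
#' @param seed Seed for the random-walk mixing.
#' @param mixing Horizontal diffusivity in m^2/s (default 0 = off).
#' @param direction `"backward"` (default) or `"forward"` in time.
#' @return A `trajectory_set`: the release table plus `end_lat`, `end_lon`
#'   (`n_obs x n_particles` matrices), the configuration, and an `edge`
#'   flag matrix for particles that hit the domain boundary.
#' @export
backtrack <- function(observations, field, duration_days = 10,
                      n_particles = 100, step_hours = 1, seed = 1,
                      mixing = 0, direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  check(nrow(observations) > 0, "no observations to back-track")
  inside <- observations$lat >= min(field$lat) & observations$lat <= max(field$lat) &
    observations$lon >= min(field$lon) & observations$lon <= max(field$lon)
  if (any(!inside)) {
    warning(sprintf("%d observation(s) outside the velocity field domain were skipped",
                    sum(!inside)))
    observations <- observations[inside, , drop = FALSE]
    check(nrow(observations) > 0, "all observations outside the field domain")
  }
  nobs <- nrow(observations)
  lat <- matrix(rep(observations$lat, n_particles), nobs, n_particles)
  lon <- matrix(rep(observations$lon, n_particles), nobs, n_particles)
  edge <- matrix(FALSE, nobs, n_particles)
  dt <- step_hours * 3600
  nstep <- ceiling(duration_days * 86400 / dt)
  sgn <- if (direction == "backward") -1 else 1
  R <- .EARTH_RADIUS_KM * 1000
  latr <- range(field$lat); lonr <- range(field$lon)
  with_seed(seed, {
    for (s in seq_len(nstep)) {
      st <- rk4_step(field, as.vector(lat), as.vector(lon), dt, sgn)
      la <- st$lat; lo <- st$lon
      if (mixing > 0) {
        sd_m <- sqrt(2 * mixing * dt)
        la <- la + stats::rnorm(length(la), sd = sd_m) / R * 180 / pi
        lo <- lo + stats::rnorm(length(lo), sd = sd_m) /
          (R * cos(la * pi / 180)) * 180 / pi
      }
      out <- la < latr[1] | la > latr[2] | lo < lonr[1] | lo > lonr[2]
      edge <- edge | matrix(out, nobs, n_particles)
      lat <- matrix(pmin(pmax(la, latr[1]), latr[2]), nobs, n_particles)
      lon <- matrix(pmin(pmax(lo, lonr[1]), lonr[2]), nobs, n_particles)
    }
  })
  structure(list(release = observations, end_lat = lat, end_lon = lon,
                 duration_days = duration_days, n_particles = n_particles,
                 step_hours = step_hours, mixing = mixing,
                 direction = direction, edge = edge),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("trajectory_set: %d observation(s) x %d particles, %g day(s) %s\n",
              nrow(x$release), x$n_particles, x$duration_days, x$direction))
  invisible(x)
}

#' Displacement statistics of back-tracked particles
#'
#' Great-circle displacement between each particle end point and its capture
#' point; the per-observation median displacement is pooled across
#' observations into an empirical cumulative distribution, from which the
#' requested quantiles are read.  Quantiles use linear interpolation of the
#' empirical distribution function (`type = 4`), so for pooled medians
#' 10, 20, ..., 100 km the 0.90 quantile is exactly 90 km.
#'
#' @param traj A `trajectory_set` from [backtrack()].
#' @param quantiles Quantile levels to report (default 0.75 and 0.90,
#'   the customary drift summaries).
#' @return A `displacement_summary`: `per_obs_median` (km), `pooled`
#'   (identical, pooled across observations), `ecdf`, `quantiles_km`.
#' @export
displacement_summary <- function(traj, quantiles = c(0.75, 0.90)) {
  check(nrow(traj$release) > 0, "empty trajectory set")
  disp <- matrix(haversine_km(rep(traj$release$lat, traj$n_particles),
                              rep(traj$release$lon, traj$n_particles),
                              as.vector(traj$end_lat), as.vector(traj$end_lon)),
                 nrow(traj$release), traj$n_particles)
  med <- apply(disp, 1, stats::median)
  qs <- stats::quantile(med, probs = quantiles, type = 4, names = FALSE)
  structure(list(per_obs_median = med, pooled = med,
                 ecdf = stats::ecdf(med),
                 quantiles_km = stats::setNames(qs, paste0("q", quantiles * 100)),
                 n_obs = length(med)),
            class = "displacement_summary")
}

#' @export
print.displacement_summary <- function(x, ...) {
  cat(sprintf("displacement_summary: %d observation(s), median of medians %.1f km\n",
              x$n_obs, stats::median(x$per_obs_median)))
  for (i in seq_along(x$quantiles_km))
    cat(sprintf("  %s: %.1f km\n", names(x$quantiles_km)[i], x$quantiles_km[i]))
  invisible(x)
}

#' Histogram and ECDF of pooled displacements
#' @param x A `displacement_summary`.
#' @param bin_km Histogram bin width in km.
#' @param ... Unused.
#' @export
plot.displacement_summary <- function(x, bin_km = 10, ...) {
  old <- graphics::par(mar = c(5, 4, 4, 4) + 0.1)
  on.exit(graphics::par(old))
  brk <- seq(0, max(x$pooled) + bin_km, by = bin_km)
  h <- graphics::hist(x$pooled, breaks = brk, col = "grey80",
                      xlab = "displacement (km)", main = "Particle displacement")
  xx <- sort(x$pooled)
  graphics::par(new = TRUE)
  graphics::plot(xx, x$ecdf(xx), type = "s", axes = FALSE, xlab = "", ylab = "",
                 ylim = c(0, 1), xlim = range(h$breaks), lwd = 2)
  graphics::axis(4); graphics::mtext("ECDF", side = 4, line = 2)
  invisible(x)
}
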