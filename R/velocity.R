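# Gridded velocity fields for particle tracking, with analytic generators.

#' Construct an analytic velocity field sampled on a regular grid
#'
#' Test and demonstration currents for the drift analysis, sampled on a
#' regular lat/lon node grid and interpolated bilinearly at particle
#' positions:
#' \describe{
#'   \item{still}{zero velocity everywhere}
#'   \item{uniform}{constant `(u, v)` m/s}
#'   \item{solid_rotation}{rigid-body rotation with angular velocity `omega`
#'     (rad/s) about `center = c(lat, lon)`; speed at distance r is omega*r}
#'   \item{gyre}{a single closed circulation cell filling the domain, with
#'     maximum speed `speed` m/s}
#' }
#'
#' @param kind One of `"still"`, `"uniform"`, `"solid_rotation"`, `"gyre"`.
#' @param lat,lon Strictly increasing node coordinate vectors (degrees).
#' @param params List of parameters for the chosen kind (see above).
#' @return A `velocity_field`: node grid plus `u`, `v` matrices (m/s,
#'   dimension `nlat x nlon`).
#' @export
make_velocity_field <- function(kind = c("still", "uniform", "solid_rotation", "gyre"),
                                lat, lon, params = list()) {
  kind <- match.arg(kind)
  check(all(diff(lat) > 0) && all(diff(lon) > 0),
        "node coordinates must be strictly increasing")
  R <- .EARTH_RADIUS_KM * 1000
  LAT <- matrix(lat, length(lat), length(lon))
  LON <- matrix(lon, length(lat), length(lon), byrow = TRUE)
  uv <- switch(kind,
    still = list(u = LAT * 0, v = LAT * 0),
    uniform = {
      p <- modifyList(list(u = 0.1, v = 0), params)
      list(u = LAT * 0 + p$u, v = LAT * 0 + p$v)
    },
    solid_rotation = {
      p <- modifyList(list(center = c(mean(lat), mean(lon)), omega = 2 * pi / (10 * 86400)),
                      params)
      x <- R * cos(p$center[1] * pi / 180) * (LON - p$center[2]) * pi / 180
      y <- R * (LAT - p$center[1]) * pi / 180
      list(u = -p$omega * y, v = p$omega * x)
    },
    gyre = {
      p <- modifyList(list(speed = 0.1), params)
      X <- (LON - min(lon)) / max(1e-9, diff(range(lon)))
      Y <- (LAT - min(lat)) / max(1e-9, diff(range(lat)))
      list(u = -p$speed * sin(pi * X) * cos(pi * Y),
           v = p$speed * cos(pi * X) * sin(pi * Y))
    })
  structure(list(kind = kind, lat = lat, lon = lon, u = uv$u, v = uv$v,
                 params = params), class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field '%s': %d x %d nodes, max speed %.3f m/s\n",
              x$kind, length(x$lat), length(x$lon),
              max(sqrt(x$u^2 + x$v^2))))
  invisible(x)
}

#' Write a velocity field as long-format CSV
#' @param field A `velocity_field`.
#' @param path Output path.
#' @export
write_velocity_field <- function(field, path) {
  d <- expand.grid(ilat = seq_along(field$lat), ilon = seq_along(field$lon))
  utils::write.csv(data.frame(lat = field$lat[d$ilat], lon = field$lon[d$ilon],
                              u = field$u[cbind(d$ilat, d$ilon)],
                              v = field$v[cbind(d$ilat, d$ilon)]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a velocity field written by [write_velocity_field()]
#' @param path CSV path.
#' @export
read_velocity_field <- function(path) {
  d <- utils::read.csv(path)
  lat <- sort(unique(d$lat)); lon <- sort(unique(d$lon))
  u <- v <- matrix(NA_real_, length(lat), length(lon))
  i <- cbind(match(d$lat, lat), match(d$lon, lon))
  u[i] <- d$u; v[i] <- d$v
  structure(list(kind = "gridded", lat = lat, lon = lon, u = u, v = v,
                 params = list()), class = "velocity_field")
}

## bilinear interpolation of (u, v) at positions; positions outside the node
## hull are clamped to it and flagged
velocity_at <- function(field, lat, lon) {
  clamp <- function(x, r) pmin(pmax(x, r[1]), r[2])
  outside <- lat < min(field$lat) | lat > max(field$lat) |
    lon < min(field$lon) | lon > max(field$lon)
  la <- clamp(lat, range(field$lat)); lo <- clamp(lon, range(field$lon))
  fi <- stats::approx(field$lat, seq_along(field$lat), xout = la, rule = 2)$y
  fj <- stats::approx(field$lon, seq_along(field$lon), xout = lo, rule = 2)$y
  i0 <- pmin(floor(fi), length(field$lat) - 1); wi <- fi - i0
  j0 <- pmin(floor(fj), length(field$lon) - 1); wj <- fj - j0
  if (length(field$lat) == 1) { i0 <- rep(1, length(fi)); wi <- 0 }
  if (length(field$lon) == 1) { j0 <- rep(1, length(fj)); wj <- 0 }
  bil <- function(M) {
    i1 <- pmin(i0 + 1, length(field$lat)); j1 <- pmin(j0 + 1, length(field$lon))
    (1 - wi) * (1 - wj) * M[cbind(i0, j0)] + wi * (1 - wj) * M[cbind(i1, j0)] +
      (1 - wi) * wj * M[cbind(i0, j1)] + wi * wj * M[cbind(i1, j1)]
  }
  list(u = bil(field$u), v = bil(field$v), outside = outside)
}
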