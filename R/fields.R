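# Gridded monthly covariate fields (thermocline depth) on a regular
# lat/lon node grid, with plain-text (long CSV) serialization.

#' Construct a gridded monthly covariate field
#'
#' @param variable Name of the variable (e.g. `"thermocline_depth_m"`).
#' @param lat,lon Strictly increasing vectors of node coordinates (degrees).
#' @param time Data frame with integer columns `year` and `month`, strictly
#'   increasing in calendar order.
#' @param values Numeric array of dim `(ntime, nlat, nlon)`.  `NA` marks
#'   masked nodes (e.g. a fully mixed column with no defined thermocline).
#' @return An object of class `covariate_field`.
#' @export
covariate_field <- function(variable, lat, lon, time, values) {
  check(all(diff(lat) > 0) && all(diff(lon) > 0), "node coordinates must be strictly increasing")
  check(all(c("year", "month") %in% names(time)), "time needs year and month columns")
  tcode <- time$year * 12 + time$month
  check(all(diff(tcode) > 0), "time axis must be strictly increasing")
  check(length(dim(values)) == 3 &&
          all(dim(values) == c(nrow(time), length(lat), length(lon))),
        "values must have dim (ntime, nlat, nlon)")
  structure(list(variable = variable, lat = lat, lon = lon,
                 time = time, values = values),
            class = "covariate_field")
}

#' @export
print.covariate_field <- function(x, ...) {
  cat(sprintf("covariate_field '%s': %d x %d nodes, %d month(s), %.1f%% masked\n",
              x$variable, length(x$lat), length(x$lon), nrow(x$time),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Look up field values at point locations
#'
#' Nearest grid node in space, exact calendar month in time.  Returns `NA`
#' for masked nodes.
#'
#' @param field A [covariate_field()].
#' @param lat,lon,year,month Vectors of equal length (recycled as usual).
#' @return Numeric vector of field values.
#' @export
field_lookup <- function(field, lat, lon, year, month) {
  n <- max(length(lat), length(lon), length(year), length(month))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  year <- rep_len(year, n); month <- rep_len(month, n)
  ilat <- pmax(1, pmin(length(field$lat),
                       round(stats::approx(field$lat, seq_along(field$lat),
                                           xout = lat, rule = 2)$y)))
  ilon <- pmax(1, pmin(length(field$lon),
                       round(stats::approx(field$lon, seq_along(field$lon),
                                           xout = lon, rule = 2)$y)))
  it <- match(year * 12 + month, field$time$year * 12 + field$time$month)
  if (anyNA(it))
    stop("field does not cover requested year/month(s): ",
         paste(unique(paste(year, month, sep = "-")[is.na(it)]), collapse = ", "),
         call. = FALSE)
  field$values[cbind(it, ilat, ilon)]
}

#' Write a covariate field as long-format CSV
#'
#' One row per (year, month, lat, lon) node with the value (`NA` for masked
#' nodes); the regular grid is reconstructed on reading.
#'
#' @param field A [covariate_field()].
#' @param path Output path.
#' @export
write_field <- function(field, path) {
  d <- expand.grid(lat = field$lat, lon = field$lon, it = seq_len(nrow(field$time)))
  out <- data.frame(variable = field$variable,
                    year = field$time$year[d$it], month = field$time$month[d$it],
                    lat = d$lat, lon = d$lon,
                    value = field$values[cbind(d$it, match(d$lat, field$lat),
                                               match(d$lon, field$lon))])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a covariate field written by [write_field()]
#'
#' @param path CSV path.
#' @return A [covariate_field()].
#' @export
read_field <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lat <- sort(unique(d$lat)); lon <- sort(unique(d$lon))
  tcode <- sort(unique(d$year * 12 + d$month))
  ## invert tcode = year*12 + month with month in 1..12
  time <- data.frame(year = ifelse(tcode %% 12 == 0, tcode %/% 12 - 1, tcode %/% 12),
                     month = ifelse(tcode %% 12 == 0, 12, tcode %% 12))
  vals <- array(NA_real_, c(length(tcode), length(lat), length(lon)))
  vals[cbind(match(d$year * 12 + d$month, tcode),
             match(d$lat, lat), match(d$lon, lon))] <- d$value
  covariate_field(d$variable[1], lat, lon, time, vals)
}
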