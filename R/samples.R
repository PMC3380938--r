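# Sample-table I/O and validation.
#
# A sample table is a plain data.frame with one row per silk-band sample:
#   sample_id, lat, lon, year, day_of_year, hour, count
# and optionally thermocline_depth_m and cell_id.

.SAMPLE_COLS <- c("sample_id", "lat", "lon", "year", "day_of_year", "hour", "count")

#' Validate a sample table
#'
#' Checks the per-row invariants of the sampling scheme: integer non-negative
#' counts, day-of-year in 1..366, hour in 0..23, and positions inside the
#' configured domain bounds.  Invalid rows are rejected and reported.
#'
#' @param samples Data frame with at least the mandatory columns
#'   `sample_id, lat, lon, year, day_of_year, hour, count`.
#' @param bounds Named list with `lat` and `lon` ranges (each length 2), or
#'   `NULL` to skip the domain check.  The default is the North Sea study
#'   domain, 51-61 degrees N by 3.5 W - 9.5 E.
#' @param on_invalid One of `"drop"` (reject bad rows with a warning,
#'   default), `"error"`, or `"keep"`.
#' @return The validated table, with an attribute `"rejected"` holding a data
#'   frame of rejected rows and the reason for each.
#' @export
validate_samples <- function(samples,
                             bounds = list(lat = c(51, 61), lon = c(-3.5, 9.5)),
                             on_invalid = c("drop", "error", "keep")) {
  on_invalid <- match.arg(on_invalid)
  missing_cols <- setdiff(.SAMPLE_COLS, names(samples))
  if (length(missing_cols))
    stop("sample table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  reason <- rep(NA_character_, nrow(samples))
  flag <- function(bad, why) reason[bad & is.na(reason)] <<- why
  cnt <- samples$count
  flag(!is.finite(cnt) | cnt < 0 | cnt != round(cnt), "count not a non-negative integer")
  flag(!is.finite(samples$day_of_year) | samples$day_of_year < 1 |
         samples$day_of_year > 366, "day_of_year outside 1..366")
  flag(!is.finite(samples$hour) | samples$hour < 0 | samples$hour > 23,
       "hour outside 0..23")
  if (!is.null(bounds)) {
    flag(samples$lat < bounds$lat[1] | samples$lat > bounds$lat[2],
         "latitude outside domain")
    flag(samples$lon < bounds$lon[1] | samples$lon > bounds$lon[2],
         "longitude outside domain")
  }
  bad <- !is.na(reason)
  rejected <- cbind(samples[bad, , drop = FALSE], reason = reason[bad])
  if (any(bad)) {
    msg <- sprintf("%d invalid sample row(s): %s", sum(bad),
                   paste(unique(reason[bad]), collapse = "; "))
    if (on_invalid == "error") stop(msg, call. = FALSE)
    if (on_invalid == "drop") {
      warning(msg)
      samples <- samples[!bad, , drop = FALSE]
    }
  }
  samples$count <- as.integer(round(samples$count))
  attr(samples, "rejected") <- rejected
  samples
}

#' Read a sample table from a delimited text file
#'
#' Expects a header naming at least the mandatory sample columns; extra
#' columns are carried along.  Rows violating the invariants are rejected and
#' reported via [validate_samples()].
#'
#' @param path File path.
#' @param sep Field delimiter (default comma).
#' @param ... Passed on to [validate_samples()] (e.g. `bounds`, `on_invalid`).
#' @return A validated sample data frame.
#' @export
read_samples <- function(path, sep = ",", ...) {
  samples <- utils::read.table(path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE)
  validate_samples(samples, ...)
}

#' Write a sample table to CSV
#'
#' Coordinates are written with enough digits for an exact round trip via
#' [read_samples()] (integers bit-exact, coordinates to better than 1e-9).
#'
#' @param samples Sample data frame.
#' @param path Output file path.
#' @export
write_samples <- function(samples, path) {
  out <- samples
  for (col in names(out))
    if (is.double(out[[col]])) out[[col]] <- format(out[[col]], digits = 15)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach thermocline depth to samples from a gridded monthly field
#'
#' Each sample receives the field value at the spatially nearest grid node in
#' its calendar month (derived from `year` and `day_of_year`).  Samples
#' falling in masked nodes -- a fully mixed water column with no defined
#' thermocline -- get `NA`; how those are treated at fitting time is governed
#' by the `thermocline_policy` of [lgcp_fit()].
#'
#' @param samples Sample data frame.
#' @param field A [covariate_field()] covering the sample domain and period.
#' @return `samples` with a `thermocline_depth_m` column.
#' @export
attach_thermocline <- function(samples, field) {
  month <- 1 + pmin(11, (pmax(1, samples$day_of_year) - 1) %/% 30.44)
  bad_years <- setdiff(unique(samples$year), unique(field$time$year))
  if (length(bad_years))
    stop("covariate field does not cover sample year(s): ",
         paste(sort(bad_years), collapse = ", "), call. = FALSE)
  samples$thermocline_depth_m <- field_lookup(field, samples$lat, samples$lon,
                                              samples$year, month)
  samples
}
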