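make_samples <- function() {
  data.frame(sample_id = c("A", "B", "C", "D"),
             lat = c(55.1, 56.2, 57.3, 58.4),
             lon = c(1.0, 2.0, 3.0, 4.0),
             year = c(1999L, 1999L, 2000L, 2000L),
             day_of_year = c(100L, 200L, 150L, 250L),
             hour = c(0L, 6L, 12L, 23L),
             count = c(0L, 2L, 0L, 5L))
}

test_that("validate_samples accepts a clean table unchanged", {
  s <- make_samples()
  out <- validate_samples(s)
  expect_equal(out$count, s$count)
  expect_equal(nrow(attr(out, "rejected")), 0L)
})

test_that("validate_samples rejects rows violating each invariant with a reason", {
  s <- make_samples()
  s$count[1] <- -1          # negative count
  s$day_of_year[2] <- 400   # impossible day
  s$hour[3] <- 24           # impossible hour
  s$lat[4] <- 40            # outside the domain
  expect_warning(out <- validate_samples(s), "invalid")
  expect_equal(nrow(out), 0L)
  rej <- attr(out, "rejected")
  expect_equal(nrow(rej), 4L)
  expect_match(rej$reason[1], "count")
  expect_match(rej$reason[2], "day_of_year")
  expect_match(rej$reason[3], "hour")
  expect_match(rej$reason[4], "latitude")
  expect_error(validate_samples(s, on_invalid = "error"), "invalid")
  kept <- suppressWarnings(validate_samples(s, on_invalid = "keep"))
  expect_equal(nrow(kept), 4L)
})

test_that("validate_samples requires the mandatory columns", {
  s <- make_samples()
  s$count <- NULL
  expect_error(validate_samples(s), "count")
})

test_that("sample tables round-trip exactly through CSV", {
  s <- make_samples()
  s$lat <- s$lat + 1e-7     # non-trivial decimals
  path <- tempfile(fileext = ".csv")
  write_samples(s, path)
  back <- read_samples(path)
  expect_equal(back$lat, s$lat, tolerance = 1e-12)
  expect_identical(back$count, s$count)
  expect_identical(back$sample_id, s$sample_id)
})

test_that("attach_thermocline looks up the nearest node in the right month", {
  time <- expand.grid(month = 1:12, year = 1999:2000)[, c("year", "month")]
  lat <- c(55, 57); lon <- c(1, 3)
  vals <- array(0, c(24, 2, 2))
  vals[ , 1, 1] <- 10; vals[ , 2, 1] <- 20
  vals[ , 1, 2] <- 30; vals[ , 2, 2] <- 40
  ## make July of 1999 distinctive at node (55, 1)
  vals[7, 1, 1] <- 99
  fld <- covariate_field("thermocline_depth_m", lat, lon, time, vals)
  s <- make_samples()
  ## day 200 of 1999 is in month 7; (56.2, 2.0) is nearest to node (57, 3)
  out <- attach_thermocline(s, fld)
  expect_equal(out$thermocline_depth_m[1], 10)  # (55.1, 1.0), April 1999
  expect_equal(out$thermocline_depth_m[2], 40)  # (56.2, 2.0) -> node (57, 3)
  s2 <- make_samples(); s2$year <- 1997L
  expect_error(attach_thermocline(s2, fld), "1997")
})
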