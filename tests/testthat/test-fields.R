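small_field <- function() {
  time <- expand.grid(month = 1:12, year = 2000:2001)[, c("year", "month")]
  lat <- c(52, 54, 56); lon <- c(0, 2)
  vals <- array(seq_len(24 * 3 * 2) / 10, c(24, 3, 2))
  vals[3, 2, 1] <- NA                       # one masked node
  covariate_field("thermocline_depth_m", lat, lon, time, vals)
}

test_that("covariate_field validates its inputs", {
  f <- small_field()
  expect_s3_class(f, "covariate_field")
  expect_error(covariate_field("x", c(2, 1), c(0, 1), f$time,
                               array(0, c(24, 2, 2))), "increasing")
  expect_error(covariate_field("x", c(52, 54, 56), c(0, 2),
                               data.frame(year = 2000, month = 1),
                               array(0, c(24, 3, 2))), "dim")
})

test_that("field_lookup returns exact node values and NA for masked nodes", {
  f <- small_field()
  ## exact node hit
  expect_equal(field_lookup(f, 54, 2, 2000, 1), f$values[1, 2, 2])
  ## nearest-node rule in space
  expect_equal(field_lookup(f, 52.7, 0.4, 2001, 12), f$values[24, 1, 1])
  ## masked node propagates NA
  expect_true(is.na(field_lookup(f, 54, 0, 2000, 3)))
  expect_error(field_lookup(f, 54, 0, 1995, 1), "1995")
})

test_that("fields round-trip through long CSV including December and NAs", {
  f <- small_field()
  path <- tempfile(fileext = ".csv")
  write_field(f, path)
  back <- read_field(path)
  expect_equal(back$lat, f$lat)
  expect_equal(back$lon, f$lon)
  expect_equal(back$time$year, f$time$year)
  expect_equal(back$time$month, f$time$month)   # month 12 inverts correctly
  expect_equal(back$values, f$values)
  expect_equal(back$variable, f$variable)
})

test_that("simulated thermocline fields are seasonal, bounded, and seeded", {
  g <- grid_spec(nlat = 2, nlon = 2, dlat = 5, dlon = 6.5)
  f1 <- simulate_thermocline(g, 2000:2001, seed = 9)
  f2 <- simulate_thermocline(g, 2000:2001, seed = 9)
  f3 <- simulate_thermocline(g, 2000:2001, seed = 10)
  expect_identical(f1$values, f2$values)
  expect_false(identical(f1$values, f3$values))
  expect_true(all(f1$values >= 5 & f1$values <= 80, na.rm = TRUE))
  ## summer thermocline is shallower than winter on average
  jul <- f1$values[f1$time$month == 7, , ]
  jan <- f1$values[f1$time$month == 1, , ]
  expect_lt(mean(jul), mean(jan))
  ## masking produces NAs
  fm <- simulate_thermocline(g, 2000, settings = list(mask_frac = 0.3), seed = 1)
  expect_gt(mean(is.na(fm$values)), 0)
})
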