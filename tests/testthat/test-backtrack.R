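lat_nodes <- seq(51, 61, by = 0.5)
lon_nodes <- seq(-3.5, 9.5, by = 0.5)

test_that("spawning-to-capture duration follows the growth arithmetic", {
  d <- spawn_to_capture_days()
  expect_equal(d$larval_days, (4.8 - 3) / 0.75)
  expect_equal(d$raw_days, 6.7 + 2.4)
  expect_equal(d$duration_days, 10)
  expect_equal(spawn_to_capture_days(egg_days = 5, capture_mm = 4.5)$raw_days,
               5 + 2)
  expect_error(spawn_to_capture_days(capture_mm = 2), "hatch")
  expect_error(spawn_to_capture_days(growth_mm_per_day = 0), "positive")
})

test_that("a still ocean produces zero displacement", {
  f <- make_velocity_field("still", lat_nodes, lon_nodes)
  obs <- data.frame(lat = c(54.2, 57.9), lon = c(0.3, 6.1))
  tr <- backtrack(obs, f, duration_days = 10, n_particles = 3)
  expect_equal(as.vector(tr$end_lat), rep(obs$lat, 3))
  expect_equal(as.vector(tr$end_lon), rep(obs$lon, 3))
  ds <- displacement_summary(tr)
  expect_equal(ds$per_obs_median, c(0, 0))
})

test_that("a uniform 0.1 m/s current over 10 days moves particles 86.4 km", {
  f <- make_velocity_field("uniform", lat_nodes, lon_nodes,
                           params = list(u = 0.1, v = 0))
  obs <- data.frame(lat = 56, lon = 5)
  tr <- backtrack(obs, f, duration_days = 10, n_particles = 1)
  d <- haversine_km(56, 5, tr$end_lat[1, 1], tr$end_lon[1, 1])
  expect_lt(abs(d - 86.4) / 86.4, 0.005)
  ## backward tracking of an eastward current ends west of the release
  expect_lt(tr$end_lon[1, 1], 5)
  ## forward tracking mirrors it
  fw <- backtrack(obs, f, duration_days = 10, n_particles = 1,
                  direction = "forward")
  expect_gt(fw$end_lon[1, 1], 5)
  expect_equal(haversine_km(56, 5, fw$end_lat[1, 1], fw$end_lon[1, 1]), d,
               tolerance = 1e-6)
})

test_that("solid-body rotation closes its orbit after one period", {
  period_s <- 10 * 86400
  f <- make_velocity_field("solid_rotation", lat_nodes, lon_nodes,
                           params = list(center = c(56, 3),
                                         omega = 2 * pi / period_s))
  obs <- data.frame(lat = 56.3, lon = 3)
  tr <- backtrack(obs, f, duration_days = 10, n_particles = 1)
  radius <- haversine_km(56, 3, 56.3, 3)
  closure <- haversine_km(56.3, 3, tr$end_lat[1, 1], tr$end_lon[1, 1])
  expect_lt(closure, 0.03 * 2 * pi * radius)
  ## half a period puts the particle diametrically opposite
  half <- backtrack(obs, f, duration_days = 5, n_particles = 1)
  d_half <- haversine_km(56.3, 3, half$end_lat[1, 1], half$end_lon[1, 1])
  expect_equal(d_half, 2 * radius, tolerance = 0.05 * 2 * radius)
})

test_that("displacement quantiles follow the sorted-sample oracle", {
  ## fabricate single-particle trajectories whose displacements are exactly
  ## 10, 20, ..., 100 km due north
  d_km <- seq(10, 100, by = 10)
  lat0 <- rep(55, 10); lon0 <- rep(3, 10)
  dlat <- d_km / (6371 * pi / 180)
  tr <- structure(list(release = data.frame(lat = lat0, lon = lon0),
                       end_lat = matrix(lat0 + dlat, 10, 1),
                       end_lon = matrix(lon0, 10, 1),
                       n_particles = 1), class = "trajectory_set")
  ds <- displacement_summary(tr, quantiles = c(0.5, 0.75, 0.9))
  expect_equal(ds$per_obs_median, d_km, tolerance = 1e-9)
  expect_equal(unname(ds$quantiles_km), c(50, 75, 90), tolerance = 1e-9)
})

test_that("random-walk mixing is seeded and spreads the particle cloud", {
  f <- make_velocity_field("still", lat_nodes, lon_nodes)
  obs <- data.frame(lat = 56, lon = 3)
  t1 <- backtrack(obs, f, duration_days = 2, n_particles = 50,
                  mixing = 20, seed = 4)
  t2 <- backtrack(obs, f, duration_days = 2, n_particles = 50,
                  mixing = 20, seed = 4)
  t3 <- backtrack(obs, f, duration_days = 2, n_particles = 50,
                  mixing = 20, seed = 5)
  expect_identical(t1$end_lat, t2$end_lat)
  expect_false(identical(t1$end_lat, t3$end_lat))
  expect_gt(stats::sd(t1$end_lat), 0)
})

test_that("observations outside the field are skipped with a warning", {
  f <- make_velocity_field("still", lat_nodes, lon_nodes)
  obs <- data.frame(lat = c(56, 45), lon = c(3, 3))
  expect_warning(tr <- backtrack(obs, f, duration_days = 1, n_particles = 2),
                 "skipped")
  expect_equal(nrow(tr$release), 1L)
  expect_error(suppressWarnings(backtrack(data.frame(lat = 45, lon = 3), f)),
               "outside")
})
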