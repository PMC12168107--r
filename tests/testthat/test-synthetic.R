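test_that("grid construction, cell lookup and the half-open convention", {
  g <- make_grid(-180, 180, -75, -30, 1)
  expect_equal(g$n_cells, 360 * 45)
  # south-west corner cell is cell 1
  expect_equal(cell_of(g, -179.5, -74.5), 1L)
  # a point exactly on an interior edge belongs to the cell it is the lower
  # edge of
  expect_equal(cell_of(g, -179, -75), cell_of(g, -178.5, -74.5))
  expect_equal(cell_of(g, -179.5, -74), cell_of(g, -179.5, -73.5))
  # outside the extent
  expect_true(is.na(cell_of(g, 0, -20)))
  # longitudes wrap into [-180, 180)
  expect_equal(cell_of(g, 180.5, -74.5), cell_of(g, -179.5, -74.5))
  # non-divisible extents rejected
  expect_error(make_grid(-180, 180, -75, -30.5, 1), "multiple")
  expect_error(make_grid(0, 1, -75, -30, 1), "2 cells")
})

test_that("temperature field is poleward-cold, seeded, and invertible", {
  g <- make_grid(-180, 180, -75, -30, 1)
  mask <- rep(TRUE, g$n_cells)
  f <- make_temperature_field(g, mask, noise_sd = 0, zonal_amp = 0)
  cc <- cell_centers(g)
  # noise-free, zonally constant: every longitude shares the profile and the
  # southern edge is colder than the northern for every longitude
  for (lon in c(-179.5, 0.5, 120.5)) {
    i_s <- cc$lon == lon & cc$lat == -74.5
    i_n <- cc$lon == lon & cc$lat == -30.5
    expect_lt(f$values[i_s], f$values[i_n])
  }
  expect_equal(length(unique(round(f$values[cc$lat == -50.5], 10))), 1)
  # monotone in latitude
  prof <- f$values[cc$lon == 0.5]
  expect_true(all(diff(prof) > 0))
  # the 8 degC isotherm latitude matches the profile inverse within one cell
  iso <- isotherm_latitude(g, 8)
  below <- max(cc$lat[cc$lon == 0.5][prof < 8])
  expect_lt(abs(below + 0.5 - iso), g$resolution)
  # linear profile closed form
  iso_lin <- isotherm_latitude(g, 8, front_weight = 0)
  expect_equal(iso_lin, -75 + (8 - (-1)) / 18 * 45)
  # reproducibility and noise rejection
  f1 <- make_temperature_field(g, mask, seed = 9)
  f2 <- make_temperature_field(g, mask, seed = 9)
  expect_identical(f1$values, f2$values)
  expect_error(make_temperature_field(g, mask, noise_sd = -1), "noise_sd")
})

test_that("species pool plants guild structure deterministically", {
  pool <- make_species_pool(n_south = 30, n_subtrop = 30, n_widespread = 5,
                            n_local = 5, barrier_temp = 8, seed = 3)
  south <- pool[pool$guild == "south", ]
  subtrop <- pool[pool$guild == "subtrop", ]
  expect_equal(nrow(south), 30)
  expect_true(all(south$thermal_optimum < 8))
  expect_true(all(subtrop$thermal_optimum > 8))
  expect_true(all(pool$niche_breadth > 0))
  expect_true(all(pool$max_occupancy > 0 & pool$max_occupancy <= 1))
  # widespread species straddle the barrier within +/- 2 s.d.
  wide <- pool[pool$guild == "widespread", ]
  expect_equal(nrow(wide), 5)
  expect_true(all(wide$thermal_optimum - 2 * wide$niche_breadth < 8 &
                    wide$thermal_optimum + 2 * wide$niche_breadth > 8))
  # local species carry longitude windows, others do not
  expect_true(all(!is.na(pool$lon_min[pool$guild == "local"])))
  expect_true(all(is.na(pool$lon_min[pool$guild != "local"])))
  expect_identical(pool, make_species_pool(seed = 3))
  expect_error(make_species_pool(n_south = 1, n_subtrop = 0), "2 guild")
})

test_that("occupancy model and detection sampling behave as specified", {
  sp <- list(thermal_optimum = 5, niche_breadth = 1.5, max_occupancy = 0.8,
             lon_min = NA_real_)
  expect_equal(occupancy_probability(sp, 5), 0.8)
  expect_lt(occupancy_probability(sp, 5 + 10 * 1.5), 1e-15)
  # replicate cells at the optimum, full effort: observed presence fraction
  # within the binomial 99% CI of max_occupancy
  g <- make_grid(0, 50, 0, 20, 1)  # 1000 cells
  f <- env_field(g, rep(5, g$n_cells), variable = "temperature")
  pool <- data.frame(species_id = "sp1", guild = "south", thermal_optimum = 5,
                     niche_breadth = 1.5, max_occupancy = 0.5,
                     lon_min = NA_real_, lon_max = NA_real_)
  attr(pool, "barrier_temp") <- 8
  out <- simulate_occurrences(pool, f, rep(1, g$n_cells), seed = 5)
  n_cells_hit <- length(unique(paste(out$records$decimalLongitude,
                                     out$records$decimalLatitude)))
  ci <- qbinom(c(0.005, 0.995), g$n_cells, 0.5)
  expect_gte(n_cells_hit, ci[1])
  expect_lte(n_cells_hit, ci[2])
  # records carry the stated date window
  expect_true(all(out$records$year >= 1950 & out$records$year <= 2019))
  expect_true(all(out$records$month %in% c(10, 11, 12, 1, 2, 3)))
  # truth table covers every ocean cell exactly once, split at the barrier
  expect_equal(sort(out$truth$cells$cell), seq_len(g$n_cells))
  expect_true(all(out$truth$cells$true_region == "south"))  # 5 < 8 everywhere
  expect_error(simulate_occurrences(pool[0, ], f, rep(1, g$n_cells)), "empty")
})

test_that("planted guilds have negligible expected presence beyond the barrier", {
  sc_pool <- make_species_pool(seed = 11)
  g <- make_grid(-180, 180, -75, -30, 1)
  f <- make_temperature_field(g, rep(TRUE, g$n_cells), noise_sd = 0, seed = 1)
  eff <- rep(1, g$n_cells)
  brd <- max(sc_pool$niche_breadth[sc_pool$guild == "south"])
  warm <- f$values > 8 + 2 * brd
  for (i in which(sc_pool$guild == "south")) {
    ex <- expected_occurrence_field(sc_pool[i, ], f, eff)
    expect_lt(sum(ex[warm]) / sum(ex), 0.05)
  }
})

test_that("pseudo-GCM anomalies have the configured mean and spread", {
  g <- make_grid(0, 20, 0, 10, 1)
  base <- env_field(g, rep(5, g$n_cells))
  # zero spread: every anomaly field is exactly the mean warming
  z <- make_future_anomalies(g, base, n_gcms = 3, mean_warming = 2,
                             gcm_sd = 0, hist_offset = 0, seed = 1)
  for (gc in z) expect_equal(gc$future$values - gc$hist$values,
                             rep(2, g$n_cells))
  # zero warming and spread: future equals hist everywhere
  z0 <- make_future_anomalies(g, base, n_gcms = 2, mean_warming = 0,
                              gcm_sd = 0, seed = 1)
  expect_identical(z0[[1]]$future$values, z0[[1]]$hist$values)
  # sampled spread matches within chi-squared Monte-Carlo bounds (n = 200)
  zs <- make_future_anomalies(g, base, n_gcms = 200, mean_warming = 2,
                              gcm_sd = 0.5, seed = 7)
  s <- sd(vapply(zs, function(gc) gc$anomaly, numeric(1)))
  bounds <- 0.5 * sqrt(qchisq(c(0.005, 0.995), 199) / 199)
  expect_gt(s, bounds[1])
  expect_lt(s, bounds[2])
  # determinism
  za <- make_future_anomalies(g, base, n_gcms = 4, seed = 3)
  zb <- make_future_anomalies(g, base, n_gcms = 4, seed = 3)
  expect_identical(za[[2]]$future$values, zb[[2]]$future$values)
})

test_that("environmental CSV round-trips through the long format", {
  g <- make_grid(0, 10, 0, 6, 1)
  mask <- rep(c(TRUE, TRUE, FALSE), length.out = g$n_cells)
  f <- env_field(g, rnorm(g$n_cells), mask, "salinity", 100)
  path <- tempfile(fileext = ".csv")
  write_env_csv(f, path, meta = list(seed = 1))
  f2 <- read_env_csv(path, g)
  expect_equal(f2$values, f$values)
  expect_equal(f2$variable, "salinity")
  expect_true(file.exists(paste0(path, ".meta")))
})
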