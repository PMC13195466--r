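grid12 <- grid_definition(12, 12)
year_dates <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = 1)

test_that("burn truth generation: edge cases and determinism", {
  expect_equal(nrow(generate_burn_truth(grid12, year_dates,
                                        mean_daily_events = 0, seed = 3)), 0)
  a <- generate_burn_truth(grid12, year_dates, mean_daily_events = 3, seed = 5)
  b <- generate_burn_truth(grid12, year_dates, mean_daily_events = 3, seed = 5)
  expect_identical(a, b)
  c <- generate_burn_truth(grid12, year_dates, mean_daily_events = 3, seed = 6)
  expect_false(identical(a, c))
  expect_true(all(a$area > 0))
  expect_true(all(a$date %in% year_dates))
  expect_error(generate_burn_truth(grid12, year_dates,
                                   seasonal_weights = c(JFMA = 0.9, OND = 0.3)),
               "summing to 1")
  expect_error(generate_burn_truth(grid12, year_dates, mean_daily_events = -1),
               "non-negative")
})

test_that("seasonal area shares converge to configured weights", {
  w <- default_seasonal_weights()
  ev <- generate_burn_truth(grid12, year_dates, w, mean_daily_events = 40,
                            seed = 21)
  share <- tapply(ev$area, season_of(ev$date), sum) / sum(ev$area)
  expect_true(all(abs(share[names(w)] - w) < 0.02))
})

test_that("satellite degradation drops small burns and rescales areas", {
  ev <- events_df(rep("2021-02-01", 3), area = c(0.5, 6.6, 40))
  sat <- degrade_to_satellite(ev, min_detectable_area = 1.18,
                              overreport_factor = 0.66,
                              miss_probability = 0, seed = 1)
  expect_equal(nrow(sat), 2)          # 0.5-acre burn is invisible
  expect_equal(sat$area[1], 6.6 / 0.66, tolerance = 1e-12)  # = 10 acres
  ident <- degrade_to_satellite(ev, min_detectable_area = 0,
                                overreport_factor = 1, miss_probability = 0,
                                seed = 1)
  expect_equal(ident$area, ev$area)
  expect_error(degrade_to_satellite(ev, overreport_factor = 0), "positive")
  expect_error(degrade_to_satellite(ev, miss_probability = 1), "miss_probability")
})

test_that("satellite record never contains events absent from truth", {
  st <- small_study()
  expect_true(all(with(st$satellite, paste(date, row, col)) %in%
                    with(st$truth_events, paste(date, row, col))))
  expect_true(nrow(st$satellite) <= nrow(st$truth_events))
})

test_that("permit sampling is a thinned copy of truth", {
  ev <- events_df(rep("2021-02-01", 10000), area = runif(10000, 1, 5))
  expect_equal(nrow(sample_permits(ev, 1, seed = 2)), 10000)
  n <- nrow(sample_permits(ev, 0.5, seed = 2))
  expect_lt(abs(n - 5000), 3 * sqrt(10000 * 0.25))   # binomial 3 SD
  expect_equal(nrow(sample_permits(ev[0, ], 0.5, seed = 2)), 0)
  p <- sample_permits(ev, 0.3, seed = 2)
  expect_true(all(p$area %in% ev$area))               # areas untouched
  expect_error(sample_permits(ev, 0), "coverage")
})

test_that("forward model: background-only, linearity, mass conservation", {
  g <- grid_definition(10, 10)
  d <- seq(as.Date("2021-03-01"), by = 1, length.out = 3)
  none <- simulate_concentration_fields(g, d, data.frame(), seed = 4)
  expect_equal(none$all_emissions$PM25_TOT$values,
               none$no_pf$PM25_TOT$values)

  emis <- data.frame(date = d[2], row = 5, col = 5, species = "OC",
                     mass_tons = 10)
  one <- simulate_concentration_fields(g, d, emis, seed = 4)
  two <- simulate_concentration_fields(g, d,
                                       transform(emis, mass_tons = 20), seed = 4)
  d1 <- pf_delta(one, "OC")$values
  d2 <- pf_delta(two, "OC")$values
  expect_equal(d2, 2 * d1, tolerance = 1e-12)

  # kernel normalization: total added mass = emitted mass x retention
  retention <- 0.12; H <- 1000
  added_ug <- sum(d1) * g$cell_area_km2 * 1e6 * H    # conc x cell volume
  expect_equal(added_ug, 10 * 1e12 * retention, tolerance = 1e-9)

  expect_error(simulate_concentration_fields(g, d, emis, kernel_sd_km = 0),
               "positive")
})

test_that("total PM2.5 field is the exact sum of component fields", {
  st <- small_study()
  p <- st$truth_pair
  comp_sum <- Reduce(`+`, lapply(PF_COMPONENTS, function(s)
    p$all_emissions[[s]]$values)) + p$all_emissions$OTHER$values
  expect_equal(comp_sum, p$all_emissions$PM25_TOT$values, tolerance = 1e-12)
})

test_that("observations follow schedules and are exact when noise-free", {
  g <- grid_definition(6, 6)
  d <- seq(as.Date("2021-01-01"), by = 1, length.out = 9)
  emis <- data.frame(date = d[3], row = 2, col = 4, species = "EC",
                     mass_tons = 5)
  pair <- simulate_concentration_fields(g, d, emis, seed = 9)
  sites <- data.frame(id = c("T01", "S01"), row = c(2, 5), col = c(4, 5),
                      kind = c("total_pm", "speciation"),
                      schedule = c("daily", "one_in_three"),
                      offset = c(0L, 1L), near_road = FALSE)
  obs <- generate_observations(pair$all_emissions, sites, noise_sd = 0, seed = 2)
  t_obs <- obs[obs$site == "T01", ]
  expect_equal(nrow(t_obs), 9)                      # daily, total only
  expect_equal(unique(t_obs$species), "PM25_TOT")
  s_obs <- obs[obs$site == "S01", ]
  expect_equal(length(unique(s_obs$date)), 3)       # 1-in-3 over 9 days
  expect_setequal(unique(s_obs$species), c("PM25_TOT", PF_COMPONENTS))
  cell <- cell_index(g, 2, 4)
  expect_equal(t_obs$value,
               pair$all_emissions$PM25_TOT$values[, cell], tolerance = 1e-12)

  bad_sites <- transform(sites, row = c(2, 99))
  expect_error(generate_observations(pair$all_emissions, bad_sites, 0, 2),
               "outside")
})

test_that("model biases reproduce the intended network-wide NMB", {
  st <- default_study()
  obs <- exclude_near_road(st$observations, st$sites)
  sim <- st$model_pair$all_emissions$PM25_TOT
  o <- pfsmoke:::obs_pairs(obs, st$sites, st$grid, sim$dates, "PM25_TOT")
  stats <- compute_stats(sim$values[cbind(o$day, o$cell)], o$value)
  # total PM2.5 underestimated by ~20%
  expect_lt(abs(stats$NMB - (-20)), 4)
})
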