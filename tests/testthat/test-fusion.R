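test_that("near-road exclusion filters exactly the flagged sites", {
  sites <- data.frame(id = c("A", "B", "C"), row = 1, col = 1:3,
                      kind = "total_pm", schedule = "daily", offset = 0L,
                      near_road = c(FALSE, TRUE, FALSE))
  obs <- data.frame(site = c("A", "B", "C", "B"),
                    date = as.Date("2021-01-01"), species = "PM25_TOT",
                    value = 1:4)
  out <- exclude_near_road(obs, sites)
  expect_setequal(out$site, c("A", "C"))
  expect_equal(nrow(exclude_near_road(obs, transform(sites, near_road = TRUE))), 0)
  expect_equal(exclude_near_road(obs, transform(sites, near_road = FALSE)), obs)
  expect_error(exclude_near_road(transform(obs, site = "Z"), sites), "unknown")
})

test_that("fusing a field against its own noise-free observations is the identity", {
  st <- exact_study()
  obs <- exclude_near_road(st$observations, st$sites)
  sim <- st$model_pair$all_emissions$PM25_TOT
  fused <- fuse_total(sim, obs, st$sites)
  expect_lt(rel_diff(fused$values, sim$values), 1e-6)
})

test_that("fusion removes a known multiplicative bias at monitored cells", {
  st <- exact_study()
  obs <- exclude_near_road(st$observations, st$sites)
  truth <- st$truth_pair$all_emissions$PM25_TOT
  sim <- field_series(truth$grid, truth$dates, "PM25_TOT", "all",
                      0.8 * truth$values)
  fused <- fuse_total(sim, obs, st$sites)
  usable <- st$sites[!st$sites$near_road & st$sites$kind == "total_pm", ]
  cells <- cell_index(st$grid, usable$row, usable$col)
  expect_lt(max(abs(fused$values[, cells] / truth$values[, cells] - 1)), 0.05)
  expect_true(all(fused$values >= fusion_config()$concentration_floor))
})

test_that("PF-total fusion follows the ratio equation and its algebra", {
  g <- grid_definition(2, 2)
  d <- as.Date("2021-01-01") + 0:1
  mk <- function(v, scen = "all", sp = "PM25_TOT")
    field_series(g, d, sp, scen, matrix(v, 2, 4))
  cfg <- fusion_config()
  out <- fuse_pf_total(mk(2, "delta_pf"), mk(10), mk(12, "fused"), cfg)
  expect_equal(unique(as.vector(out$values)), 2.4)      # 2 x 12/10
  ident <- fuse_pf_total(mk(2, "delta_pf"), mk(10), mk(10, "fused"), cfg)
  expect_equal(unique(as.vector(ident$values)), 2)

  # cap engages when the simulated denominator collapses
  capped <- fuse_pf_total(mk(1, "delta_pf"), mk(0.001), mk(5, "fused"), cfg)
  expect_equal(unique(as.vector(capped$values)), cfg$ratio_cap)

  # property: 0 <= delta_sim <= sim_total implies 0 <= delta_DF <= fused
  set.seed(41)
  for (i in 1:20) {
    sim_v <- matrix(runif(4, 1, 20), 2, 4)
    del_v <- sim_v * matrix(runif(4), 2, 4)
    fus_v <- matrix(runif(4, 1, 20), 2, 4)
    r <- fuse_pf_total(field_series(g, d, "PM25_TOT", "delta_pf", del_v),
                       field_series(g, d, "PM25_TOT", "all", sim_v),
                       field_series(g, d, "PM25_TOT", "fused", fus_v), cfg)
    expect_true(all(r$values >= 0 & r$values <= fus_v + 1e-12))
  }

  # monotone increasing in the fused total
  lo <- fuse_pf_total(mk(2, "delta_pf"), mk(10), mk(11, "fused"), cfg)
  hi <- fuse_pf_total(mk(2, "delta_pf"), mk(10), mk(13, "fused"), cfg)
  expect_true(all(hi$values >= lo$values))
})

test_that("PF fraction of total mass is preserved where floor and cap are inactive", {
  st <- default_study()
  obs <- exclude_near_road(st$observations, st$sites)
  sim <- st$model_pair$all_emissions$PM25_TOT
  fused <- fuse_total(sim, obs, st$sites)
  delta <- pf_delta(st$model_pair)
  cfg <- fusion_config()
  fd <- fuse_pf_total(delta, sim, fused, cfg)
  ok <- sim$values > cfg$denom_floor &
    fused$values / sim$values < cfg$ratio_cap
  lhs <- fd$values[ok] / fused$values[ok]
  rhs <- delta$values[ok] / sim$values[ok]
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("ratio fusion preserves mass balance and recovers biased ratios", {
  st <- default_study()
  obs <- exclude_near_road(st$observations, st$sites)
  sim_fields <- st$model_pair$all_emissions
  fused_tot <- fuse_total(sim_fields$PM25_TOT, obs, st$sites)
  rf <- fuse_species_ratios(sim_fields, obs, st$sites, fused_tot)

  # closure: components sum to the fused total everywhere
  spe_sum <- Reduce(`+`, lapply(rf$species, function(f) f$values))
  expect_lt(rel_diff(spe_sum, fused_tot$values), 1e-9)
  ratio_sum <- Reduce(`+`, lapply(rf$ratios, function(f) f$values))
  expect_lt(max(abs(ratio_sum - 1)), 1e-9)

  # the model's +42% OC ratio bias is largely removed at speciation sites
  spec_sites <- st$sites[st$sites$kind == "speciation", ]
  cells <- cell_index(st$grid, spec_sites$row, spec_sites$col)
  truth_ratio <- st$truth_pair$all_emissions$OC$values[, cells] /
    st$truth_pair$all_emissions$PM25_TOT$values[, cells]
  fused_ratio <- rf$ratios$OC$values[, cells]
  sim_ratio <- sim_fields$OC$values[, cells] / sim_fields$PM25_TOT$values[, cells]
  expect_lt(median(abs(fused_ratio / truth_ratio - 1)), 0.10)
  expect_lt(median(abs(fused_ratio / truth_ratio - 1)),
            median(abs(sim_ratio / truth_ratio - 1)))
})

test_that("unit corrections leave species fusion at the simulated ratios", {
  st <- exact_study()
  obs <- exclude_near_road(st$observations, st$sites)
  sim_fields <- st$model_pair$all_emissions
  fused_tot <- fuse_total(sim_fields$PM25_TOT, obs, st$sites)
  rf <- fuse_species_ratios(sim_fields, obs, st$sites, fused_tot)
  for (sp in PF_COMPONENTS) {
    r_sim <- sim_fields[[sp]]$values / sim_fields$PM25_TOT$values
    expect_lt(rel_diff(rf$ratios[[sp]]$values, r_sim), 1e-4)
  }
  expect_error(fuse_species_ratios(sim_fields,
                                   obs[obs$species == "PM25_TOT", ],
                                   st$sites, fused_tot),
               "no speciation observations")
})

test_that("component PF fusion mirrors the total equation and closes", {
  g <- grid_definition(2, 2)
  d <- as.Date("2021-01-01") + 0:1
  mk <- function(v, scen = "all", sp = "EC")
    field_series(g, d, sp, scen, matrix(v, 2, 4))
  out <- fuse_pf_species(mk(0.05, "delta_pf"), mk(0.2), mk(0.3, "fused"))
  expect_equal(unique(as.vector(out$values)), 0.075)
  ident <- fuse_pf_species(mk(0.05, "delta_pf"), mk(0.2), mk(0.2, "fused"))
  expect_equal(unique(as.vector(ident$values)), 0.05)

  # on the exact fixture, species PF deltas sum to the total PF delta
  st <- exact_study()
  obs <- exclude_near_road(st$observations, st$sites)
  sim_fields <- st$model_pair$all_emissions
  fused_tot <- fuse_total(sim_fields$PM25_TOT, obs, st$sites)
  rf <- fuse_species_ratios(sim_fields, obs, st$sites, fused_tot)
  delta <- pf_delta_all(st$model_pair)
  fd_tot <- fuse_pf_total(delta$PM25_TOT, sim_fields$PM25_TOT, fused_tot)
  fd_sum <- Reduce(`+`, lapply(c(PF_COMPONENTS, "OTHER"), function(sp)
    fuse_pf_species(delta[[sp]], sim_fields[[sp]], rf$species[[sp]])$values))
  expect_lt(rel_diff(fd_sum, fd_tot$values), 1e-4)
})
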