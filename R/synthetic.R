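#' Default seasonal shares of prescribed burning activity
#'
#' Area shares by burning season: 54.1% in JFMA (extensive season), 22.1%
#' in MJJAS, 23.8% in OND.
#' @export
default_seasonal_weights <- function() c(JFMA = 0.541, MJJAS = 0.221, OND = 0.238)

#' Default per-species multiplicative model biases
#'
#' The factors applied to truth fields to emulate a chemical-transport
#' model's systematic errors: total PM2.5 underestimated ~20%, EC ~29%,
#' NO3 ~10%, SO4 ~21%; OC overestimated ~42%.  The residual OTHER component
#' carries the total-mass bias.
#' @export
default_model_bias <- function() {
  c(PM25_TOT = 0.80, EC = 0.71, OC = 1.42, NO3 = 0.90, SO4 = 0.79, OTHER = 0.80)
}

#' Default non-fire background concentrations (ug/m3)
#'
#' Component levels chosen so ambient totals sit near 10 ug/m3 with a
#' composition typical of the southeastern US (EC 0.25, OC 1.8, NO3 0.3,
#' SO4 1.3, OTHER 6.35).
#' @export
default_background <- function() {
  c(EC = 0.25, OC = 1.80, NO3 = 0.30, SO4 = 1.30, OTHER = 6.35)
}

empty_events <- function() {
  data.frame(date = as.Date(character()), row = integer(), col = integer(),
             area = numeric(), source = character(), burn_type = character(),
             ownership = character(), stringsAsFactors = FALSE)
}

check_events <- function(events) {
  need <- c("date", "row", "col", "area", "source", "burn_type", "ownership")
  if (!all(need %in% names(events))) stop("burn-event table missing columns")
  if (any(events$area <= 0)) stop("event areas must be positive")
  invisible(events)
}

#' Generate ground-truth prescribed burn events
#'
#' Event dates follow the configured seasonal area shares; burned areas are
#' drawn log-normal (positive, heavy-tailed, like permit records); locations
#' are uniform over the grid; ownership is private with probability
#' `p_private` (84% of southeastern prescribed burning is on private land).
#'
#' @param grid A `pf_grid`.
#' @param dates Date vector of simulation days.
#' @param seasonal_weights Named fractions per season summing to 1.
#' @param mean_daily_events Expected number of burn events per simulated day.
#' @param area_meanlog,area_sdlog Log-normal parameters of event area (acres).
#' @param p_private Probability an event is on private (vs federal) land.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return data.frame of burn events (`date`, `row`, `col`, `area` acres,
#'   `source = "truth"`, `burn_type`, `ownership`), sorted by date.
#' @export
generate_burn_truth <- function(grid, dates,
                                seasonal_weights = default_seasonal_weights(),
                                mean_daily_events = 12,
                                area_meanlog = 3.5, area_sdlog = 1.2,
                                p_private = 0.84, seed = 1) {
  stopifnot(inherits(grid, "pf_grid"))
  dates <- as.Date(dates)
  if (length(dates) < 1L) stop("need at least one simulation day")
  if (!is.numeric(mean_daily_events) || mean_daily_events < 0)
    stop("mean_daily_events must be a non-negative rate")
  if (is.null(names(seasonal_weights)) || any(seasonal_weights < 0) ||
      abs(sum(seasonal_weights) - 1) > 1e-8)
    stop("seasonal_weights must be named non-negative fractions summing to 1")
  if (mean_daily_events == 0) return(empty_events())

  day_season <- season_of(dates)
  present <- intersect(names(seasonal_weights), unique(day_season))
  w <- seasonal_weights[present]
  if (length(w) == 0L || sum(w) <= 0)
    stop("no simulation days fall in a season with positive weight")
  w <- w / sum(w)

  with_seed(seed, {
    n <- stats::rpois(1, mean_daily_events * length(dates))
    if (n == 0) return(empty_events())
    season <- sample(names(w), n, replace = TRUE, prob = w)
    date <- as.Date(vapply(season, function(s) {
      pool <- dates[day_season == s]
      as.numeric(sample(pool, 1))
    }, numeric(1)), origin = "1970-01-01")
    row <- sample.int(grid$n_rows, n, replace = TRUE)
    col <- sample.int(grid$n_cols, n, replace = TRUE)
    area <- stats::rlnorm(n, area_meanlog, area_sdlog)
    ownership <- ifelse(stats::runif(n) < p_private, "private", "federal")
    ev <- data.frame(date = date, row = row, col = col, area = area,
                     source = "truth", burn_type = "prescribed",
                     ownership = ownership, stringsAsFactors = FALSE)
    ev[order(ev$date), , drop = FALSE]
  })
}

#' Degrade truth burns into a satellite-style fire record
#'
#' Satellite fire products cannot see small burns and systematically
#' over-report area for the burns they do detect.  Events below
#' `min_detectable_area` are dropped; survivors are missed with probability
#' `miss_probability`; reported area = truth area / `overreport_factor`
#' (default 0.66, so satellite areas exceed truth and a regression of
#' permits on satellite recovers 0.66).
#'
#' @param truth Event table from [generate_burn_truth()].
#' @param min_detectable_area Acres; smallest detectable burn (default 1.18).
#' @param overreport_factor Ratio of true to reported area, in (0, ...).
#' @param miss_probability Probability a detectable event is still missed.
#' @param seed Integer seed.
#' @return Event table with `source = "satellite"`; a subset of truth rows.
#' @export
degrade_to_satellite <- function(truth, min_detectable_area = 1.18,
                                 overreport_factor = 0.66,
                                 miss_probability = 0.3, seed = 1) {
  check_events(truth)
  if (!is.numeric(overreport_factor) || overreport_factor <= 0)
    stop("overreport_factor must be positive")
  if (miss_probability < 0 || miss_probability >= 1)
    stop("miss_probability must be in [0, 1)")
  keep <- truth[truth$area >= min_detectable_area, , drop = FALSE]
  with_seed(seed, {
    detected <- stats::runif(nrow(keep)) >= miss_probability
    out <- keep[detected, , drop = FALSE]
    out$area <- out$area / overreport_factor
    out$source <- rep("satellite", nrow(out))
    rownames(out) <- NULL
    out
  })
}

#' Sample a permit record from truth burns
#'
#' Each truth event appears in the permit record independently with
#' `coverage_probability`; permit areas equal truth areas (permits are
#' treated as the accurate area source).
#'
#' @param truth Event table from [generate_burn_truth()].
#' @param coverage_probability In (0, 1].
#' @param seed Integer seed.
#' @return Event table with `source = "permit"`.
#' @export
sample_permits <- function(truth, coverage_probability = 0.9, seed = 1) {
  check_events(truth)
  if (coverage_probability <= 0 || coverage_probability > 1)
    stop("coverage_probability must be in (0, 1]")
  with_seed(seed, {
    keep <- stats::runif(nrow(truth)) < coverage_probability
    out <- truth[keep, , drop = FALSE]
    out$source <- rep("permit", nrow(out))
    rownames(out) <- NULL
    out
  })
}

#' Lay out a synthetic monitoring network
#'
#' Total-PM2.5 monitors report daily; speciation monitors report all five
#' species on a 1-in-3-day schedule with a site-specific offset.  A few
#' total-PM sites are flagged near-road (these are excluded before fusion).
#'
#' @param grid A `pf_grid`.
#' @param n_total Number of daily total-PM2.5 sites.
#' @param n_speciation Number of 1-in-3-day speciation sites.
#' @param n_near_road How many total-PM sites to flag as near-road.
#' @param seed Integer seed.
#' @return data.frame: `id`, `row`, `col`, `kind` (total_pm | speciation),
#'   `schedule` (daily | one_in_three), `offset` (0-2), `near_road`.
#' @export
monitor_network <- function(grid, n_total = 30, n_speciation = 8,
                            n_near_road = 3, seed = 1) {
  stopifnot(inherits(grid, "pf_grid"))
  n <- n_total + n_speciation
  if (n > grid$n_cells) stop("more sites than grid cells")
  if (n_near_road > n_total) stop("n_near_road cannot exceed n_total")
  with_seed(seed, {
    cells <- sample.int(grid$n_cells, n)
    rc <- cell_rowcol(grid, cells)
    kind <- c(rep("total_pm", n_total), rep("speciation", n_speciation))
    near <- rep(FALSE, n)
    if (n_near_road > 0) near[sample.int(n_total, n_near_road)] <- TRUE
    data.frame(
      id = sprintf("%s%02d", ifelse(kind == "total_pm", "T", "S"),
                   c(seq_len(n_total), seq_len(n_speciation))),
      row = rc$row, col = rc$col, kind = kind,
      schedule = ifelse(kind == "speciation", "one_in_three", "daily"),
      offset = ifelse(kind == "speciation",
                      sample(0:2, n, replace = TRUE), 0L),
      near_road = near, stringsAsFactors = FALSE)
  })
}

#' Toy dispersion forward model: paired with/without-PF fields
#'
#' Each day's component field is a smooth background plus, for every source
#' cell, the day's emitted mass spread over the grid by an isotropic
#' Gaussian kernel (scale `kernel_sd_km`) centered at the source displaced
#' by a per-day random wind offset (plus an optional constant
#' `wind_shift_km`, used to emulate model plume-placement error).  Kernel
#' weights are normalized to sum 1 over the grid, so emitted mass is
#' conserved; mass converts to a 24 h surface concentration through a box
#' factor `retention` x 1e12 / (cell area x `mixing_height_m`).  The total
#' PM2.5 field is the sum of the five component fields, so species closure
#' holds exactly and the model is linear in emissions by construction.
#'
#' The `no_pf` member is the same background with all fire emissions
#' removed.  Background draws (daily factor, wind) consume the RNG in a
#' fixed order independent of the emissions, so two calls with the same
#' seed but different emissions or `wind_shift_km` share identical
#' backgrounds and winds.
#'
#' @param grid A `pf_grid`.
#' @param dates Date vector of simulation days.
#' @param emissions data.frame (`date`, `row`, `col`, `species`,
#'   `mass_tons`) of daily per-cell component emissions, e.g. from
#'   [compute_emissions()]; `PM25_TOT` rows are ignored (total = sum).
#' @param background Named component levels (ug/m3), see
#'   [default_background()].
#' @param kernel_sd_km Gaussian plume scale (km); must be positive.
#' @param wind_sd_km SD of the per-day random wind displacement (km).
#' @param wind_shift_km Constant extra displacement (x, y km) of every plume.
#' @param mixing_height_m Mixed-layer depth for the box conversion.
#' @param retention Fraction of emitted mass residing in the surface layer
#'   over the 24 h average (ventilation/deposition losses).
#' @param bg_temporal_sd SD of the lognormal day-to-day background factor.
#' @param bg_spatial_amp Amplitude of the smooth spatial background pattern.
#' @param seed Integer seed.
#' @return A [scenario_pair()] holding `PM25_TOT` plus the five components
#'   for both scenarios.
#' @export
simulate_concentration_fields <- function(grid, dates, emissions,
                                          background = default_background(),
                                          kernel_sd_km = 18,
                                          wind_sd_km = 12,
                                          wind_shift_km = c(0, 0),
                                          mixing_height_m = 1000,
                                          retention = 0.12,
                                          bg_temporal_sd = 0.10,
                                          bg_spatial_amp = 0.20,
                                          seed = 1) {
  stopifnot(inherits(grid, "pf_grid"))
  dates <- as.Date(dates)
  comps <- c("EC", "OC", "NO3", "SO4", "OTHER")
  if (!all(comps %in% names(background)) || any(background < 0))
    stop("background must name non-negative levels for all five components")
  if (!is.numeric(kernel_sd_km) || kernel_sd_km <= 0)
    stop("kernel scale must be positive")
  if (nrow(emissions) > 0) {
    emissions <- emissions[emissions$species %in% comps, , drop = FALSE]
    if (any(emissions$mass_tons < 0)) stop("emissions must be non-negative")
  }
  n_d <- length(dates); n_c <- grid$n_cells
  centers <- cell_centers(grid)

  # Background: level x smooth spatial pattern x seeded seasonal day factor.
  doy <- as.integer(format(dates, "%j"))
  xs <- (centers[, 1] - min(centers[, 1])) / max(diff(range(centers[, 1])), 1)
  ys <- (centers[, 2] - min(centers[, 2])) / max(diff(range(centers[, 2])), 1)
  spatial <- 1 + bg_spatial_amp * sin(pi * xs) * cos(pi * ys)

  rng <- with_seed(seed, list(
    day_factor = exp(0.20 * sin(2 * pi * (doy - 30) / 365) +
                       stats::rnorm(n_d, 0, bg_temporal_sd)),
    wind = cbind(stats::rnorm(n_d, 0, wind_sd_km),
                 stats::rnorm(n_d, 0, wind_sd_km))
  ))
  bg_pattern <- outer(rng$day_factor, spatial)            # n_d x n_c

  conv <- retention * 1e12 / (grid$cell_area_km2 * 1e6 * mixing_height_m)

  delta <- stats::setNames(
    lapply(comps, function(s) matrix(0, n_d, n_c)), comps)
  if (nrow(emissions) > 0) {
    emissions$date <- as.Date(emissions$date)
    emissions <- emissions[emissions$date %in% dates, , drop = FALSE]
  }
  if (nrow(emissions) > 0) {
    cellid <- cell_index(grid, emissions$row, emissions$col)
    key <- paste(emissions$date, cellid)
    for (k in unique(key)) {
      sel <- key == k
      d <- match(emissions$date[sel][1], dates)
      src <- cellid[sel][1]
      ctr <- centers[src, ] + rng$wind[d, ] + wind_shift_km
      d2 <- (centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2
      w <- exp(-d2 / (2 * kernel_sd_km^2))
      w <- w / sum(w)
      mass <- tapply(emissions$mass_tons[sel], emissions$species[sel], sum)
      for (s in names(mass))
        delta[[s]][d, ] <- delta[[s]][d, ] + mass[[s]] * conv * w
    }
  }

  all_f <- list(); nopf_f <- list()
  tot_all <- matrix(0, n_d, n_c); tot_nopf <- matrix(0, n_d, n_c)
  for (s in comps) {
    bg_s <- background[[s]] * bg_pattern
    all_f[[s]] <- field_series(grid, dates, s, "all", bg_s + delta[[s]])
    nopf_f[[s]] <- field_series(grid, dates, s, "no_pf", bg_s)
    tot_all <- tot_all + all_f[[s]]$values
    tot_nopf <- tot_nopf + nopf_f[[s]]$values
  }
  all_f[["PM25_TOT"]] <- field_series(grid, dates, "PM25_TOT", "all", tot_all)
  nopf_f[["PM25_TOT"]] <- field_series(grid, dates, "PM25_TOT", "no_pf", tot_nopf)
  ord <- c("PM25_TOT", comps)
  scenario_pair(all_f[ord], nopf_f[ord])
}

#' Apply per-species multiplicative biases to a scenario pair
#'
#' Turns a truth pair into a "model" pair with systematic amplitude errors.
#' Note the biased total is no longer the sum of the biased components -
#' exactly the inconsistency ratio-based species fusion is designed to
#' absorb.
#' @param pair A `pf_scenario_pair`.
#' @param biases Named factors, see [default_model_bias()].
#' @return A biased `pf_scenario_pair`.
#' @export
apply_model_bias <- function(pair, biases = default_model_bias()) {
  stopifnot(inherits(pair, "pf_scenario_pair"))
  bias_one <- function(f) {
    b <- biases[[f$species]]
    if (is.null(b)) stop(sprintf("no bias factor for species %s", f$species))
    field_series(f$grid, f$dates, f$species, f$scenario, f$values * b)
  }
  scenario_pair(lapply(pair$all_emissions, bias_one),
                lapply(pair$no_pf, bias_one))
}

schedule_indices <- function(n_days, schedule, offset) {
  if (schedule == "daily") seq_len(n_days)
  else seq_len(n_days)[(seq_len(n_days) - 1L - offset) %% 3L == 0L]
}

#' Generate monitor observations from truth fields
#'
#' Observations are unbiased: truth at the site's cell times `(1 + eps)`,
#' `eps ~ Normal(0, noise_sd)`, truncated at 0, emitted only on each site's
#' schedule days.  Total-PM sites report `PM25_TOT`; speciation sites
#' report all five measured species (total + EC, OC, NO3, SO4).
#'
#' @param truth_fields Named list of truth `pf_field`s (the `all_emissions`
#'   member of the truth pair), including `PM25_TOT` and the components.
#' @param sites Monitor table from [monitor_network()].
#' @param noise_sd Relative measurement noise SD (default 0.10).
#' @param seed Integer seed.
#' @return data.frame: `site`, `date`, `species`, `value` (ug/m3).
#' @export
generate_observations <- function(truth_fields, sites, noise_sd = 0.10, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  tot <- truth_fields[["PM25_TOT"]]
  if (is.null(tot)) stop("truth_fields must include PM25_TOT")
  grid <- tot$grid
  n_days <- length(tot$dates)
  cells <- cell_index(grid, sites$row, sites$col)
  rows <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(sites))) {
      idx <- schedule_indices(n_days, sites$schedule[i], sites$offset[i])
      spp <- if (sites$kind[i] == "speciation") c("PM25_TOT", PF_COMPONENTS)
             else "PM25_TOT"
      for (sp in spp) {
        tru <- truth_fields[[sp]]$values[idx, cells[i]]
        val <- pmax(0, tru * (1 + stats::rnorm(length(idx), 0, noise_sd)))
        rows[[length(rows) + 1L]] <- data.frame(
          site = sites$id[i], date = tot$dates[idx], species = sp,
          value = val, stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the default synthetic study
#'
#' One call that generates every input the pipeline needs under the default
#' study conditions: a 30 x 30 grid at 12 km, 120 daily field slices spread
#' over calendar 2021 (all three burning seasons), JFMA-heavy burn truth,
#' degraded satellite and permit records, component emissions, truth
#' concentration fields, a biased + plume-displaced model pair, a 38-site
#' monitor network, and unbiased noisy observations.
#'
#' @param seed Global seed; per-stage seeds are derived deterministically.
#' @param n_rows,n_cols,cell_size_km Grid geometry.
#' @param dates Simulation days (default: every third day of 2021).
#' @param mean_daily_events,area_meanlog,area_sdlog Burn-truth parameters.
#' @param seasonal_weights Seasonal area shares.
#' @param ef_table Emission factors, see [emission_factor_table()].
#' @param background Non-fire component background levels.
#' @param model_bias Per-species model bias factors.
#' @param model_wind_shift_km Constant plume displacement of the model pair
#'   (km), emulating transport/timing error; `c(0, 0)` disables it.
#' @param model_day_error_sd SD of the per-day lognormal amplitude error of
#'   the model fields (meteorology-driven, common to all species and both
#'   scenario members); 0 disables it.
#' @param n_total,n_speciation,n_near_road Monitor network sizes.
#' @param noise_sd Observation noise.
#' @param ... Passed to [simulate_concentration_fields()].
#' @return List: `grid`, `dates`, `truth_events`, `satellite`, `permits`,
#'   `sites`, `emissions`, `truth_pair`, `model_pair`, `observations`.
#' @export
synthetic_study <- function(seed = 1,
                            n_rows = 30, n_cols = 30, cell_size_km = 12,
                            dates = seq(as.Date("2021-01-01"),
                                        as.Date("2021-12-31"), by = 3),
                            mean_daily_events = 12,
                            area_meanlog = 3.5, area_sdlog = 1.2,
                            seasonal_weights = default_seasonal_weights(),
                            ef_table = emission_factor_table(),
                            background = default_background(),
                            model_bias = default_model_bias(),
                            model_wind_shift_km = c(24, 0),
                            model_day_error_sd = 0.15,
                            n_total = 30, n_speciation = 8, n_near_road = 3,
                            noise_sd = 0.10, ...) {
  grid <- grid_definition(n_rows, n_cols, cell_size_km)
  truth <- generate_burn_truth(grid, dates, seasonal_weights,
                               mean_daily_events, area_meanlog, area_sdlog,
                               seed = derive_seed(seed, 1))
  satellite <- degrade_to_satellite(truth, seed = derive_seed(seed, 2))
  permits <- sample_permits(truth, seed = derive_seed(seed, 3))
  sites <- monitor_network(grid, n_total, n_speciation, n_near_road,
                           seed = derive_seed(seed, 4))
  emis <- compute_emissions(truth, ef_table)
  field_seed <- derive_seed(seed, 5)
  truth_pair <- simulate_concentration_fields(grid, dates, emis, background,
                                              seed = field_seed, ...)
  model_pair <- apply_model_bias(
    simulate_concentration_fields(grid, dates, emis, background,
                                  wind_shift_km = model_wind_shift_km,
                                  seed = field_seed, ...),
    model_bias)
  if (model_day_error_sd > 0) {
    day_err <- with_seed(derive_seed(seed, 8),
                         exp(stats::rnorm(length(dates), 0, model_day_error_sd)))
    scale_days <- function(f)
      field_series(f$grid, f$dates, f$species, f$scenario, f$values * day_err)
    model_pair <- scenario_pair(lapply(model_pair$all_emissions, scale_days),
                                lapply(model_pair$no_pf, scale_days))
  }
  obs <- generate_observations(truth_pair$all_emissions, sites, noise_sd,
                               seed = derive_seed(seed, 6))
  list(grid = grid, dates = as.Date(dates), truth_events = truth,
       satellite = satellite, permits = permits, sites = sites,
       emissions = emis, truth_pair = truth_pair, model_pair = model_pair,
       observations = obs)
}
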