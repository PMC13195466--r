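#' Configuration of the observation-model data fusion
#'
#' @param polynomial_degree Degree of the per-day polynomial mapping
#'   simulated to observed totals.  Default 1: with a few dozen pairs per
#'   day, quadratic fits extrapolate erratically to plume cells outside
#'   the monitored concentration range (see the methods vignette); higher
#'   degrees remain available.
#' @param min_pairs_per_day Minimum collocated pairs for a day-specific
#'   polynomial fit; below this a pooled climatological fit is used.
#' @param idw_power Inverse-distance-weighting exponent for the residual
#'   log-ratio interpolation.
#' @param idw_radius_km Radius beyond which the residual correction tapers
#'   to ratio 1 (model-shaped far from monitors).
#' @param denom_floor Concentration floor (ug/m3) for every denominator in
#'   the ratio equations, preventing blow-up near zero.
#' @param ratio_cap Cap on every multiplicative correction (and its
#'   reciprocal), preventing unbounded inflation.
#' @param concentration_floor Floor applied to fused concentration fields.
#' @return A `pf_fusion_config` object.
#' @export
fusion_config <- function(polynomial_degree = 1, min_pairs_per_day = 5,
                          idw_power = 2, idw_radius_km = 300,
                          denom_floor = 0.01, ratio_cap = 10,
                          concentration_floor = 0.01) {
  if (polynomial_degree < 1) stop("polynomial_degree must be >= 1")
  if (denom_floor <= 0) stop("denom_floor must be positive")
  if (ratio_cap <= 1) stop("ratio_cap must exceed 1")
  if (idw_power <= 0 || idw_radius_km <= 0) stop("idw parameters must be positive")
  structure(list(polynomial_degree = as.integer(polynomial_degree),
                 min_pairs_per_day = as.integer(min_pairs_per_day),
                 idw_power = idw_power, idw_radius_km = idw_radius_km,
                 denom_floor = denom_floor, ratio_cap = ratio_cap,
                 concentration_floor = concentration_floor),
            class = "pf_fusion_config")
}

#' Drop observations from near-road monitors
#'
#' Near-road sites sample local traffic gradients unrepresentative of a
#' grid cell and would drag the fusion upward; they are removed before any
#' fusion step.
#' @param observations Observation table (`site`, `date`, `species`, `value`).
#' @param sites Monitor table with `id` and `near_road` columns.
#' @return Filtered observation table.
#' @export
exclude_near_road <- function(observations, sites) {
  unknown <- setdiff(unique(observations$site), sites$id)
  if (length(unknown))
    stop(sprintf("observations reference unknown sites: %s",
                 paste(unknown, collapse = ", ")))
  flagged <- sites$id[sites$near_road]
  out <- observations[!observations$site %in% flagged, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- internal helpers -------------------------------------------------------

site_cells <- function(grid, sites) cell_index(grid, sites$row, sites$col)

# Distance (km) from each site to each cell center: n_sites x n_cells.
site_cell_dist <- function(grid, sites) {
  centers <- cell_centers(grid)
  sx <- grid$origin[1] + (sites$col - 0.5) * grid$cell_size_km
  sy <- grid$origin[2] + (sites$row - 0.5) * grid$cell_size_km
  sqrt(outer(sx, centers[, 1], "-")^2 + outer(sy, centers[, 2], "-")^2)
}

# IDW of per-site values over cells with taper to 0 beyond radius.
# vals: n_sites vector (NA = site silent); returns n_cells vector (0 where
# no site in range).
idw_interp <- function(dist, vals, power, radius) {
  ok <- which(!is.na(vals))
  out <- numeric(ncol(dist))
  if (!length(ok)) return(out)
  d <- dist[ok, , drop = FALSE]
  w <- ifelse(d < radius, (1 - d / radius) / pmax(d, 1e-3)^power, 0)
  denom <- colSums(w)
  num <- colSums(w * vals[ok])
  nz <- denom > 0
  out[nz] <- num[nz] / denom[nz]
  out
}

poly_fit <- function(x, y, degree) {
  deg <- min(degree, length(unique(x)) - 1L)
  if (deg < 1L) return(NULL)
  fit <- stats::lm(y ~ stats::poly(x, deg, raw = TRUE))
  list(coef = stats::coef(fit), range = range(x))
}

# Evaluate the fitted polynomial; beyond the range of the fitting data it
# continues linearly (tangent at the range endpoint), so high plume values
# outside the monitored range are rescaled, not extrapolated quadratically.
poly_apply <- function(fit, x) {
  pv <- function(z) {
    out <- rep(fit$coef[1], length(z))
    for (k in seq_along(fit$coef)[-1]) out <- out + fit$coef[k] * z^(k - 1)
    out
  }
  pd <- function(z) {
    out <- rep(0, length(z))
    for (k in seq_along(fit$coef)[-1]) out <- out + (k - 1) * fit$coef[k] * z^(k - 2)
    out
  }
  lo <- fit$range[1]; hi <- fit$range[2]
  out <- pv(pmin(pmax(x, lo), hi))
  below <- x < lo; above <- x > hi
  if (any(below)) out[below] <- pv(lo) + pd(lo) * (x[below] - lo)
  if (any(above)) out[above] <- pv(hi) + pd(hi) * (x[above] - hi)
  out
}

clip_ratio <- function(r, cap) pmin(pmax(r, 1 / cap), cap)

# Mean observation per (site, date) for one species, joined to site cells.
obs_pairs <- function(observations, sites, grid, dates, species) {
  o <- observations[observations$species == species, , drop = FALSE]
  if (nrow(o) == 0) return(NULL)
  o <- stats::aggregate(value ~ site + date, o, mean)
  o$date <- as.Date(o$date)
  o$day <- match(o$date, dates)
  o <- o[!is.na(o$day), , drop = FALSE]
  o$site_idx <- match(o$site, sites$id)
  if (anyNA(o$site_idx)) stop("observations reference unknown sites")
  o$cell <- site_cells(grid, sites)[o$site_idx]
  o
}

# --- public operations ------------------------------------------------------

#' Fuse the simulated total-PM2.5 field with monitor observations
#'
#' Two-step correction, per day: (1) a polynomial of
#' `polynomial_degree` mapping simulated to observed values is fit over
#' collocated pairs (a pooled fit over all days is used when a day has
#' fewer than `min_pairs_per_day` pairs) and applied to the whole field -
#' this removes network-wide amplitude bias; (2) residual ratios
#' obs / corrected at each monitor are interpolated over the grid as
#' log-ratios by tapered inverse-distance weighting and multiplied in -
#' this makes the field track observations near monitors while staying
#' model-shaped far away.  The result is floored at
#' `concentration_floor`.
#'
#' @param sim A `pf_field` (simulated total PM2.5, scenario `all`).
#' @param observations Observation table (only `PM25_TOT` rows are used);
#'   exclude near-road sites first via [exclude_near_road()].
#' @param sites Monitor table (for site locations).
#' @param config A [fusion_config()].
#' @return A `pf_field` with scenario `"fused"`.
#' @export
fuse_total <- function(sim, observations, sites, config = fusion_config()) {
  stopifnot(inherits(sim, "pf_field"), inherits(config, "pf_fusion_config"))
  o <- obs_pairs(observations, sites, sim$grid, sim$dates, "PM25_TOT")
  if (is.null(o) || nrow(o) == 0)
    stop("no usable total-PM2.5 observation/model pairs")
  simv <- sim$values
  o$sim <- simv[cbind(o$day, o$cell)]
  pooled <- poly_fit(o$sim, o$value, config$polynomial_degree)
  if (is.null(pooled)) stop("degenerate fusion input: constant simulated values")

  n_d <- nrow(simv)
  fused <- matrix(NA_real_, n_d, ncol(simv))
  dist <- site_cell_dist(sim$grid, sites)
  by_day <- split(o, o$day)
  for (d in seq_len(n_d)) {
    od <- by_day[[as.character(d)]]
    fit <- pooled
    if (!is.null(od) && nrow(od) >= config$min_pairs_per_day) {
      dayfit <- poly_fit(od$sim, od$value, config$polynomial_degree)
      if (!is.null(dayfit)) fit <- dayfit
    }
    corrected <- pmax(poly_apply(fit, simv[d, ]), config$denom_floor)
    if (!is.null(od) && nrow(od) > 0) {
      r <- clip_ratio(od$value / pmax(corrected[od$cell], config$denom_floor),
                      config$ratio_cap)
      lvals <- rep(NA_real_, nrow(sites))
      lr <- tapply(log(r), od$site_idx, mean)
      lvals[as.integer(names(lr))] <- lr
      L <- idw_interp(dist, lvals, config$idw_power, config$idw_radius_km)
      corrected <- corrected * exp(L)
    }
    fused[d, ] <- pmax(corrected, config$concentration_floor)
  }
  field_series(sim$grid, sim$dates, "PM25_TOT", "fused", fused)
}

#' Observation-adjusted PF impact on total PM2.5
#'
#' Scales the simulated PF delta by the ratio of fused to simulated total
#' concentrations: `delta_DF = delta_sim x fused / max(sim, denom_floor)`,
#' with the multiplier capped at `ratio_cap`.  Where the floor and cap are
#' inactive the PF *fraction* of total mass is preserved exactly by
#' fusion.
#'
#' @param delta_sim Simulated PF delta field (scenario `delta_pf`).
#' @param sim_total Simulated total field.
#' @param fused_total Fused total field from [fuse_total()].
#' @param config A [fusion_config()].
#' @return A `pf_field` with scenario `"fused_delta_pf"`.
#' @export
fuse_pf_total <- function(delta_sim, sim_total, fused_total,
                          config = fusion_config()) {
  stop_if_misaligned(delta_sim, sim_total)
  stop_if_misaligned(delta_sim, fused_total)
  mult <- pmin(fused_total$values / pmax(sim_total$values, config$denom_floor),
               config$ratio_cap)
  field_series(delta_sim$grid, delta_sim$dates, delta_sim$species,
               "fused_delta_pf", delta_sim$values * mult)
}

#' Fuse species-to-total ratios and derive fused component fields
#'
#' Fusing component concentrations directly would break mass balance (the
#' fused components would not sum to the fused total) and suffer from the
#' 1-in-3-day speciation schedule.  Instead the simulated species-to-total
#' ratios are corrected toward observed ratios: at each speciation site on
#' its sampling days the correction `c = r_obs / r_sim` is computed,
#' log-interpolated linearly in time between the site's sampling days
#' (held constant beyond endpoints), interpolated in space by the same
#' tapered IDW as [fuse_total()], and multiplied into the simulated ratio
#' field.  Ratios are clipped to [0, 1], the residual OTHER component is
#' defined by subtraction, and the five-component vector is renormalized
#' to sum exactly 1; fused component concentration = fused ratio x fused
#' total.
#'
#' @param sim_fields Named list of simulated fields including `PM25_TOT`
#'   and the four components (scenario `all`).
#' @param observations Observation table with speciation records (component
#'   and collocated total values from the same sampler).
#' @param sites Monitor table.
#' @param fused_total Fused total field from [fuse_total()].
#' @param config A [fusion_config()].
#' @return List with named lists `ratios` (fused ratio fields, including
#'   `OTHER`) and `species` (fused component concentration fields).
#' @export
fuse_species_ratios <- function(sim_fields, observations, sites, fused_total,
                                config = fusion_config()) {
  tot <- sim_fields[["PM25_TOT"]]
  if (is.null(tot)) stop("sim_fields must include PM25_TOT")
  grid <- tot$grid; dates <- tot$dates
  n_d <- length(dates); n_c <- grid$n_cells
  stop_if_misaligned(tot, fused_total)
  tot_floor <- pmax(tot$values, config$denom_floor)

  o_tot <- obs_pairs(observations, sites, grid, dates, "PM25_TOT")
  has_spec <- FALSE
  dist <- site_cell_dist(grid, sites)
  ratios <- list()
  for (sp in PF_COMPONENTS) {
    f <- sim_fields[[sp]]
    if (is.null(f)) stop(sprintf("sim_fields must include %s", sp))
    stop_if_misaligned(tot, f)
    r_sim <- f$values / tot_floor
    o_sp <- obs_pairs(observations, sites, grid, dates, sp)
    logc_site <- matrix(NA_real_, nrow(sites), n_d)
    if (!is.null(o_sp) && nrow(o_sp) > 0 && !is.null(o_tot)) {
      has_spec <- TRUE
      m <- merge(o_sp, o_tot[, c("site", "day", "value")],
                 by = c("site", "day"), suffixes = c("", "_tot"))
      if (nrow(m) > 0) {
        r_obs <- pmin(pmax(m$value / pmax(m$value_tot, config$denom_floor), 0), 1)
        r_sim_at <- pmax(r_sim[cbind(m$day, m$cell)], 1e-6)
        m$logc <- log(clip_ratio(r_obs / r_sim_at, config$ratio_cap))
        for (si in unique(m$site_idx)) {
          ms <- m[m$site_idx == si, , drop = FALSE]
          ms <- stats::aggregate(logc ~ day, ms, mean)
          logc_site[si, ] <- if (nrow(ms) == 1L) rep(ms$logc, n_d)
            else stats::approx(ms$day, ms$logc, xout = seq_len(n_d),
                               rule = 2)$y
        }
      }
    }
    Lc <- matrix(0, n_d, n_c)
    for (d in seq_len(n_d))
      Lc[d, ] <- idw_interp(dist, logc_site[, d], config$idw_power,
                            config$idw_radius_km)
    ratios[[sp]] <- pmin(pmax(r_sim * exp(Lc), 0), 1)
  }
  if (!has_spec) stop("no speciation observations available for ratio fusion")

  named_sum <- Reduce(`+`, ratios)
  ratios[["OTHER"]] <- pmax(0, 1 - named_sum)
  total_ratio <- named_sum + ratios[["OTHER"]]
  ratio_fields <- list(); spe_fields <- list()
  for (sp in c(PF_COMPONENTS, "OTHER")) {
    rr <- ratios[[sp]] / total_ratio
    ratio_fields[[sp]] <- field_series(grid, dates, sp, "fused", rr)
    spe_fields[[sp]] <- field_series(grid, dates, sp, "fused",
                                     rr * fused_total$values)
  }
  list(ratios = ratio_fields, species = spe_fields)
}

#' Observation-adjusted PF impact for a PM2.5 component
#'
#' `delta_spe_DF = delta_spe_sim x fused_spe / max(sim_spe, denom_floor)`,
#' multiplier capped at `ratio_cap` - the component analogue of
#' [fuse_pf_total()].
#'
#' @param delta_spe_sim Simulated component PF delta.
#' @param sim_spe Simulated component field.
#' @param fused_spe Fused component field from [fuse_species_ratios()].
#' @param config A [fusion_config()].
#' @return A `pf_field` with scenario `"fused_delta_pf"`.
#' @export
fuse_pf_species <- function(delta_spe_sim, sim_spe, fused_spe,
                            config = fusion_config()) {
  stop_if_misaligned(delta_spe_sim, sim_spe)
  stop_if_misaligned(delta_spe_sim, fused_spe)
  mult <- pmin(fused_spe$values / pmax(sim_spe$values, config$denom_floor),
               config$ratio_cap)
  field_series(delta_spe_sim$grid, delta_spe_sim$dates, delta_spe_sim$species,
               "fused_delta_pf", delta_spe_sim$values * mult)
}
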