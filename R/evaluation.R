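#' Air-quality model performance statistics
#'
#' Standard paired model/observation metrics: mean bias (MB), root mean
#' squared error (RMSE), sum-normalized bias and error (NMB, NME, percent),
#' per-pair mean normalized bias and error (MNB, MNE, percent, computed
#' over pairs with observation above `mnb_floor` to avoid division
#' blow-up), and squared Pearson correlation.
#'
#' @param model,observed Numeric vectors of equal length (n >= 2).
#' @param mnb_floor Observation floor (ug/m3) for MNB/MNE pairs.
#' @return A `pf_perf_stats` object (named list): `n`, `MB`, `RMSE`,
#'   `NMB`, `NME`, `MNB`, `MNE`, `r_squared`.
#' @export
compute_stats <- function(model, observed, mnb_floor = 1) {
  if (length(model) != length(observed)) stop("model/observed length mismatch")
  ok <- is.finite(model) & is.finite(observed)
  model <- model[ok]; observed <- observed[ok]
  n <- length(model)
  if (n < 2) stop("need at least 2 pairs")
  if (any(observed < 0)) stop("observed values must be non-negative")
  if (sum(observed) == 0) stop("degenerate input: observations sum to zero")
  d <- model - observed
  nb <- observed >= mnb_floor
  r <- if (stats::sd(model) > 0 && stats::sd(observed) > 0)
    stats::cor(model, observed) else NA_real_
  structure(list(
    n = n,
    MB = mean(d),
    RMSE = sqrt(mean(d^2)),
    NMB = 100 * sum(d) / sum(observed),
    NME = 100 * sum(abs(d)) / sum(observed),
    MNB = if (any(nb)) 100 * mean(d[nb] / observed[nb]) else NA_real_,
    MNE = if (any(nb)) 100 * mean(abs(d[nb]) / observed[nb]) else NA_real_,
    r_squared = r^2
  ), class = "pf_perf_stats")
}

#' @export
print.pf_perf_stats <- function(x, ...) {
  cat(sprintf(
    "pf_perf_stats: n=%d MB=%.3f RMSE=%.3f NMB=%.1f%% NME=%.1f%% MNB=%.1f%% MNE=%.1f%% R2=%.3f\n",
    x$n, x$MB, x$RMSE, x$NMB, x$NME, x$MNB, x$MNE, x$r_squared))
  invisible(x)
}

#' Site-held-out k-fold cross-validation of the total-PM2.5 fusion
#'
#' Monitoring sites (near-road sites excluded) are partitioned into `k`
#' random folds.  For each fold the fusion is refit with that fold's
#' observations withheld; fused values at the withheld sites' cells are
#' then compared against the withheld observations.  Folds are by site,
#' not by observation, because the fusion interpolates spatially and
#' record-level folds would leak information through neighboring days at
#' the same site.
#'
#' @param sim Simulated total-PM2.5 `pf_field`.
#' @param observations Observation table (PM25_TOT rows used).
#' @param sites Monitor table.
#' @param k Number of folds (>= 2).
#' @param config A [fusion_config()].
#' @param seed Integer seed for the fold assignment.
#' @return List: `pooled` (list with `sim` and `fused` [compute_stats()]
#'   over all held-out pairs), `folds` (per-fold stats), `assignments`
#'   (site id -> fold).
#' @export
kfold_cv <- function(sim, observations, sites, k = 10,
                     config = fusion_config(), seed = 1) {
  if (k < 2) stop("k must be >= 2")
  usable <- sites[!sites$near_road, , drop = FALSE]
  obs <- exclude_near_road(observations, sites)
  obs <- obs[obs$species == "PM25_TOT", , drop = FALSE]
  cv_sites <- intersect(usable$id, unique(obs$site))
  if (length(cv_sites) < k) stop("need at least k sites with observations")
  fold <- with_seed(seed, {
    sample(rep_len(seq_len(k), length(cv_sites)))
  })
  names(fold) <- cv_sites

  pooled_sim <- c(); pooled_obs <- c(); pooled_fused <- c()
  per_fold <- vector("list", k)
  cells <- stats::setNames(site_cells(sim$grid, usable), usable$id)
  for (j in seq_len(k)) {
    test_sites <- cv_sites[fold == j]
    train_obs <- obs[!obs$site %in% test_sites, , drop = FALSE]
    fused <- fuse_total(sim, train_obs, usable, config)
    test <- obs[obs$site %in% test_sites, , drop = FALSE]
    day <- match(as.Date(test$date), sim$dates)
    keep <- !is.na(day)
    test <- test[keep, , drop = FALSE]; day <- day[keep]
    cell <- cells[test$site]
    m_sim <- sim$values[cbind(day, cell)]
    m_fus <- fused$values[cbind(day, cell)]
    per_fold[[j]] <- list(sim = compute_stats(m_sim, test$value),
                          fused = compute_stats(m_fus, test$value))
    pooled_sim <- c(pooled_sim, m_sim)
    pooled_fused <- c(pooled_fused, m_fus)
    pooled_obs <- c(pooled_obs, test$value)
  }
  list(pooled = list(sim = compute_stats(pooled_sim, pooled_obs),
                     fused = compute_stats(pooled_fused, pooled_obs)),
       folds = per_fold,
       assignments = fold)
}

#' Model-performance benchmark flags
#'
#' Compares statistics against configured thresholds in the style of the
#' photochemical-model benchmarks of Emery et al.: goals |NMB| <= 10%,
#' NME <= 35%; criteria |NMB| <= 30%, NME <= 50%.
#'
#' @param stats A [compute_stats()] result.
#' @param thresholds Named list; entries `nmb_abs` and/or `nme` per level,
#'   see [emery_benchmarks()].
#' @return Named logical vector, one flag per configured criterion.
#' @export
benchmark_flags <- function(stats, thresholds = emery_benchmarks()) {
  out <- logical(0)
  for (nm in names(thresholds)) {
    th <- thresholds[[nm]]
    pass <- TRUE
    if (!is.null(th$nmb_abs)) pass <- pass && abs(stats$NMB) <= th$nmb_abs
    if (!is.null(th$nme)) pass <- pass && stats$NME <= th$nme
    out[nm] <- pass
  }
  out
}

#' Default PM2.5 performance benchmark thresholds
#' @return Named list of threshold sets for [benchmark_flags()].
#' @export
emery_benchmarks <- function() {
  list(goal = list(nmb_abs = 10, nme = 35),
       criteria = list(nmb_abs = 30, nme = 50))
}

#' Count cell-days where the estimated PF impact exceeds the observed total
#'
#' The observed-vs-PF scatter diagnostic: an estimated PF contribution
#' larger than the collocated observed *total* PM2.5 is physically
#' unrealistic (smoke predicted to hit a monitor that it missed).  Fusion
#' should reduce the number of such cases.
#'
#' @param delta PF delta `pf_field` (simulated or fused).
#' @param observations Observation table (PM25_TOT rows used).
#' @param sites Monitor table.
#' @return Integer count of monitor cell-days with `delta > observed`.
#' @export
count_pf_exceeds_obs <- function(delta, observations, sites) {
  o <- obs_pairs(observations, sites, delta$grid, delta$dates, "PM25_TOT")
  if (is.null(o) || nrow(o) == 0) return(0L)
  sum(delta$values[cbind(o$day, o$cell)] > o$value)
}
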