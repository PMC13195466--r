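#' Exact coverage weights of a polygon over grid cells
#'
#' For every grid cell intersected by the polygon, the coverage fraction is
#' the area of the polygon-cell intersection divided by the cell area,
#' computed by exact polygon-rectangle clipping (Sutherland-Hodgman) and
#' the shoelace formula.  Planar geometry in the grid's km coordinate
#' frame.
#'
#' @param grid A `pf_grid`.
#' @param polygon Two-column matrix (or data.frame) of vertex x/y
#'   coordinates (km); closed automatically, either winding order.
#' @return A `pf_zonal_weights` object: data.frame (`cell`, `fraction`)
#'   with the grid attached; fractions in (0, 1].
#' @export
compute_coverage_weights <- function(grid, polygon) {
  stopifnot(inherits(grid, "pf_grid"))
  poly <- as.matrix(polygon)
  if (ncol(poly) != 2 || nrow(poly) < 3) stop("polygon needs >= 3 x/y vertices")
  cs <- grid$cell_size_km; org <- grid$origin
  # candidate cells: polygon bounding box
  c0 <- max(1L, floor((min(poly[, 1]) - org[1]) / cs) + 1L)
  c1 <- min(grid$n_cols, ceiling((max(poly[, 1]) - org[1]) / cs))
  r0 <- max(1L, floor((min(poly[, 2]) - org[2]) / cs) + 1L)
  r1 <- min(grid$n_rows, ceiling((max(poly[, 2]) - org[2]) / cs))
  if (c1 < c0 || r1 < r0) stop("polygon does not intersect the grid")
  cells <- integer(0); fracs <- numeric(0)
  for (cc in c0:c1) {
    xlo <- org[1] + (cc - 1) * cs; xhi <- xlo + cs
    for (rr in r0:r1) {
      ylo <- org[2] + (rr - 1) * cs; yhi <- ylo + cs
      a <- clip_area_rect(poly, xlo, xhi, ylo, yhi)
      if (a > 1e-12 * grid$cell_area_km2) {
        cells <- c(cells, cell_index(grid, rr, cc))
        fracs <- c(fracs, min(a / grid$cell_area_km2, 1))
      }
    }
  }
  if (!length(cells)) stop("polygon does not intersect the grid")
  structure(data.frame(cell = cells, fraction = fracs),
            grid = grid, class = c("pf_zonal_weights", "data.frame"))
}

# Sutherland-Hodgman clip of a polygon against an axis-aligned rectangle,
# returning the absolute area of the clipped polygon (shoelace).
clip_area_rect <- function(poly, xlo, xhi, ylo, yhi) {
  clip_halfplane <- function(p, inside, intersect) {
    n <- nrow(p)
    if (n == 0) return(p)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      cur <- p[i, ]; prev <- p[if (i == 1) n else i - 1, ]
      cin <- inside(cur); pin <- inside(prev)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(a, b, x) {  # intersection with vertical line at x
    t <- (x - a[1]) / (b[1] - a[1]); c(x, a[2] + t * (b[2] - a[2]))
  }
  iy <- function(a, b, y) {
    t <- (y - a[2]) / (b[2] - a[2]); c(a[1] + t * (b[1] - a[1]), y)
  }
  p <- poly
  p <- clip_halfplane(p, function(v) v[1] >= xlo, function(a, b) ix(a, b, xlo))
  p <- clip_halfplane(p, function(v) v[1] <= xhi, function(a, b) ix(a, b, xhi))
  p <- clip_halfplane(p, function(v) v[2] >= ylo, function(a, b) iy(a, b, ylo))
  p <- clip_halfplane(p, function(v) v[2] <= yhi, function(a, b) iy(a, b, yhi))
  shoelace_area(p)
}

shoelace_area <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

#' Area-weighted zonal daily mean of a field
#'
#' Per day: `sum(value x fraction x cell_area) / sum(fraction x cell_area)`
#' over the weight entries - the weighted spatial mean of the field over
#' the region the weights describe.
#'
#' @param field A `pf_field`.
#' @param weights A [compute_coverage_weights()] result on the same grid.
#' @param floor_zero Clamp negative daily values (of delta fields) to 0.
#' @return data.frame: `date`, `value`.
#' @export
weighted_daily_mean <- function(field, weights, floor_zero = FALSE) {
  stopifnot(inherits(field, "pf_field"), inherits(weights, "pf_zonal_weights"))
  if (!same_grid(field$grid, attr(weights, "grid")))
    stop("weights were computed on a different grid")
  w <- weights$fraction * field$grid$cell_area_km2
  v <- as.vector(field$values[, weights$cell, drop = FALSE] %*% w) / sum(w)
  if (floor_zero) v <- pmax(v, 0)
  data.frame(date = field$dates, value = v)
}

#' Seasonal and annual summary of a daily series
#'
#' Arithmetic mean, sample SD, and median of the daily values within each
#' (year, season) stratum, per season pooled across years, per year, and
#' overall.  Empty strata are simply absent (missing, never zero-filled).
#'
#' @param daily data.frame with `date` and `value` columns.
#' @param seasons A [season_definition()].
#' @return data.frame: `year`, `season`, `n`, `mean`, `sd`, `median`.
#'   Pooled rows carry `"all"` in the pooled dimension.
#' @export
period_summary <- function(daily, seasons = season_definition()) {
  if (nrow(daily) == 0) stop("empty daily series")
  date <- as.Date(daily$date)
  year <- format(date, "%Y")
  season <- season_of(date, seasons)
  strat <- function(y, s, sel) {
    v <- daily$value[sel]
    data.frame(year = y, season = s, n = length(v), mean = mean(v),
               sd = stats::sd(v), median = stats::median(v),
               stringsAsFactors = FALSE)
  }
  season_levels <- unique(unname(unclass(seasons)))
  out <- list()
  for (y in sort(unique(year)))
    for (s in intersect(season_levels, season[year == y]))
      out[[length(out) + 1]] <- strat(y, s, year == y & season == s)
  for (y in sort(unique(year)))
    out[[length(out) + 1]] <- strat(y, "all", year == y)
  for (s in intersect(season_levels, season))
    out[[length(out) + 1]] <- strat("all", s, season == s)
  out[[length(out) + 1]] <- strat("all", "all", rep(TRUE, nrow(daily)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' PF share of ambient concentration
#'
#' Period share = 100 x mean(PF daily) / mean(ambient daily) over the
#' aligned dates (ratio of period means, not mean of daily ratios); daily
#' shares are also returned.
#'
#' @param pf_daily,ambient_daily data.frames (`date`, `value`) on matching
#'   dates.
#' @return List: `period_pct` (scalar percent), `daily` (data.frame with
#'   `date`, `pf`, `ambient`, `share_pct`).
#' @export
pf_share <- function(pf_daily, ambient_daily) {
  m <- merge(pf_daily, ambient_daily, by = "date",
             suffixes = c("_pf", "_ambient"))
  if (nrow(m) == 0) stop("series share no dates")
  amb_mean <- mean(m$value_ambient)
  if (amb_mean <= 0) stop("degenerate input: ambient period mean is zero")
  list(period_pct = 100 * mean(m$value_pf) / amb_mean,
       daily = data.frame(date = m$date, pf = m$value_pf,
                          ambient = m$value_ambient,
                          share_pct = 100 * m$value_pf /
                            ifelse(m$value_ambient > 0, m$value_ambient, NA)))
}

#' Exceedance statistics for a field and its zonal daily series
#'
#' Fraction of grid-cell-days at or above `threshold`, and (when `daily`
#' is supplied) the count of days whose regional daily mean is at or above
#' the threshold.
#'
#' @param field A `pf_field`.
#' @param threshold Concentration threshold (ug/m3), > 0.
#' @param daily Optional zonal daily-mean series from
#'   [weighted_daily_mean()].
#' @return List: `cell_day_fraction`, `n_cell_days`, `n_days_regional`
#'   (NA without `daily`).
#' @export
exceedance_stats <- function(field, threshold, daily = NULL) {
  stopifnot(inherits(field, "pf_field"))
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  total <- length(field$values)
  list(cell_day_fraction = sum(field$values >= threshold) / total,
       n_cell_days = total,
       n_days_regional = if (is.null(daily)) NA_integer_
                         else sum(daily$value >= threshold))
}
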