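#' Match satellite and permit burned areas on gridded daily keys
#'
#' Areas are summed within each (cell, date) key.  A pair is emitted for
#' every key where the satellite total is positive; the permit total is 0
#' when no permit record exists for that key (discarding those keys would
#' bias the calibration slope upward).  Permit-only keys are not paired.
#'
#' @param satellite,permits Burn-event tables.
#' @param grid The shared `pf_grid` (validates cell indices).
#' @return data.frame: `date`, `row`, `col`, `satellite_area`, `permit_area`.
#' @export
match_pairs <- function(satellite, permits, grid) {
  stopifnot(inherits(grid, "pf_grid"))
  check_events(satellite)
  check_events(permits)
  cell_index(grid, satellite$row, satellite$col)   # validates extent
  if (nrow(permits) > 0) cell_index(grid, permits$row, permits$col)
  if (nrow(satellite) == 0)
    return(data.frame(date = as.Date(character()), row = integer(),
                      col = integer(), satellite_area = numeric(),
                      permit_area = numeric()))
  sat <- stats::aggregate(area ~ date + row + col, satellite, sum)
  names(sat)[4] <- "satellite_area"
  if (nrow(permits) > 0) {
    per <- stats::aggregate(area ~ date + row + col, permits, sum)
    names(per)[4] <- "permit_area"
    out <- merge(sat, per, by = c("date", "row", "col"), all.x = TRUE)
    out$permit_area[is.na(out$permit_area)] <- 0
  } else {
    out <- sat
    out$permit_area <- 0
  }
  out <- out[order(out$date, out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the satellite-to-permit area calibration
#'
#' Least-squares regression of permit area on satellite area over matched
#' gridded daily pairs, through the origin by default (a single scaling
#' factor).  The fitted slope rescales satellite burned areas to the
#' permit scale.
#'
#' @param pairs Output of [match_pairs()], or any data.frame with
#'   `satellite_area` and `permit_area` columns.
#' @param intercept Include an intercept term (default FALSE).
#' @return A `pf_calibration` object: `slope`, `intercept`, `n_pairs`,
#'   `r_squared`, `residual_sd`.
#' @export
fit_scaling <- function(pairs, intercept = FALSE) {
  ok <- pairs$satellite_area > 0
  if (sum(ok) < 2) stop("need at least 2 pairs with positive satellite area")
  x <- pairs$satellite_area[ok]
  y <- pairs$permit_area[ok]
  fit <- if (intercept) stats::lm(y ~ x) else stats::lm(y ~ x + 0)
  slope <- unname(stats::coef(fit)[if (intercept) "x" else "x"])
  icpt <- if (intercept) unname(stats::coef(fit)["(Intercept)"]) else 0
  if (!is.finite(slope) || slope <= 0)
    stop("degenerate calibration: non-positive fitted slope")
  res <- stats::residuals(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  structure(list(slope = slope, intercept = icpt, n_pairs = sum(ok),
                 r_squared = r2,
                 residual_sd = stats::sd(res)),
            class = "pf_calibration")
}

#' @export
print.pf_calibration <- function(x, ...) {
  cat(sprintf("pf_calibration: slope %.4f (intercept %.3f), n = %d, R2 = %.3f\n",
              x$slope, x$intercept, x$n_pairs, x$r_squared))
  invisible(x)
}

#' Apply an area calibration to satellite events
#'
#' Multiplies every event's area by the fitted slope (plus intercept if
#' one was fit); all other fields, the event count and ordering are
#' unchanged.
#' @param satellite Burn-event table.
#' @param model A [fit_scaling()] result.
#' @return Calibrated event table.
#' @export
apply_calibration <- function(satellite, model) {
  stopifnot(inherits(model, "pf_calibration"))
  if (model$slope <= 0) stop("calibration slope must be positive")
  check_events(satellite)
  out <- satellite
  out$area <- pmax(model$intercept + model$slope * satellite$area, 0)
  out
}

#' Burn-activity summary by year, season, and ownership
#'
#' @param events Burn-event table; an optional `region` column adds a
#'   `by_region` table (e.g. per-state totals and shares).
#' @param seasons A [season_definition()].
#' @return List of data.frames: `by_year`, `by_season`, `by_ownership`
#'   (and `by_region` when available), each with total acres and `share`
#'   of the grand total, plus `total_acres` and `acres_per_year` (grand
#'   total / number of calendar years spanned).
#' @export
burn_summary <- function(events, seasons = season_definition()) {
  check_events(events)
  if (nrow(events) == 0) stop("no events to summarize")
  year <- as.integer(format(as.Date(events$date), "%Y"))
  season <- season_of(events$date, seasons)
  total <- sum(events$area)
  mk <- function(key, name) {
    t <- stats::aggregate(events$area, list(key), sum)
    names(t) <- c(name, "acres")
    t$share <- t$acres / total
    t
  }
  n_years <- max(year) - min(year) + 1L
  out <- list(by_year = mk(year, "year"),
              by_season = mk(season, "season"),
              by_ownership = mk(events$ownership, "ownership"),
              total_acres = total,
              acres_per_year = total / n_years)
  if (!is.null(events$region)) out$by_region <- mk(events$region, "region")
  out
}
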