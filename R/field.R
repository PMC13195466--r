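#' Species labels used throughout the pipeline
#'
#' Total fine particulate mass plus its speciated components: elemental
#' carbon, organic carbon, nitrate, sulfate, and the residual "other"
#' (crustal material, ammonium, metals, ...).
#' @export
PF_SPECIES <- c("PM25_TOT", "EC", "OC", "NO3", "SO4", "OTHER")

#' The four directly speciated components (excludes total and OTHER)
#' @export
PF_COMPONENTS <- c("EC", "OC", "NO3", "SO4")

pf_scenarios <- c("all", "no_pf", "delta_pf", "fused", "fused_delta_pf", "truth")

#' Daily gridded concentration series for one species and scenario
#'
#' Values are stored as a dense `n_days x n_cells` matrix (cells in linear
#' id order, see [cell_index()]), concentrations in ug/m3.  Delta scenarios
#' (`delta_pf`, `fused_delta_pf`) may be negative; all others must be
#' non-negative.
#'
#' @param grid A `pf_grid`.
#' @param dates Ordered `Date` vector, one per matrix row.
#' @param species One of `PF_SPECIES`.
#' @param scenario One of `"all"`, `"no_pf"`, `"delta_pf"`, `"fused"`,
#'   `"fused_delta_pf"`, `"truth"`.
#' @param values `length(dates) x grid$n_cells` numeric matrix (ug/m3).
#' @return A `pf_field` object.
#' @export
field_series <- function(grid, dates, species, scenario, values) {
  stopifnot(inherits(grid, "pf_grid"))
  dates <- as.Date(dates)
  if (is.unsorted(dates, strictly = TRUE)) stop("dates must be strictly increasing")
  species <- match.arg(species, PF_SPECIES)
  scenario <- match.arg(scenario, pf_scenarios)
  values <- as.matrix(values)
  if (nrow(values) != length(dates) || ncol(values) != grid$n_cells)
    stop("values must be length(dates) x grid$n_cells")
  if (!all(is.finite(values))) stop("field values must be finite")
  if (!scenario %in% c("delta_pf", "fused_delta_pf") && any(values < 0))
    stop(sprintf("scenario '%s' fields must be non-negative", scenario))
  structure(list(grid = grid, dates = dates, species = species,
                 scenario = scenario, values = values),
            class = "pf_field")
}

#' @export
print.pf_field <- function(x, ...) {
  cat(sprintf("pf_field: %s [%s], %d days (%s .. %s) on %dx%d grid, mean %.3g ug/m3\n",
              x$species, x$scenario, length(x$dates),
              format(min(x$dates)), format(max(x$dates)),
              x$grid$n_rows, x$grid$n_cols, mean(x$values)))
  invisible(x)
}

fields_aligned <- function(a, b) {
  same_grid(a$grid, b$grid) && length(a$dates) == length(b$dates) &&
    all(a$dates == b$dates)
}

stop_if_misaligned <- function(a, b, what = "fields") {
  if (!fields_aligned(a, b))
    stop(sprintf("%s are misaligned: grids or dates differ", what))
  invisible(TRUE)
}

#' Pair of simulations with and without prescribed-fire emissions
#'
#' The zero-out design: a baseline run with all emissions and a second run
#' identical except prescribed-fire emissions are removed.  Both members are
#' named lists of [field_series()] objects (one per species) sharing grid,
#' dates and species set.
#'
#' @param all_emissions,no_pf Named lists of `pf_field` (names = species).
#' @return A `pf_scenario_pair` object.
#' @export
scenario_pair <- function(all_emissions, no_pf) {
  if (!setequal(names(all_emissions), names(no_pf)))
    stop("scenario members must share the same species set")
  for (sp in names(all_emissions)) {
    a <- all_emissions[[sp]]; b <- no_pf[[sp]]
    stopifnot(inherits(a, "pf_field"), inherits(b, "pf_field"))
    stop_if_misaligned(a, b, sprintf("scenario members for %s", sp))
  }
  structure(list(all_emissions = all_emissions, no_pf = no_pf),
            class = "pf_scenario_pair")
}

#' @export
print.pf_scenario_pair <- function(x, ...) {
  f <- x$all_emissions[[1]]
  cat(sprintf("pf_scenario_pair: species {%s}, %d days on %dx%d grid\n",
              paste(names(x$all_emissions), collapse = ", "),
              length(f$dates), f$grid$n_rows, f$grid$n_cols))
  invisible(x)
}

#' Write / read a field series as long-format CSV
#'
#' Columns: `date` (ISO-8601), `row`, `col`, `value` plus constant `species`
#' and `scenario`.  A plain-text stand-in for a gridded binary format so
#' pipeline stages can exchange fields through files.
#' @param field A `pf_field`.
#' @param path Output CSV path.
#' @export
write_field_csv <- function(field, path) {
  rc <- cell_rowcol(field$grid, seq_len(field$grid$n_cells))
  n_d <- length(field$dates); n_c <- field$grid$n_cells
  df <- data.frame(
    date = rep(format(field$dates), times = n_c),
    row = rep(rc$row, each = n_d),
    col = rep(rc$col, each = n_d),
    species = field$species,
    scenario = field$scenario,
    value = as.vector(field$values)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @param grid The `pf_grid` the file was written on.
#' @export
read_field_csv <- function(path, grid) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dates <- sort(unique(as.Date(df$date)))
  values <- matrix(0, length(dates), grid$n_cells)
  d_idx <- match(as.Date(df$date), dates)
  c_idx <- cell_index(grid, df$row, df$col)
  values[cbind(d_idx, c_idx)] <- df$value
  field_series(grid, dates, df$species[1], df$scenario[1], values)
}
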