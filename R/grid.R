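#' Define a rectangular model grid
#'
#' The spatial frame for every gridded object in the pipeline: a regular
#' `n_rows` x `n_cols` raster of square cells of side `cell_size_km`,
#' anchored at `origin` (the lower-left corner, planar km coordinates).
#' Cells are indexed by `(row, col)` with row 1 at the bottom; the linear
#' cell id runs column-major, matching R's matrix layout.
#'
#' @param n_rows,n_cols Number of rows and columns (>= 1).
#' @param cell_size_km Cell side length in km (default 12, a typical
#'   regional chemical-transport-model resolution).
#' @param origin Numeric length-2, x/y of the grid's lower-left corner (km).
#' @return An object of class `pf_grid` with fields `n_rows`, `n_cols`,
#'   `cell_size_km`, `origin`, `cell_area_km2`, `n_cells`.
#' @examples
#' g <- grid_definition(30, 30)
#' g$cell_area_km2  # 144
#' @export
grid_definition <- function(n_rows, n_cols, cell_size_km = 12, origin = c(0, 0)) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("n_rows and n_cols must be integers >= 1")
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1L || cell_size_km <= 0)
    stop("cell_size_km must be a positive scalar")
  if (length(origin) != 2L || !is.numeric(origin))
    stop("origin must be a numeric length-2 vector")
  structure(list(
    n_rows = n_rows, n_cols = n_cols,
    cell_size_km = cell_size_km,
    origin = as.numeric(origin),
    cell_area_km2 = cell_size_km^2,
    n_cells = n_rows * n_cols
  ), class = "pf_grid")
}

#' @export
print.pf_grid <- function(x, ...) {
  cat(sprintf("pf_grid: %d x %d cells of %g km (%g km2 each), origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size_km, x$cell_area_km2,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' Linear cell id from (row, col)
#'
#' Column-major: `id = (col - 1) * n_rows + row`.
#' @param grid A `pf_grid`.
#' @param row,col Integer vectors of equal length.
#' @return Integer vector of cell ids in `[1, n_cells]`.
#' @export
cell_index <- function(grid, row, col) {
  stopifnot(inherits(grid, "pf_grid"))
  row <- as.integer(row); col <- as.integer(col)
  bad <- row < 1L | row > grid$n_rows | col < 1L | col > grid$n_cols
  if (any(bad, na.rm = TRUE) || anyNA(row) || anyNA(col))
    stop("cell (row, col) outside grid extent")
  (col - 1L) * grid$n_rows + row
}

#' (row, col) from linear cell id
#' @param grid A `pf_grid`.
#' @param id Integer vector of cell ids.
#' @return data.frame with columns `row`, `col`.
#' @export
cell_rowcol <- function(grid, id) {
  stopifnot(inherits(grid, "pf_grid"))
  id <- as.integer(id)
  if (anyNA(id) || any(id < 1L | id > grid$n_cells))
    stop("cell id outside grid")
  data.frame(row = (id - 1L) %% grid$n_rows + 1L,
             col = (id - 1L) %/% grid$n_rows + 1L)
}

#' Planar centers of all grid cells
#' @param grid A `pf_grid`.
#' @return `n_cells` x 2 matrix of (x, y) centers in km, in cell-id order.
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "pf_grid"))
  rc <- cell_rowcol(grid, seq_len(grid$n_cells))
  cbind(x = grid$origin[1] + (rc$col - 0.5) * grid$cell_size_km,
        y = grid$origin[2] + (rc$row - 0.5) * grid$cell_size_km)
}

same_grid <- function(a, b) {
  identical(a$n_rows, b$n_rows) && identical(a$n_cols, b$n_cols) &&
    isTRUE(all.equal(a$cell_size_km, b$cell_size_km)) &&
    isTRUE(all.equal(a$origin, b$origin))
}
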