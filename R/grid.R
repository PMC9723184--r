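#' Define the 1-km analysis lattice
#'
#' All stages of the pipeline operate on a common rectangular grid of square
#' cells. Coordinates are planar; cells are half-open,
#' `[x0, x0 + cell) x [y0, y0 + cell)`, so every point belongs to exactly one
#' cell. Cell ids run row-major from the top-left cell (row 1, column 1),
#' matching the storage order of the landscape matrices.
#'
#' @param n_rows,n_cols Positive integer grid dimensions (cells).
#' @param cell_size Side length of a square cell, in km. Default 1.
#' @return An object of class `grid_definition`.
#' @export
#' @examples
#' g <- grid_definition(10, 12)
#' n_cells(g)
grid_definition <- function(n_rows, n_cols, cell_size = 1) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      n_rows < 1 || n_cols < 1 ||
      n_rows != as.integer(n_rows) || n_cols != as.integer(n_cols)) {
    stop("grid dimensions must be positive integers", call. = FALSE)
  }
  if (n_rows * n_cols < 4) {
    stop("grid must contain at least 4 cells", call. = FALSE)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = cell_size),
    class = "grid_definition"
  )
}

#' @rdname grid_definition
#' @param grid A `grid_definition`.
#' @export
n_cells <- function(grid) grid$n_rows * grid$n_cols

#' @export
print.grid_definition <- function(x, ...) {
  cat(sprintf("<grid_definition> %d x %d cells of %g km (%d cells)\n",
              x$n_rows, x$n_cols, x$cell_size, n_cells(x)))
  invisible(x)
}

#' Map planar coordinates to cell ids
#'
#' Uses the half-open cell convention: a point on a shared cell edge belongs
#' to the cell whose origin it touches. `x` runs along columns, `y` along
#' rows, both starting at 0 at the top-left grid corner.
#'
#' @param grid A `grid_definition`.
#' @param x,y Numeric coordinate vectors (km).
#' @return Integer cell ids (row-major, 1-based).
#' @export
cell_id_at <- function(grid, x, y) {
  col <- floor(x / grid$cell_size) + 1L
  row <- floor(y / grid$cell_size) + 1L
  bad <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows
  if (any(bad)) stop("coordinates fall outside the grid", call. = FALSE)
  as.integer((row - 1L) * grid$n_cols + col)
}

#' @rdname cell_id_at
#' @param cell_id Integer cell ids.
#' @return `cell_center()`: a data.frame with `x`, `y` cell-center coordinates.
#' @export
cell_center <- function(grid, cell_id) {
  cell_id <- as.integer(cell_id)
  if (any(cell_id < 1L | cell_id > n_cells(grid))) {
    stop("cell_id out of range", call. = FALSE)
  }
  row <- (cell_id - 1L) %/% grid$n_cols + 1L
  col <- (cell_id - 1L) %% grid$n_cols + 1L
  data.frame(
    x = (col - 0.5) * grid$cell_size,
    y = (row - 0.5) * grid$cell_size
  )
}

same_grid <- function(a, b) {
  identical(a$n_rows, b$n_rows) && identical(a$n_cols, b$n_cols) &&
    isTRUE(all.equal(a$cell_size, b$cell_size))
}
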