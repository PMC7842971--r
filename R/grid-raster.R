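#' Grid specification
#'
#' A `grid_spec` fully determines a north-up analysis grid: upper-left corner
#' in map coordinates, cell sizes in map units, row/column counts and a CRS
#' identifier. Row indices increase southward, column indices eastward, and
#' all point semantics in the package (sampling, interpolation) refer to cell
#' centers. Two rasters are *aligned* iff their `grid_spec`s are equal.
#'
#' @param origin_x,origin_y Map coordinates of the upper-left corner of the
#'   upper-left cell.
#' @param cell_size_x,cell_size_y Cell dimensions in map units; both must be
#'   strictly positive (the northward decrease of y is implied by the
#'   north-up convention, not by a negative size).
#' @param n_rows,n_cols Grid dimensions.
#' @param crs_id Free-text coordinate reference system identifier (e.g. an
#'   EPSG code string). Used only for equality checks; no reprojection is
#'   performed by this package.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size_x, cell_size_y,
                      n_rows, n_cols, crs_id = "local") {
  stopifnot(cell_size_x > 0, cell_size_y > 0, n_rows >= 1, n_cols >= 1)
  structure(list(origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 cell_size_x = as.numeric(cell_size_x),
                 cell_size_y = as.numeric(cell_size_y),
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 crs_id = as.character(crs_id)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g x %g, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size_x, x$cell_size_y,
              x$origin_x, x$origin_y, x$crs_id))
  invisible(x)
}

#' Test whether two grid specifications describe the same grid
#'
#' @param a,b `grid_spec` objects.
#' @param tol Relative tolerance on origin and cell size comparisons.
#' @return Logical scalar.
#' @export
specs_equal <- function(a, b, tol = 1e-9) {
  num_ok <- function(u, v) abs(u - v) <= tol * max(1, abs(u), abs(v))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols && a$crs_id == b$crs_id &&
    num_ok(a$origin_x, b$origin_x) && num_ok(a$origin_y, b$origin_y) &&
    num_ok(a$cell_size_x, b$cell_size_x) && num_ok(a$cell_size_y, b$cell_size_y)
}

#' Multi-band gridded raster
#'
#' The universal raster currency of the package: an `n_rows x n_cols x n_bands`
#' numeric array tied to a [grid_spec()]. Missing cells are stored as `NA`
#' internally; the `nodata` sentinel is only used when reading and writing
#' files. All bands share one grid.
#'
#' @param values Numeric array `(rows, cols, bands)`, or a matrix (single
#'   band), or a single value to fill the grid with.
#' @param spec A [grid_spec()]. Its dimensions must match `values`.
#' @param band_names Character vector, one name per band.
#' @param nodata Sentinel written in place of `NA` on file output.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, spec, band_names = NULL, nodata = -9999) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) == 2L)
    values <- array(values, dim = c(spec$n_rows, spec$n_cols, 1L))
  if (length(dim(values)) != 3L)
    stop("`values` must be a (rows, cols, bands) array or a matrix")
  if (dim(values)[1] != spec$n_rows || dim(values)[2] != spec$n_cols)
    stop(sprintf("values are %d x %d but spec is %d x %d",
                 dim(values)[1], dim(values)[2], spec$n_rows, spec$n_cols))
  nb <- dim(values)[3]
  if (is.null(band_names)) band_names <- paste0("band_", seq_len(nb))
  if (length(band_names) != nb)
    stop("band_names length must equal the number of bands")
  if (anyDuplicated(band_names)) stop("band names must be unique")
  storage.mode(values) <- "double"
  structure(list(values = values, band_names = as.character(band_names),
                 spec = spec, nodata = nodata),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %d band(s) [%s] on ", n_bands(x),
              paste(x$band_names, collapse = ", ")))
  print(x$spec)
  v <- x$values
  cat(sprintf("  finite cells: %d / %d; range [%g, %g]\n",
              sum(is.finite(v)), length(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' @rdname grid_raster
#' @param x A `grid_raster`.
#' @export
n_bands <- function(x) dim(x$values)[3]

#' Extract one band as a matrix
#' @param x A `grid_raster`.
#' @param band Band index or name.
#' @return Numeric matrix `(rows x cols)`.
#' @export
band_matrix <- function(x, band = 1L) {
  if (is.character(band)) {
    band <- match(band, x$band_names)
    if (is.na(band)) stop("unknown band name")
  }
  x$values[, , band, drop = TRUE]
}

#' Cell-center coordinates of a grid
#'
#' @param spec A [grid_spec()].
#' @param rows,cols Integer indices (recycled together). If `NULL`, all cells
#'   in row-major order.
#' @return A data.frame with columns `row`, `col`, `x`, `y`.
#' @export
cell_centers <- function(spec, rows = NULL, cols = NULL) {
  if (is.null(rows)) {
    rows <- rep(seq_len(spec$n_rows), each = spec$n_cols)
    cols <- rep(seq_len(spec$n_cols), times = spec$n_rows)
  }
  data.frame(row = rows, col = cols,
             x = spec$origin_x + (cols - 0.5) * spec$cell_size_x,
             y = spec$origin_y - (rows - 0.5) * spec$cell_size_y)
}

#' Locate map coordinates on a grid
#'
#' @param spec A [grid_spec()].
#' @param x,y Map coordinates.
#' @return data.frame with integer `row`, `col` (NA when outside the grid).
#' @export
cell_index <- function(spec, x, y) {
  col <- floor((x - spec$origin_x) / spec$cell_size_x) + 1L
  row <- floor((spec$origin_y - y) / spec$cell_size_y) + 1L
  bad <- row < 1L | row > spec$n_rows | col < 1L | col > spec$n_cols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' @rdname grid_raster
#' @export
is_aligned <- function(x, y) specs_equal(x$spec, y$spec)

# extent as xmin/xmax/ymin/ymax, for error messages and overlap checks
spec_extent <- function(s) {
  c(xmin = s$origin_x, xmax = s$origin_x + s$n_cols * s$cell_size_x,
    ymin = s$origin_y - s$n_rows * s$cell_size_y, ymax = s$origin_y)
}

fmt_extent <- function(e)
  sprintf("[x %g..%g, y %g..%g]", e["xmin"], e["xmax"], e["ymin"], e["ymax"])

#' Serialize / restore a grid specification as JSON
#'
#' @param spec A [grid_spec()]; `path` a file path.
#' @return `spec_to_json` returns `path` invisibly; `spec_from_json` a
#'   `grid_spec`.
#' @export
spec_to_json <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname spec_to_json
#' @param path JSON file written by `spec_to_json`.
#' @export
spec_from_json <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid_spec(s$origin_x, s$origin_y, s$cell_size_x, s$cell_size_y,
            s$n_rows, s$n_cols, s$crs_id)
}

#' Apply a function cell-wise, preserving NoData
#'
#' Per-cell arithmetic that keeps `NA` cells `NA` (the NoData-through
#' invariant of the data model).
#'
#' @param x A `grid_raster`.
#' @param f Vectorized function applied to the value array.
#' @return A `grid_raster` on the same grid.
#' @export
map_cells <- function(x, f) {
  v <- f(x$values)
  v[is.na(x$values)] <- NA_real_
  grid_raster(array(v, dim = dim(x$values)), x$spec, x$band_names, x$nodata)
}
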