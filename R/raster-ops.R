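#' Resample a raster onto a reference grid
#'
#' Interpolates `input` at the cell centers of `reference` so that the output
#' grid equals the reference grid exactly. `method = "bilinear"` is intended
#' for continuous layers, `"nearest"` for categorical ones (masks, land
#' cover); the caller must state which. Both grids must share a CRS — no
#' reprojection facility is provided, so a CRS mismatch is an error rather
#' than a warp.
#'
#' Bilinear weights are renormalized over the finite members of the 2x2
#' support, so isolated NoData cells do not bleed outward; a cell whose
#' entire support is NoData (or which falls outside the input footprint) is
#' NoData.
#'
#' @param input A [grid_raster()].
#' @param reference A [grid_spec()] (or a `grid_raster`, whose spec is used).
#' @param method `"bilinear"` or `"nearest"`.
#' @return A `grid_raster` on the reference grid.
#' @export
match_resolution <- function(input, reference, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  ref <- if (inherits(reference, "grid_raster")) reference$spec else reference
  if (input$spec$crs_id != ref$crs_id)
    stop(sprintf("CRS mismatch ('%s' vs '%s'); no reprojection facility available",
                 input$spec$crs_id, ref$crs_id))
  if (!any(is.finite(input$values)))
    stop("input raster has no finite cell")
  ei <- spec_extent(input$spec); er <- spec_extent(ref)
  if (ei["xmin"] >= er["xmax"] || ei["xmax"] <= er["xmin"] ||
      ei["ymin"] >= er["ymax"] || ei["ymax"] <= er["ymin"])
    stop(sprintf("input extent %s does not overlap reference extent %s",
                 fmt_extent(ei), fmt_extent(er)))

  ctr <- cell_centers(ref)
  # continuous (0-based) position of reference centers in input center space
  gx <- (ctr$x - input$spec$origin_x) / input$spec$cell_size_x - 0.5
  gy <- (input$spec$origin_y - ctr$y) / input$spec$cell_size_y - 0.5
  nr <- input$spec$n_rows; nc <- input$spec$n_cols
  inside <- gx >= -0.5 & gx <= nc - 0.5 & gy >= -0.5 & gy <= nr - 0.5

  out <- array(NA_real_, c(ref$n_rows, ref$n_cols, n_bands(input)))
  if (method == "nearest") {
    r0 <- pmin(pmax(round(gy) + 1, 1), nr)
    c0 <- pmin(pmax(round(gx) + 1, 1), nc)
    for (b in seq_len(n_bands(input))) {
      v <- band_matrix(input, b)[cbind(r0, c0)]
      v[!inside] <- NA_real_
      out[, , b] <- matrix(v, ref$n_rows, ref$n_cols, byrow = TRUE)
    }
  } else {
    c0 <- floor(gx); r0 <- floor(gy)
    fx <- gx - c0; fy <- gy - r0
    cl <- function(i, n) pmin(pmax(i, 0), n - 1) + 1  # clamp to border
    rr <- cbind(cl(r0, nr), cl(r0, nr), cl(r0 + 1, nr), cl(r0 + 1, nr))
    cc <- cbind(cl(c0, nc), cl(c0 + 1, nc), cl(c0, nc), cl(c0 + 1, nc))
    w <- cbind((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
    for (b in seq_len(n_bands(input))) {
      m <- band_matrix(input, b)
      vals <- matrix(m[cbind(as.vector(rr), as.vector(cc))], ncol = 4)
      wgt <- w; wgt[is.na(vals)] <- 0
      sw <- rowSums(wgt)
      num <- rowSums(wgt * ifelse(is.na(vals), 0, vals))
      v <- ifelse(sw > 0, num / sw, NA_real_)
      v[!inside] <- NA_real_
      out[, , b] <- matrix(v, ref$n_rows, ref$n_cols, byrow = TRUE)
    }
  }
  grid_raster(out, ref, input$band_names, input$nodata)
}

#' Crop/pad a raster to a reference extent, optionally masking
#'
#' `input` and `reference` must already be aligned in CRS, resolution and
#' grid phase (run [match_resolution()] first otherwise). The output covers
#' exactly the reference extent; with `mask_nodata = TRUE` cells that are
#' NoData in the reference's first band become NoData in every output band.
#'
#' @param input,reference [grid_raster()] objects on phase-compatible grids.
#' @param mask_nodata Apply the reference's NoData pattern to the output.
#' @return A `grid_raster` on the reference grid.
#' @export
match_extent <- function(input, reference, mask_nodata = FALSE) {
  si <- input$spec; sr <- reference$spec
  if (si$crs_id != sr$crs_id) stop("CRS mismatch; run match_resolution first")
  if (abs(si$cell_size_x - sr$cell_size_x) > 1e-9 * sr$cell_size_x ||
      abs(si$cell_size_y - sr$cell_size_y) > 1e-9 * sr$cell_size_y)
    stop("resolution mismatch; run match_resolution first")
  dc <- (sr$origin_x - si$origin_x) / si$cell_size_x
  dr <- (si$origin_y - sr$origin_y) / si$cell_size_y
  if (abs(dc - round(dc)) > 1e-6 || abs(dr - round(dr)) > 1e-6)
    stop("grids are not phase-aligned; run match_resolution first")
  dc <- as.integer(round(dc)); dr <- as.integer(round(dr))
  if (dc >= si$n_cols || dc + sr$n_cols <= 0 || dr >= si$n_rows || dr + sr$n_rows <= 0)
    stop(sprintf("reference extent %s is disjoint from input extent %s",
                 fmt_extent(spec_extent(sr)), fmt_extent(spec_extent(si))))

  out <- array(NA_real_, c(sr$n_rows, sr$n_cols, n_bands(input)))
  ri <- intersect(seq_len(sr$n_rows), seq_len(si$n_rows) - dr)
  ci <- intersect(seq_len(sr$n_cols), seq_len(si$n_cols) - dc)
  out[ri, ci, ] <- input$values[ri + dr, ci + dc, , drop = FALSE]
  if (mask_nodata) {
    msk <- is.na(band_matrix(reference, 1L))
    for (b in seq_len(dim(out)[3])) { m <- out[, , b]; m[msk] <- NA_real_; out[, , b] <- m }
  }
  spec <- grid_spec(sr$origin_x, sr$origin_y, sr$cell_size_x, sr$cell_size_y,
                    sr$n_rows, sr$n_cols, sr$crs_id)
  grid_raster(out, spec, input$band_names, input$nodata)
}

#' Moving-window filter on every band
#'
#' Applies `statistic` in an odd square window centered on each cell, band by
#' band. The 90 m smoothing of 30 m predictors used before model training is
#' `window = 3, statistic = "mean"`. Windows are truncated at the raster
#' boundary; under `na_policy = "propagate"` any missing member of the full
#' window (including the part outside the raster) makes the cell NoData,
#' under `"ignore"` the statistic is taken over the available finite members.
#'
#' @param input A [grid_raster()].
#' @param window Odd window side length in cells (`1` is the identity).
#' @param statistic `"mean"`, `"median"`, or a function reducing a numeric
#'   vector to a scalar.
#' @param na_policy `"propagate"` (default, conservative) or `"ignore"`.
#' @return A `grid_raster` on the same grid.
#' @export
focal_multiband <- function(input, window, statistic = "mean",
                            na_policy = c("propagate", "ignore")) {
  na_policy <- match.arg(na_policy)
  if (window < 1 || window %% 2 == 0) stop("`window` must be odd and >= 1")
  if (is.character(statistic)) {
    statistic <- switch(statistic, mean = mean, median = stats::median,
                        stop("unknown statistic '", statistic, "'"))
  } else if (!is.function(statistic)) stop("`statistic` must be a name or function")
  if (window == 1L) return(input)

  nr <- input$spec$n_rows; nc <- input$spec$n_cols
  h <- (window - 1L) %/% 2L
  offs <- expand.grid(dr = -h:h, dc = -h:h)
  out <- array(NA_real_, dim(input$values))
  for (b in seq_len(n_bands(input))) {
    m <- band_matrix(input, b)
    # neighborhood matrix: one column per window offset, NA outside the raster
    nb <- matrix(NA_real_, nr * nc, nrow(offs))
    rows <- rep(seq_len(nr), times = nc); cols <- rep(seq_len(nc), each = nr)
    for (k in seq_len(nrow(offs))) {
      r2 <- rows + offs$dr[k]; c2 <- cols + offs$dc[k]
      ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
      nb[ok, k] <- m[cbind(r2[ok], c2[ok])]
    }
    v <- if (na_policy == "propagate") {
      full <- rowSums(is.na(nb)) == 0L
      res <- rep(NA_real_, nr * nc)
      if (any(full)) res[full] <- apply(nb[full, , drop = FALSE], 1, statistic)
      res
    } else {
      apply(nb, 1, function(z) {
        z <- z[is.finite(z)]
        if (length(z) == 0L) NA_real_ else statistic(z)
      })
    }
    out[, , b] <- matrix(v, nr, nc)
  }
  grid_raster(out, input$spec, input$band_names, input$nodata)
}

#' Buffer NoData cells (edge removal)
#'
#' Every cell within Chebyshev (queen) distance `buffer_cells` of a NoData
#' cell becomes NoData; all other values are unchanged. A cell counts as
#' NoData if any band is NA, and the dilated mask is applied to all bands
#' (a cell is one sampling unit). Typical use: shaving cells adjacent to
#' forest-mask boundaries before sampling, to limit edge effects.
#'
#' @param input A [grid_raster()].
#' @param buffer_cells Positive integer buffer radius in cells.
#' @param treat_boundary_as_nodata Also buffer inward from the raster edge.
#' @return A `grid_raster` on the same grid.
#' @export
edges <- function(input, buffer_cells, treat_boundary_as_nodata = FALSE) {
  if (buffer_cells < 1) stop("`buffer_cells` must be >= 1")
  nr <- input$spec$n_rows; nc <- input$spec$n_cols
  na0 <- apply(is.na(input$values), c(1, 2), any)
  b <- as.integer(buffer_cells)
  pad <- matrix(treat_boundary_as_nodata, nr + 2L * b, nc + 2L * b)
  pad[b + seq_len(nr), b + seq_len(nc)] <- na0
  dil <- matrix(FALSE, nr, nc)
  for (dr in -b:b) for (dc in -b:b)
    dil <- dil | pad[b + dr + seq_len(nr), b + dc + seq_len(nc)]
  out <- input$values
  for (bb in seq_len(n_bands(input))) { m <- out[, , bb]; m[dil] <- NA_real_; out[, , bb] <- m }
  grid_raster(out, input$spec, input$band_names, input$nodata)
}

#' Split a raster into a grid of tiles
#'
#' Tiles are disjoint, cover the input exactly, and each carries the correct
#' geotransform, so memory-bounded processing can run tile by tile and
#' [mosaic()] reassembles the input bit-for-bit.
#'
#' @param input A [grid_raster()].
#' @param n_rows_tiles,n_cols_tiles Number of tiles along rows / columns.
#' @return List of `grid_raster` tiles in row-major tile order.
#' @export
tile <- function(input, n_rows_tiles, n_cols_tiles) {
  s <- input$spec
  if (n_rows_tiles < 1 || n_cols_tiles < 1) stop("tile counts must be >= 1")
  if (n_rows_tiles > s$n_rows || n_cols_tiles > s$n_cols)
    stop("more tiles than rows/columns")
  even_split <- function(n, k) {
    sizes <- rep(n %/% k, k)
    if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
    split(seq_len(n), rep(seq_len(k), times = sizes))
  }
  rsplit <- even_split(s$n_rows, n_rows_tiles)
  csplit <- even_split(s$n_cols, n_cols_tiles)
  tiles <- list()
  for (ri in seq_along(rsplit)) for (ci in seq_along(csplit)) {
    rr <- rsplit[[ri]]; cc <- csplit[[ci]]
    ts <- grid_spec(s$origin_x + (cc[1] - 1) * s$cell_size_x,
                    s$origin_y - (rr[1] - 1) * s$cell_size_y,
                    s$cell_size_x, s$cell_size_y,
                    length(rr), length(cc), s$crs_id)
    tiles[[length(tiles) + 1L]] <-
      grid_raster(input$values[rr, cc, , drop = FALSE], ts,
                  input$band_names, input$nodata)
  }
  tiles
}

#' Reassemble tiles produced by [tile()]
#'
#' @param tiles List of aligned `grid_raster` tiles on one parent grid.
#' @return A single `grid_raster` covering the union of tile extents.
#' @export
mosaic <- function(tiles) {
  stopifnot(length(tiles) >= 1)
  s1 <- tiles[[1]]$spec
  ox <- min(vapply(tiles, function(t) t$spec$origin_x, 0))
  oy <- max(vapply(tiles, function(t) t$spec$origin_y, 0))
  xmax <- max(vapply(tiles, function(t) spec_extent(t$spec)["xmax"], 0))
  ymin <- min(vapply(tiles, function(t) spec_extent(t$spec)["ymin"], 0))
  nc <- as.integer(round((xmax - ox) / s1$cell_size_x))
  nr <- as.integer(round((oy - ymin) / s1$cell_size_y))
  out <- array(NA_real_, c(nr, nc, n_bands(tiles[[1]])))
  for (t in tiles) {
    r0 <- as.integer(round((oy - t$spec$origin_y) / s1$cell_size_y))
    c0 <- as.integer(round((t$spec$origin_x - ox) / s1$cell_size_x))
    out[r0 + seq_len(t$spec$n_rows), c0 + seq_len(t$spec$n_cols), ] <- t$values
  }
  spec <- grid_spec(ox, oy, s1$cell_size_x, s1$cell_size_y, nr, nc, s1$crs_id)
  grid_raster(out, spec, tiles[[1]]$band_names, tiles[[1]]$nodata)
}
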