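#' Read and write gridded rasters
#'
#' Two plain-text on-disk forms are supported:
#' \itemize{
#'   \item `*.asc` — single-band ESRI ASCII grid (square cells required by
#'     the format). CRS and band name are carried by an optional `*.asc.json`
#'     sidecar; without it the band is named after the file.
#'   \item `*.json` — a multiband *stack*: a JSON header listing the
#'     [grid_spec()], band names, NoData sentinel and one ASCII grid file per
#'     band (`<base>_<band>.asc`), all in the header's directory.
#' }
#' Every write logs the grid shape via `message()` so reshapes are traceable.
#'
#' @param x A [grid_raster()].
#' @param path Output path ending in `.asc` (single band) or `.json` (stack).
#' @return `write_raster` returns `path` invisibly; `read_raster` returns a
#'   `grid_raster`.
#' @export
write_raster <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "asc") {
    if (n_bands(x) != 1L)
      stop("ESRI ASCII holds one band; use a .json stack for ", n_bands(x), " bands")
    write_asc(band_matrix(x, 1L), x$spec, x$nodata, path)
    meta <- list(crs_id = x$spec$crs_id, band_name = x$band_names[1],
                 nodata = x$nodata)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  } else if (ext == "json") {
    base <- tools::file_path_sans_ext(basename(path))
    dir <- dirname(path)
    files <- sprintf("%s_%s.asc", base, gsub("[^A-Za-z0-9_.-]", "_", x$band_names))
    for (b in seq_len(n_bands(x)))
      write_asc(band_matrix(x, b), x$spec, x$nodata, file.path(dir, files[b]))
    hdr <- list(format = "forstruct_stack", spec = unclass(x$spec),
                band_names = x$band_names, nodata = x$nodata, files = files)
    jsonlite::write_json(hdr, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported raster extension: .", ext)
  message(sprintf("wrote %s: %d x %d x %d", path,
                  x$spec$n_rows, x$spec$n_cols, n_bands(x)))
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "asc") {
    side <- paste0(path, ".json")
    meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
            else list(crs_id = "local",
                      band_name = tools::file_path_sans_ext(basename(path)),
                      nodata = -9999)
    r <- read_asc(path, meta$crs_id)
    r$band_names <- as.character(meta$band_name)
    r$nodata <- meta$nodata
    r
  } else if (ext == "json") {
    hdr <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(hdr$format, "forstruct_stack"))
      stop(path, " is not a forstruct raster stack header")
    s <- hdr$spec
    spec <- grid_spec(s$origin_x, s$origin_y, s$cell_size_x, s$cell_size_y,
                      s$n_rows, s$n_cols, s$crs_id)
    v <- array(NA_real_, c(spec$n_rows, spec$n_cols, length(hdr$files)))
    for (b in seq_along(hdr$files))
      v[, , b] <- band_matrix(read_asc(file.path(dirname(path), hdr$files[b]),
                                       spec$crs_id), 1L)
    grid_raster(v, spec, hdr$band_names, hdr$nodata)
  } else stop("unsupported raster extension: .", ext)
}

write_asc <- function(m, spec, nodata, path) {
  if (abs(spec$cell_size_x - spec$cell_size_y) > 1e-9 * spec$cell_size_x)
    stop("ESRI ASCII requires square cells")
  con <- file(path, "w"); on.exit(close(con))
  yll <- spec$origin_y - spec$n_rows * spec$cell_size_y
  writeLines(c(sprintf("ncols %d", spec$n_cols),
               sprintf("nrows %d", spec$n_rows),
               sprintf("xllcorner %.10g", spec$origin_x),
               sprintf("yllcorner %.10g", yll),
               sprintf("cellsize %.10g", spec$cell_size_x),
               sprintf("NODATA_value %g", nodata)), con)
  m[is.na(m)] <- nodata
  utils::write.table(format(m, trim = TRUE, digits = 15, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

read_asc <- function(path, crs_id = "local") {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  m[m == h[["nodata_value"]]] <- NA_real_
  spec <- grid_spec(h[["xllcorner"]],
                    h[["yllcorner"]] + h[["nrows"]] * h[["cellsize"]],
                    h[["cellsize"]], h[["cellsize"]],
                    h[["nrows"]], h[["ncols"]], crs_id)
  grid_raster(m, spec)
}
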