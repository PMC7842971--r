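#' Annual raster time series
#'
#' An ordered collection of aligned [grid_raster()] layers, one per year.
#' Years must be unique; layers are stored sorted by year, so downstream
#' metrics are invariant to the order in which layers are supplied.
#'
#' @param layers List of `grid_raster` objects on one grid, with identical
#'   band layouts.
#' @param years Integer vector, one calendar year per layer.
#' @return An object of class `raster_time_series`.
#' @export
raster_time_series <- function(layers, years) {
  stopifnot(length(layers) == length(years), length(layers) >= 1)
  years <- as.integer(years)
  if (anyDuplicated(years)) stop("years must be unique")
  for (l in layers[-1]) {
    if (!is_aligned(l, layers[[1]])) stop("all layers must share one grid")
    if (!identical(l$band_names, layers[[1]]$band_names))
      stop("all layers must share one band layout")
  }
  o <- order(years)
  structure(list(layers = layers[o], years = years[o]),
            class = "raster_time_series")
}

#' @export
print.raster_time_series <- function(x, ...) {
  cat(sprintf("<raster_time_series> %d layers (%d..%d), bands [%s] on ",
              length(x$years), min(x$years), max(x$years),
              paste(x$layers[[1]]$band_names, collapse = ", ")))
  print(x$layers[[1]]$spec)
  invisible(x)
}

#' Theil-Sen slope of a series
#'
#' The median of all pairwise slopes `(y_j - y_i) / (t_j - t_i)`, `i < j` —
#' a robust trend estimator. Missing pairs are dropped; calendar times are
#' used, so gap years weight the slopes correctly. With fewer than two
#' finite pairs the result is `NA` (a missing value, not an error, since at
#' raster scale many pixels are legitimately data-poor).
#'
#' @param values Numeric series.
#' @param times Numeric observation times (same length), e.g. years.
#' @return Slope in value units per time unit, or `NA_real_`.
#' @export
theil_sen_slope <- function(values, times = seq_along(values)) {
  stopifnot(length(values) == length(times))
  ok <- is.finite(values) & is.finite(times)
  y <- values[ok]; t <- times[ok]
  n <- length(y)
  if (n < 2L) return(NA_real_)
  ij <- utils::combn(n, 2L)
  stats::median((y[ij[2, ]] - y[ij[1, ]]) / (t[ij[2, ]] - t[ij[1, ]]))
}

# --- metric registry ---------------------------------------------------------

metric_registry <- new.env(parent = emptyenv())

builtin_metrics <- c("median", "IQR", "theil_sen")

#' Register a user-defined temporal metric
#'
#' Makes a reducer available to [temporal_summary()] under `name`. The
#' reducer is called per pixel with the finite values of the series; if it
#' accepts a second argument it also receives the matching years.
#'
#' @param name Metric name (must not collide with a built-in or an existing
#'   registration).
#' @param reducer `function(values)` or `function(values, years)` returning
#'   a scalar.
#' @param overwrite Allow replacing an existing user metric.
#' @return `name`, invisibly.
#' @export
register_metric <- function(name, reducer, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1, is.function(reducer))
  if (name %in% builtin_metrics) stop("'", name, "' is a built-in metric")
  if (!overwrite && !is.null(metric_registry[[name]]))
    stop("metric '", name, "' is already registered")
  assign(name, reducer, envir = metric_registry)
  invisible(name)
}

#' @rdname register_metric
#' @export
registered_metrics <- function() sort(names(metric_registry))

resolve_metric <- function(name) {
  if (name %in% builtin_metrics) return(name)
  f <- metric_registry[[name]]
  if (is.null(f)) stop("unknown metric '", name, "'")
  f
}

# apply one metric to a pixels x years matrix of finite-or-NA values
apply_metric <- function(metric, M, years, nvalid, min_valid) {
  res <- if (identical(metric, "median")) {
    apply(M, 1, stats::median, na.rm = TRUE)
  } else if (identical(metric, "IQR")) {
    # linear-interpolation quantiles (type 7), Q75 - Q25
    apply(M, 1, function(z) {
      z <- z[is.finite(z)]
      if (!length(z)) return(NA_real_)
      q <- stats::quantile(z, c(0.25, 0.75), names = FALSE, type = 7)
      q[2] - q[1]
    })
  } else if (identical(metric, "theil_sen")) {
    theil_sen_rows(M, years)
  } else {
    f <- metric
    wants_years <- length(formals(f)) >= 2L
    apply(M, 1, function(z) {
      ok <- is.finite(z)
      if (!any(ok)) return(NA_real_)
      if (wants_years) f(z[ok], years[ok]) else f(z[ok])
    })
  }
  res[nvalid < min_valid] <- NA_real_
  res
}

# vectorized Theil-Sen over rows: one pass per year pair
theil_sen_rows <- function(M, years) {
  n <- length(years)
  ij <- utils::combn(n, 2L)
  S <- matrix(NA_real_, nrow(M), ncol(ij))
  for (k in seq_len(ncol(ij))) {
    i <- ij[1, k]; j <- ij[2, k]
    S[, k] <- (M[, j] - M[, i]) / (years[j] - years[i])
  }
  r <- apply(S, 1, function(z) {
    z <- z[is.finite(z)]
    if (!length(z)) NA_real_ else stats::median(z)
  })
  r
}

#' Temporal summary metrics of an annual series
#'
#' Reduces each pixel's annual trajectory to summary metrics — the
#' pre-defined set is median, interquartile range (IQR, Q75 - Q25 with
#' linear-interpolation quantiles) and Theil-Sen slope — one output band per
#' (input band x metric), named `<band>_<metric>`. Pixels with fewer than
#' `min_valid` finite years are NoData in every metric band. Works on a
#' [raster_time_series()] or on a data.frame of per-point series (columns
#' `<band>_<year>`). The computation is independent of any row-block
#' splitting used for memory: results for a block depend only on that
#' block's pixels.
#'
#' @param series A `raster_time_series`.
#' @param metrics Character vector of built-in (`"median"`, `"IQR"`,
#'   `"theil_sen"`) and/or [registered][register_metric] metric names.
#' @param min_valid Minimum finite years per pixel (default 3: a slope from
#'   two points is a single pairwise ratio with no median smoothing).
#' @param block_rows Optional number of raster rows per processing block;
#'   the output is bit-identical for any value.
#' @return A `grid_raster` with `n_bands(series) * length(metrics)` bands.
#' @export
temporal_summary <- function(series, metrics = c("median", "IQR", "theil_sen"),
                             min_valid = 3L, block_rows = NULL) {
  stopifnot(inherits(series, "raster_time_series"), length(metrics) >= 1)
  if (min_valid < 2) stop("`min_valid` must be >= 2")
  mets <- lapply(metrics, resolve_metric)  # fail fast on unknown names
  spec <- series$layers[[1]]$spec
  bnames <- series$layers[[1]]$band_names
  nb <- length(bnames); ny <- length(series$years)
  out_names <- as.vector(t(outer(bnames, metrics, paste, sep = "_")))
  out <- array(NA_real_, c(spec$n_rows, spec$n_cols, nb * length(metrics)))

  blocks <- if (is.null(block_rows)) list(seq_len(spec$n_rows)) else
    split(seq_len(spec$n_rows),
          ceiling(seq_len(spec$n_rows) / max(1L, as.integer(block_rows))))
  for (rows in blocks) {
    npix <- length(rows) * spec$n_cols
    for (b in seq_len(nb)) {
      M <- matrix(NA_real_, npix, ny)
      for (k in seq_len(ny))
        M[, k] <- as.vector(series$layers[[k]]$values[rows, , b])
      nvalid <- rowSums(is.finite(M))
      for (mi in seq_along(metrics)) {
        v <- apply_metric(mets[[mi]], M, series$years, nvalid, min_valid)
        out[rows, , (b - 1L) * length(metrics) + mi] <-
          matrix(v, length(rows), spec$n_cols)
      }
    }
  }
  grid_raster(out, spec, out_names, series$layers[[1]]$nodata)
}
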