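#' Map semantic band roles to raster bands
#'
#' Spectral index formulas are written against semantic roles (blue, green,
#' red, nir, swir1, swir2); a `band_map` says which band of a raster (or
#' which value column of sample points) plays each role, plus the sensor tag
#' that selects a Tasseled Cap coefficient set.
#'
#' @param ... Named role = band pairs, e.g. `red = 3, nir = 4` (indices) or
#'   `red = "B3"` (band/column names).
#'   Recognized roles: `blue`, `green`, `red`, `nir`, `swir1`, `swir2`.
#' @param sensor Sensor tag; see [tc_coefficients()] for supported tags.
#' @return An object of class `band_map`.
#' @export
band_map <- function(..., sensor = "Landsat5TM") {
  m <- c(...)
  roles <- c("blue", "green", "red", "nir", "swir1", "swir2")
  if (is.null(names(m)) || any(!names(m) %in% roles))
    stop("band_map roles must be among: ", paste(roles, collapse = ", "))
  if (anyDuplicated(names(m))) stop("duplicate band roles")
  if (anyDuplicated(m)) stop("two roles map to the same band")
  if (is.numeric(m) && any(m < 1)) stop("band indices must be >= 1")
  structure(list(roles = m, sensor = sensor), class = "band_map")
}

#' Tasseled Cap coefficients by sensor
#'
#' Published reflectance-space coefficient sets for the brightness,
#' greenness and wetness components, keyed by sensor tag: `"Landsat5TM"`
#' (Crist 1985, TM reflectance factors), `"Landsat7ETM"` (Huang et al. 2002,
#' at-satellite reflectance) and `"Landsat8OLI"` (Baig et al. 2014).
#' Coefficients assume surface reflectance scaled to `[0, 1]` (or a
#' consistent integer scaling, since the transform is linear).
#'
#' @param sensor Sensor tag.
#' @return A 3 x 6 numeric matrix (rows TCB/TCG/TCW, columns
#'   blue/green/red/nir/swir1/swir2).
#' @export
tc_coefficients <- function(sensor = "Landsat5TM") {
  tabs <- list(
    Landsat5TM = rbind(
      TCB = c(0.2043, 0.4158, 0.5524, 0.5741, 0.3124, 0.2303),
      TCG = c(-0.1603, -0.2819, -0.4934, 0.7940, -0.0002, -0.1446),
      TCW = c(0.0315, 0.2021, 0.3102, 0.1594, -0.6806, -0.6109)),
    Landsat7ETM = rbind(
      TCB = c(0.3561, 0.3972, 0.3904, 0.6966, 0.2286, 0.1596),
      TCG = c(-0.3344, -0.3544, -0.4556, 0.6966, -0.0242, -0.2630),
      TCW = c(0.2626, 0.2141, 0.0926, 0.0656, -0.7629, -0.5388)),
    Landsat8OLI = rbind(
      TCB = c(0.3029, 0.2786, 0.4733, 0.5599, 0.5080, 0.1872),
      TCG = c(-0.2941, -0.2430, -0.5424, 0.7276, 0.0713, -0.1608),
      TCW = c(0.1511, 0.1973, 0.3283, 0.3407, -0.7117, -0.4559)))
  if (!sensor %in% names(tabs))
    stop("unknown sensor tag '", sensor, "'; supported: ",
         paste(names(tabs), collapse = ", "))
  m <- tabs[[sensor]]
  colnames(m) <- c("blue", "green", "red", "nir", "swir1", "swir2")
  m
}

index_requirements <- function() {
  list(NDVI = c("red", "nir"), NBR = c("nir", "swir2"),
       TCB = c("blue", "green", "red", "nir", "swir1", "swir2"),
       TCG = c("blue", "green", "red", "nir", "swir1", "swir2"),
       TCW = c("blue", "green", "red", "nir", "swir1", "swir2"))
}

# core formulas on a list of role-named numeric vectors/matrices
compute_index <- function(name, bands, coefs) {
  ratio <- function(a, b) { d <- a + b; r <- (a - b) / d; r[d == 0] <- NA_real_; r }
  switch(name,
    NDVI = ratio(bands$nir, bands$red),
    NBR  = ratio(bands$nir, bands$swir2),
    TCB = , TCG = , TCW = {
      k <- coefs[name, ]
      Reduce(`+`, Map(function(role, w) w * bands[[role]], colnames(coefs), k))
    },
    stop("unknown index '", name, "'"))
}

#' Compute spectral indices on a raster or at sample points
#'
#' Works on both code paths of the modelling workflow: wall-to-wall on a
#' [grid_raster()] of reflectance bands, or column-wise on extracted
#' [sample points][draw_sample] (useful when predictors are only needed at
#' sample locations). NDVI = (nir - red)/(nir + red); NBR = (nir - swir2)/
#' (nir + swir2); TCB/TCG/TCW are dot products of the six reflective bands
#' with the sensor's published coefficients. Zero-denominator cells are
#' NoData.
#'
#' @param input A `grid_raster`, or a `data.frame` of point values whose
#'   columns are indexed by `bands`.
#' @param indices Character vector among `"NDVI"`, `"NBR"`, `"TCB"`,
#'   `"TCG"`, `"TCW"`.
#' @param bands A [band_map()]. For the data.frame path, role indices refer
#'   to columns of `input` counted among its numeric value columns.
#' @return Same container as `input`: a `grid_raster` with one band per
#'   index, or the data.frame with one added column per index.
#' @export
calc_indices <- function(input, indices, bands) {
  stopifnot(inherits(bands, "band_map"), length(indices) >= 1)
  req <- index_requirements()
  for (ix in indices) {
    if (!ix %in% names(req)) stop("unknown index '", ix, "'")
    miss <- setdiff(req[[ix]], names(bands$roles))
    if (length(miss))
      stop("index ", ix, " needs band role(s) missing from band_map: ",
           paste(miss, collapse = ", "))
  }
  coefs <- if (any(indices %in% c("TCB", "TCG", "TCW")))
    tc_coefficients(bands$sensor) else NULL

  if (inherits(input, "grid_raster")) {
    if (is.numeric(bands$roles) && max(bands$roles) > n_bands(input))
      stop("band index exceeds band count")
    vals <- lapply(as.list(bands$roles), function(b) band_matrix(input, b))
    out <- array(NA_real_, c(input$spec$n_rows, input$spec$n_cols, length(indices)))
    for (i in seq_along(indices))
      out[, , i] <- compute_index(indices[i], vals, coefs)
    grid_raster(out, input$spec, indices, input$nodata)
  } else if (is.data.frame(input)) {
    # numeric roles index the value columns (extracted band columns), in the
    # order get_sample_values() appended them
    valcols <- setdiff(names(input),
                       c("id", "x", "y", "row", "col", "stratum", "fold"))
    vals <- lapply(as.list(bands$roles), function(b) {
      cn <- if (is.character(b)) b else valcols[b]
      if (is.na(cn) || !cn %in% names(input)) stop("band '", b, "' not found")
      input[[cn]]
    })
    names(vals) <- names(bands$roles)
    for (ix in indices) input[[ix]] <- compute_index(ix, vals, coefs)
    input
  } else stop("`input` must be a grid_raster or a data.frame")
}
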