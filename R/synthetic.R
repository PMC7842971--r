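#' Parameters of a synthetic forest scene
#'
#' Defines a fully synthetic, seeded study scene emulating the input stack of
#' a structure-extrapolation study on one shared grid: an annual time series
#' of six-band reflectance composites, terrain elevation and slope, a
#' forest-eligibility mask, and two response rasters (a canopy-height
#' percentile `p95` in metres and canopy `cover` in percent) tied to the
#' predictors by a known link function. Defaults describe a 3 km x 3 km
#' scene of 20 m cells with a 25-year annual series.
#'
#' @param n_rows,n_cols Grid dimensions (default 150 x 150).
#' @param cell_size Cell size in metres (default 20).
#' @param years Calendar years of the annual series (default 1984:2008).
#' @param corr_length Spatial correlation length of the latent fields, in
#'   cells (Gaussian smoothing sigma; default 10).
#' @param trend_max Maximum absolute per-year trend of the latent vegetation
#'   density (default 0.006/yr, a gentle multi-decade green-up/decline).
#' @param band_noise_sd Per-year reflectance noise sd (default 0.005).
#' @param response_noise_frac Response noise sd as a fraction of the
#'   noiseless response range (default 0.10).
#' @param mask_fraction Fraction of cells excluded as non-forest (default
#'   0.03; contiguous patches, not salt-and-pepper).
#' @param seed Integer seed fixing every random draw.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(n_rows = 150L, n_cols = 150L, cell_size = 20,
                         years = 1984:2008, corr_length = 10,
                         trend_max = 0.006, band_noise_sd = 0.005,
                         response_noise_frac = 0.10, mask_fraction = 0.03,
                         seed = 1L) {
  stopifnot(n_rows >= 4, n_cols >= 4, cell_size > 0, length(years) >= 2,
            corr_length > 0, band_noise_sd >= 0, response_noise_frac >= 0,
            mask_fraction >= 0, mask_fraction <= 1)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, years = as.integer(sort(years)),
                 corr_length = corr_length, trend_max = trend_max,
                 band_noise_sd = band_noise_sd,
                 response_noise_frac = response_noise_frac,
                 mask_fraction = mask_fraction, seed = as.integer(seed)),
            class = "scene_params")
}

# smooth correlated random field: white noise, separable Gaussian kernel
# (reflection-padded), standardized to mean 0 / sd 1
smooth_field <- function(nr, nc, sigma) {
  h <- ceiling(3 * sigma)
  k <- stats::dnorm(-h:h, sd = sigma); k <- k / sum(k)
  m <- matrix(stats::rnorm((nr + 2 * h) * (nc + 2 * h)), nr + 2 * h, nc + 2 * h)
  m <- apply(m, 2, function(z) stats::filter(z, k, sides = 2))
  m <- t(apply(m, 1, function(z) stats::filter(z, k, sides = 2)))
  m <- m[h + seq_len(nr), h + seq_len(nc)]
  (m - mean(m)) / stats::sd(m)
}

band_model <- function() {
  # reflectance = intercept + soil * s + veg * v, linear in the latent fields
  rbind(blue  = c(0.06, 0.04, -0.02),
        green = c(0.08, 0.05, -0.02),
        red   = c(0.10, 0.10, -0.08),
        nir   = c(0.15, 0.05,  0.35),
        swir1 = c(0.12, 0.10, -0.05),
        swir2 = c(0.10, 0.10, -0.07))
}

#' Generate a complete synthetic scene
#'
#' Smooth correlated random fields drive a latent vegetation-density field
#' `v0` (probability-integral-transformed so it spreads evenly over (0, 1)),
#' a per-pixel linear trend, a soil-brightness field and terrain elevation.
#' Yearly reflectance layers are linear in the (clamped) vegetation
#' trajectory plus Gaussian noise; each response is a monotone
#' (probability-integral) transform of an affine-with-interaction
#' combination of the vegetation and elevation fields — so responses spread
#' evenly across their stated range — plus Gaussian noise scaled to the
#' noiseless response range. The `truth` element records the exact link, the latent fields,
#' the per-band generating slopes and the noiseless responses, so every
#' downstream stage can be validated against the generating process.
#'
#' @param params A [scene_params()].
#' @return List with `ts` ([raster_time_series()] of six-band reflectance),
#'   `dem`, `slope`, `mask` (1 = eligible, NoData = excluded), `responses`
#'   (bands `p95`, `cover`, masked), and `truth`.
#' @export
make_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  spec <- grid_spec(500000, 5600000 + p$n_rows * p$cell_size,
                    p$cell_size, p$cell_size, p$n_rows, p$n_cols,
                    crs_id = "EPSG:32610")
  withr::with_seed(p$seed, {
    f_veg <- smooth_field(p$n_rows, p$n_cols, p$corr_length)
    f_tr  <- smooth_field(p$n_rows, p$n_cols, p$corr_length)
    f_soil <- smooth_field(p$n_rows, p$n_cols, p$corr_length)
    f_dem <- smooth_field(p$n_rows, p$n_cols, p$corr_length * 1.5)
    f_mask <- smooth_field(p$n_rows, p$n_cols, p$corr_length)

    v0 <- stats::pnorm(f_veg)                      # vegetation density (0,1)
    tr <- (stats::pnorm(f_tr) - 0.5) * 2 * p$trend_max  # per-year trend
    s  <- stats::pnorm(f_soil)                     # soil brightness (0,1)
    enorm <- stats::pnorm(f_dem)
    dem_v <- 600 + 400 * enorm                     # elevation, m

    # terrain slope in degrees from central differences
    dzdx <- (dem_v[, c(2:p$n_cols, p$n_cols)] - dem_v[, c(1, 1:(p$n_cols - 1))]) /
      (2 * p$cell_size)
    dzdy <- (dem_v[c(2:p$n_rows, p$n_rows), ] - dem_v[c(1, 1:(p$n_rows - 1)), ]) /
      (2 * p$cell_size)
    slope_v <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi

    mid_year <- p$years[ceiling(length(p$years) / 2)]
    bm <- band_model()
    clamped <- matrix(FALSE, p$n_rows, p$n_cols)
    layers <- vector("list", length(p$years))
    for (i in seq_along(p$years)) {
      v_raw <- v0 + tr * (p$years[i] - mid_year)
      v <- pmin(pmax(v_raw, 0.001), 0.999)
      clamped <- clamped | (v != v_raw)
      arr <- array(NA_real_, c(p$n_rows, p$n_cols, 6L))
      for (b in 1:6) {
        refl <- bm[b, 1] + bm[b, 2] * s + bm[b, 3] * v
        if (p$band_noise_sd > 0)
          refl <- refl + matrix(stats::rnorm(length(refl), sd = p$band_noise_sd),
                                p$n_rows, p$n_cols)
        arr[, , b] <- pmin(pmax(refl, 0), 1)
      }
      layers[[i]] <- grid_raster(arr, spec, rownames(bm))
    }

    # response link: an affine-with-interaction combination of the latent
    # fields, probability-integral-transformed so the driver is ~Uniform(0,1)
    # and responses spread evenly across their stated range. Vegetation
    # dominates and elevation enters inversely, so spectral medians and the
    # DEM carry the predictive signal.
    pit <- function(g) stats::pnorm((g - mean(g)) / stats::sd(g))
    a_p95 <- pit(0.75 * f_veg - 0.20 * f_dem - 0.05 * f_veg * f_dem)
    a_cov <- pit(0.85 * f_veg - 0.12 * f_dem - 0.03 * f_veg * f_dem)
    p95_true <- 2 + 40 * a_p95
    cov_true <- 5 + 85 * a_cov
    noise_sd <- p$response_noise_frac *
      c(p95 = diff(range(p95_true)), cover = diff(range(cov_true)))
    p95 <- p95_true + matrix(stats::rnorm(length(p95_true), sd = noise_sd["p95"]),
                             p$n_rows, p$n_cols)
    cov_ <- cov_true + matrix(stats::rnorm(length(cov_true), sd = noise_sd["cover"]),
                              p$n_rows, p$n_cols)

    # contiguous exclusion patches: lowest mask_fraction of a smooth field
    excl <- if (p$mask_fraction >= 1) {
      matrix(TRUE, p$n_rows, p$n_cols)
    } else if (p$mask_fraction > 0) {
      f_mask <= stats::quantile(f_mask, p$mask_fraction)
    } else matrix(FALSE, p$n_rows, p$n_cols)
    mask_v <- matrix(1, p$n_rows, p$n_cols); mask_v[excl] <- NA_real_
    p95[excl] <- NA_real_; cov_[excl] <- NA_real_
  })

  responses <- grid_raster(array(c(p95, cov_), c(p$n_rows, p$n_cols, 2L)),
                           spec, c("p95", "cover"))
  truth <- list(
    link = paste(
      "p95 = 2 + 40*PIT(0.75*f_veg - 0.20*f_dem - 0.05*f_veg*f_dem);",
      "cover = 5 + 85*PIT(0.85*f_veg - 0.12*f_dem - 0.03*f_veg*f_dem);",
      "PIT = pnorm after standardization"),
    f_veg = f_veg, f_dem = f_dem, driver = list(p95 = a_p95, cover = a_cov),
    v0 = v0, trend = tr, soil = s, enorm = enorm, clamped = clamped,
    band_slopes = lapply(stats::setNames(rownames(band_model()),
                                         rownames(band_model())),
                         function(b) band_model()[b, 3] * tr),
    mid_year = mid_year,
    response_true = list(p95 = p95_true, cover = cov_true),
    noise_sd = noise_sd, params = p)

  list(ts = raster_time_series(layers, p$years),
       dem = grid_raster(dem_v, spec, "DEM"),
       slope = grid_raster(slope_v, spec, "DEM_slope"),
       mask = grid_raster(mask_v, spec, "forest_mask"),
       responses = responses, truth = truth)
}

#' Retain responses only inside simulated acquisition strips
#'
#' Emulates discontinuous lidar acquisition blocks: `n_strips` vertical
#' strips of `strip_width_cells` columns, evenly spaced across the raster,
#' keep their response values; everywhere else becomes NoData. The
#' complement (finite response cells outside the strips) is returned as a
#' target mask so imputed values can be scored against the withheld truth.
#'
#' @param responses A [grid_raster()] of response variables.
#' @param n_strips Number of strips (0 = retain nothing).
#' @param strip_width_cells Strip width in columns.
#' @return List: `reference` (responses masked to the strips),
#'   `target_mask` (1 where a finite response was withheld, NoData
#'   elsewhere), `strip_cols` (integer columns retained).
#' @export
make_reference_strips <- function(responses, n_strips = 3L,
                                  strip_width_cells = 25L) {
  s <- responses$spec
  if (n_strips < 0 || strip_width_cells < 1) stop("invalid strip geometry")
  if (n_strips * strip_width_cells > s$n_cols)
    stop("strips exceed the raster width")
  strip_cols <- integer(0)
  if (n_strips > 0) {
    gap <- (s$n_cols - n_strips * strip_width_cells) / (n_strips + 1)
    for (i in seq_len(n_strips)) {
      start <- round(gap * i + strip_width_cells * (i - 1)) + 1L
      strip_cols <- c(strip_cols, start:(start + strip_width_cells - 1L))
    }
  }
  keep <- matrix(FALSE, s$n_rows, s$n_cols)
  keep[, strip_cols] <- TRUE
  vals <- responses$values
  finite_any <- apply(is.finite(vals), c(1, 2), all)
  for (b in seq_len(n_bands(responses))) {
    m <- vals[, , b]; m[!keep] <- NA_real_; vals[, , b] <- m
  }
  tm <- matrix(NA_real_, s$n_rows, s$n_cols)
  tm[!keep & finite_any] <- 1
  list(reference = grid_raster(vals, s, responses$band_names, responses$nodata),
       target_mask = grid_raster(tm, s, "target_mask", responses$nodata),
       strip_cols = strip_cols)
}
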