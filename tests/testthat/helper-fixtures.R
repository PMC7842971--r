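# shared fixture builders; everything generated in code, no files

toy_spec <- function(nr = 5, nc = 5, cs = 10, ox = 0, oy = nr * cs,
                     crs = "local") {
  grid_spec(ox, oy, cs, cs, nr, nc, crs)
}

# single-band raster with values from a function of (row, col)
toy_raster <- function(nr = 5, nc = 5, f = function(r, c) (r - 1) * nc + c,
                       cs = 10, band = "b1", crs = "local") {
  m <- outer(seq_len(nr), seq_len(nc), f)
  grid_raster(m, toy_spec(nr, nc, cs, crs = crs), band)
}

random_raster <- function(nr, nc, n_band = 1, seed = 1, na_frac = 0, cs = 10) {
  withr::with_seed(seed, {
    v <- array(rnorm(nr * nc * n_band), c(nr, nc, n_band))
    if (na_frac > 0) {
      idx <- sample(nr * nc * n_band, round(na_frac * nr * nc * n_band))
      v[idx] <- NA_real_
    }
  })
  grid_raster(v, toy_spec(nr, nc, cs), paste0("b", seq_len(n_band)))
}

# small reference set with a smooth predictor-response link, for model tests
toy_training <- function(n = 30, p = 4, seed = 1, noise = 0.1) {
  withr::with_seed(seed, {
    X <- as.data.frame(matrix(runif(n * p), n, p))
    names(X) <- paste0("x", seq_len(p))
    Y <- data.frame(y1 = 3 * X$x1 + X$x2 + rnorm(n, sd = noise),
                    y2 = 10 - 4 * X$x2 + rnorm(n, sd = noise))
  })
  list(X = X, Y = Y)
}

small_scene <- function(seed = 1, nr = 60, nc = 60, ...) {
  make_scene(scene_params(n_rows = nr, n_cols = nc, seed = seed, ...))
}

# predictors raster used by pipeline-style tests: temporal metrics + terrain
scene_predictors <- function(sc, indices = c("NDVI", "TCB"),
                             metrics = c("median", "IQR", "theil_sen")) {
  bm <- band_map(blue = 1, green = 2, red = 3, nir = 4, swir1 = 5, swir2 = 6)
  it <- raster_time_series(
    lapply(sc$ts$layers, calc_indices, indices = indices, bands = bm),
    sc$ts$years)
  tm <- temporal_summary(it, metrics)
  s <- tm$spec
  v <- array(c(tm$values, sc$dem$values, sc$slope$values),
             c(s$n_rows, s$n_cols, n_bands(tm) + 2L))
  grid_raster(v, s, c(tm$band_names, "DEM", "DEM_slope"))
}
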