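# --- match_resolution --------------------------------------------------------

test_that("resampling onto the raster's own grid is the identity", {
  r <- random_raster(6, 6, n_band = 2, seed = 1)
  for (m in c("bilinear", "nearest")) {
    out <- match_resolution(r, r$spec, m)
    expect_equal(out$values, r$values)
    expect_true(specs_equal(out$spec, r$spec))
  }
})

test_that("a constant raster stays constant under resampling", {
  r <- grid_raster(matrix(7, 10, 10), toy_spec(10, 10, cs = 20))
  ref <- grid_spec(0, 200, 30, 30, 6, 6, "local")
  for (m in c("bilinear", "nearest")) {
    out <- match_resolution(r, ref, m)
    expect_true(all(out$values == 7))
    expect_true(specs_equal(out$spec, ref))
  }
})

test_that("bilinear resampling matches a hand-computed interpolation", {
  # 2x2 input [[0,2],[4,6]], reference with one cell centered at the input's
  # central point: bilinear value is the mean of the four cells = 3
  r <- grid_raster(matrix(c(0, 4, 2, 6), 2, 2), toy_spec(2, 2, cs = 10))
  ref <- grid_spec(5, 15, 10, 10, 1, 1, "local")  # center at (10, 10)
  out <- match_resolution(r, ref, "bilinear")
  expect_equal(as.vector(out$values), 3.0)

  # off-center reference: weights (0.75, 0.25) in each axis
  ref2 <- grid_spec(2.5, 12.5, 10, 10, 1, 1, "local")  # center (7.5, 7.5)
  # input centers: (5,15)=0 (5,5)=4 (15,15)=2 (15,5)=6; gx=0.25, gy=0.75
  hand <- 0 * 0.75 * 0.25 + 2 * 0.25 * 0.25 + 4 * 0.75 * 0.75 + 6 * 0.25 * 0.75
  out2 <- match_resolution(r, ref2, "bilinear")
  expect_equal(as.vector(out2$values), hand)
})

test_that("resampling is idempotent on the reference grid", {
  r <- random_raster(9, 9, seed = 2, cs = 20)
  ref <- grid_spec(0, 180, 30, 30, 6, 6, "local")
  once <- match_resolution(r, ref, "bilinear")
  twice <- match_resolution(once, ref, "bilinear")
  expect_equal(twice$values, once$values)
})

test_that("resampling rejects bad inputs", {
  r <- random_raster(5, 5)
  expect_error(match_resolution(r, r$spec, "cubic"))
  far <- grid_spec(1e6, 1e6, 10, 10, 5, 5, "local")
  expect_error(match_resolution(r, far, "bilinear"), "overlap")
  other <- grid_spec(0, 50, 10, 10, 5, 5, "EPSG:3005")
  expect_error(match_resolution(r, other, "bilinear"), "CRS")
  allna <- grid_raster(matrix(NA_real_, 3, 3), toy_spec(3, 3))
  expect_error(match_resolution(allna, toy_spec(3, 3), "nearest"), "finite")
})

# --- match_extent ------------------------------------------------------------

test_that("matching an identical extent is the identity", {
  r <- random_raster(6, 6, seed = 3)
  out <- match_extent(r, r, mask_nodata = FALSE)
  expect_equal(out$values, r$values)
})

test_that("an all-NoData reference masks everything", {
  r <- random_raster(4, 4, seed = 4)
  ref <- grid_raster(matrix(NA_real_, 4, 4), r$spec)
  out <- match_extent(r, ref, mask_nodata = TRUE)
  expect_true(all(is.na(out$values)))
})

test_that("cropping equals direct index slicing from the geotransforms", {
  r <- toy_raster(10, 10, f = function(rr, cc) (rr - 1) * 10 + cc)
  # 4x4 window starting at input row 3, col 5 (cs = 10, oy = 100)
  ref_spec <- grid_spec(40, 100 - 2 * 10, 10, 10, 4, 4, "local")
  ref <- grid_raster(matrix(0, 4, 4), ref_spec)
  out <- match_extent(r, ref)
  expect_equal(band_matrix(out), band_matrix(r)[3:6, 5:8])
})

test_that("match_extent pads beyond the input with NoData and rejects misalignment", {
  r <- random_raster(4, 4, seed = 5)
  big <- grid_raster(matrix(0, 6, 6), grid_spec(-10, 50, 10, 10, 6, 6, "local"))
  out <- match_extent(r, big)
  expect_true(all(is.na(out$values[1, , ])))      # north padding row
  expect_equal(out$values[2:5, 2:5, ], r$values[, , ])
  shifted <- grid_raster(matrix(0, 4, 4), grid_spec(3, 40, 10, 10, 4, 4, "local"))
  expect_error(match_extent(r, shifted), "phase")
  disjoint <- grid_raster(matrix(0, 2, 2), grid_spec(500, 40, 10, 10, 2, 2, "local"))
  expect_error(match_extent(r, disjoint), "disjoint")
})

# --- focal_multiband ---------------------------------------------------------

test_that("window 1 is the identity and constants are invariant under mean", {
  r <- random_raster(5, 5, n_band = 2, seed = 6)
  expect_equal(focal_multiband(r, 1, "mean")$values, r$values)
  cst <- grid_raster(matrix(4.2, 6, 6), toy_spec(6, 6))
  sm <- focal_multiband(cst, 3, "mean")
  expect_true(all(sm$values[2:5, 2:5, ] == 4.2))
})

test_that("focal mean matches a brute-force window loop", {
  r <- toy_raster(5, 5, f = function(rr, cc) rr * 2 + cc)
  out <- focal_multiband(r, 3, "mean", na_policy = "ignore")
  m <- band_matrix(r)
  for (i in 1:5) for (j in 1:5) {
    win <- m[max(1, i - 1):min(5, i + 1), max(1, j - 1):min(5, j + 1)]
    expect_equal(band_matrix(out)[i, j], mean(win))
  }
})

test_that("focal mean commutes with affine value rescaling", {
  r <- random_raster(7, 7, seed = 7)
  a <- 2.5; b <- -3
  lhs <- focal_multiband(map_cells(r, function(v) a * v + b), 3, "mean",
                         na_policy = "ignore")
  rhs <- map_cells(focal_multiband(r, 3, "mean", na_policy = "ignore"),
                   function(v) a * v + b)
  expect_equal(lhs$values, rhs$values, tolerance = 1e-12)
})

test_that("NA policy propagate vs ignore behaves as documented", {
  m <- matrix(1, 5, 5); m[3, 3] <- NA
  r <- grid_raster(m, toy_spec(5, 5))
  prop <- focal_multiband(r, 3, "mean", "propagate")
  # any window touching (3,3) or the boundary is NA
  expect_true(all(is.na(band_matrix(prop)[2:4, 2:4])))
  ign <- focal_multiband(r, 3, "mean", "ignore")
  expect_equal(band_matrix(ign)[2, 2], 1)
  expect_equal(band_matrix(ign)[3, 3], 1)  # computed from 8 finite neighbors
  expect_error(focal_multiband(r, 4, "mean"), "odd")
  expect_error(focal_multiband(r, 3, "mode"), "unknown statistic")
})

test_that("focal accepts a user-supplied reducer", {
  r <- toy_raster(4, 4)
  out <- focal_multiband(r, 3, max, na_policy = "ignore")
  expect_equal(band_matrix(out)[1, 1], band_matrix(r)[2, 2])
})

# --- edges -------------------------------------------------------------------

test_that("edges is the identity without NoData and boundary flag off", {
  r <- random_raster(6, 6, seed = 8)
  expect_equal(edges(r, 2)$values, r$values)
})

test_that("edge buffering matches an exhaustive Chebyshev distance check", {
  m <- matrix(1, 5, 5); m[3, 3] <- NA
  r <- grid_raster(m, toy_spec(5, 5))
  out <- edges(r, 1)
  for (i in 1:5) for (j in 1:5) {
    cheb <- max(abs(i - 3), abs(j - 3))
    expect_equal(is.na(band_matrix(out)[i, j]), cheb <= 1,
                 info = sprintf("cell (%d,%d)", i, j))
  }
  allna <- grid_raster(matrix(NA_real_, 3, 3), toy_spec(3, 3))
  expect_true(all(is.na(edges(allna, 1)$values)))
  expect_error(edges(r, 0), ">= 1")
})

test_that("edge buffers are monotone in the buffer radius", {
  r <- random_raster(12, 12, seed = 9, na_frac = 0.08)
  na1 <- is.na(edges(r, 1)$values)
  na2 <- is.na(edges(r, 2)$values)
  expect_true(all(na2[na1]))
})

test_that("boundary flag buffers inward from the raster edge", {
  r <- grid_raster(matrix(1, 5, 5), toy_spec(5, 5))
  out <- edges(r, 1, treat_boundary_as_nodata = TRUE)
  expect_true(all(is.na(band_matrix(out)[c(1, 5), ])))
  expect_false(anyNA(band_matrix(out)[2:4, 2:4]))
})

# --- tile / mosaic -----------------------------------------------------------

test_that("1x1 tiling returns the input and tilings mosaic back exactly", {
  r <- random_raster(10, 10, n_band = 2, seed = 10, na_frac = 0.1)
  t1 <- tile(r, 1, 1)
  expect_length(t1, 1)
  expect_equal(t1[[1]]$values, r$values)

  for (nt in list(c(2, 2), c(3, 2), c(1, 3))) {
    tl <- tile(r, nt[1], nt[2])
    expect_length(tl, nt[1] * nt[2])
    back <- mosaic(tl)
    expect_equal(back$values, r$values)
    expect_true(specs_equal(back$spec, r$spec))
  }
})

test_that("tile origins follow the geotransform arithmetic", {
  r <- toy_raster(3, 3, cs = 10)
  tl <- tile(r, 1, 3)
  expect_equal(vapply(tl, function(t) t$spec$origin_x, 0), c(0, 10, 20))
  expect_equal(vapply(tl, function(t) t$spec$n_cols, 0L), rep(1L, 3))
  expect_error(tile(r, 4, 1), "more tiles")
})
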