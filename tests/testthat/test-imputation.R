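# --- training and exact-match imputation -------------------------------------

test_that("a target identical to a reference is imputed verbatim with k = 1", {
  d <- toy_training(n = 30, seed = 61)
  m <- train_nn(d$X, d$Y, k = 1, ntree = 50, seed = 1)
  res <- impute(m, d$X[7, , drop = FALSE])
  expect_equal(res$nn_ids[1, 1], 7L)
  expect_equal(as.numeric(res$imputed[1, ]), as.numeric(d$Y[7, ]))
  # proximity of an identical predictor vector is 1 (same leaf in every tree)
  expect_equal(res$proximity[1, 7], 1)
})

test_that("the worked-example configuration is accepted and recorded", {
  d <- toy_training(n = 40, p = 14, seed = 62)
  m <- train_nn(d$X, d$Y, k = 1, ntree = 200, mtry = 3, seed = 2)
  expect_equal(m$k, 1L)
  expect_equal(m$ntree, 200L)
  expect_equal(m$mtry, 3L)
  expect_equal(m$method, "random_forest")
  expect_length(m$forests, 2)
  expect_equal(dim(m$ref_leaf_nodes), c(40L, 2L * 200L))
})

test_that("training validates k, mtry and drops incomplete rows", {
  d <- toy_training(n = 10, seed = 63)
  expect_error(train_nn(d$X, d$Y, k = 11, ntree = 5), "k exceeds")
  expect_error(train_nn(d$X, d$Y, k = 1, ntree = 5, mtry = 9), "mtry exceeds")
  d$X$x1[3] <- NA
  expect_message(m <- train_nn(d$X, d$Y, k = 1, ntree = 5, seed = 1),
                 "dropped")
  expect_equal(nrow(m$X_ref), 9L)
})

# --- proximity ---------------------------------------------------------------

test_that("one-tree proximities are 0/1 by shared leaf", {
  d <- toy_training(n = 20, seed = 64)
  m <- train_nn(d$X, d$Y["y1"], k = 1, ntree = 1, seed = 3)
  P <- rf_proximity(m, d$X)
  expect_true(all(P %in% c(0, 1)))
  expect_true(all(diag(P) == 1))
})

test_that("proximity equals the exhaustive (target, reference, tree) count", {
  d <- toy_training(n = 20, seed = 65)
  m <- train_nn(d$X, d$Y, k = 1, ntree = 4, seed = 4)   # 2 forests x 4 trees
  withr::with_seed(66, {
    Xt <- as.data.frame(matrix(runif(10 * 4), 10, 4))
  })
  names(Xt) <- names(d$X)
  P <- rf_proximity(m, Xt)
  expect_equal(dim(P), c(10L, 20L))
  expect_true(all(P >= 0 & P <= 1))

  # independent triple loop over pooled leaf matrices
  tl <- do.call(cbind, lapply(m$forests, function(rf)
    predict(rf, data = Xt, type = "terminalNodes", num.threads = 1)$predictions))
  oracle <- matrix(0, 10, 20)
  for (t in 1:10) for (r in 1:20) {
    cnt <- 0L
    for (tr in 1:8) if (tl[t, tr] == m$ref_leaf_nodes[r, tr]) cnt <- cnt + 1L
    oracle[t, r] <- cnt / 8
  }
  expect_equal(P, oracle)
})

test_that("proximity rejects mismatched predictor columns", {
  d <- toy_training(n = 15, seed = 67)
  m <- train_nn(d$X, d$Y, k = 1, ntree = 5, seed = 5)
  bad <- d$X; names(bad)[2] <- "zz"
  expect_error(rf_proximity(m, bad), "zz")
  expect_error(impute(m, d$X[, c(2, 1, 3, 4)]), "order matters")
})

# --- aggregation -------------------------------------------------------------

test_that("neighbor aggregation reproduces hand-computed means", {
  Y <- matrix(c(10, 20, 8, 4, 0), 5, 1, dimnames = list(NULL, "y"))
  agg <- forstruct:::aggregate_neighbors

  # equal proximity to refs 1 and 2, mean aggregation -> 15
  prox <- matrix(c(0.6, 0.6, 0, 0, 0), 1, 5)
  expect_equal(agg(prox, Y[, , drop = FALSE], 2, "mean")$imputed$y, 15)

  # proximities (0.5, 0.25, 0.25) to responses (8, 4, 0), weighted -> 5.0
  prox3 <- matrix(c(0, 0, 0.5, 0.25, 0.25), 1, 5)
  res <- agg(prox3, Y, 3, "distance_weighted_mean")
  expect_equal(res$imputed$y, (0.5 * 8 + 0.25 * 4 + 0.25 * 0) / 1)
  expect_equal(sort(res$nn_ids[1, ]), 3:5)

  # proximity ties break toward the lowest reference ID
  tie <- matrix(c(0.4, 0.4, 0.4, 0, 0), 1, 5)
  expect_equal(agg(tie, Y, 1, "mean")$nn_ids[1, 1], 1L)

  # all-zero proximities: degenerate target warning, lowest-ID references
  expect_warning(z <- agg(matrix(0, 1, 5), Y, 2, "mean"), "degenerate")
  expect_equal(sort(z$nn_ids[1, ]), 1:2)
})

test_that("euclidean k = 1 matches a brute-force nearest neighbor search", {
  d <- toy_training(n = 40, seed = 68)
  m <- train_nn(d$X, d$Y, k = 1, method = "euclidean", seed = 6)
  withr::with_seed(69, {
    Xt <- as.data.frame(matrix(runif(15 * 4), 15, 4))
  })
  names(Xt) <- names(d$X)
  res <- impute(m, Xt)
  Z <- scale(as.matrix(d$X))
  Zt <- scale(as.matrix(Xt), attr(Z, "scaled:center"), attr(Z, "scaled:scale"))
  for (i in 1:15) {
    dd <- colSums((t(Z) - Zt[i, ])^2)
    expect_equal(res$nn_ids[i, 1], which.min(dd))
    expect_equal(as.numeric(res$imputed[i, ]), as.numeric(d$Y[which.min(dd), ]))
  }
})

test_that("mahalanobis proximity ranks by mahalanobis distance", {
  d <- toy_training(n = 30, seed = 70)
  m <- train_nn(d$X, d$Y, k = 1, method = "mahalanobis", seed = 7)
  Xt <- d$X[c(3, 12), ]
  res <- impute(m, Xt)
  expect_equal(res$nn_ids[, 1], c(3L, 12L))  # self is nearest
})

# --- cross-validation path ---------------------------------------------------

test_that("cross-validated pairs cover every point once per response", {
  d <- toy_training(n = 50, seed = 71)
  strata <- rep(1:2, 25)
  fl <- partition(strata, "kfold", kfold = 5, seed = 8)
  m <- train_nn(d$X, d$Y, k = 3, folds = fl, ntree = 30, seed = 9)
  expect_equal(nrow(m$cv), 50 * 2)
  for (r in c("y1", "y2"))
    expect_setequal(m$cv$id[m$cv$response == r], 1:50)
  # the held-out imputations must carry real skill on this smooth link
  rep_ <- accuracy_report(m$cv)
  expect_true(all(rep_$r2[rep_$fold == "all"] > 0.5))
})

# --- wall-to-wall prediction -------------------------------------------------

test_that("a raster cell equal to a reference imputes that reference (k = 1 closure)", {
  sc <- small_scene(seed = 72, nr = 30, nc = 30)
  preds <- scene_predictors(sc, indices = "NDVI", metrics = c("median", "theil_sen"))
  pts <- data.frame(x = cell_centers(preds$spec)$x[seq(1, 900, 37)],
                    y = cell_centers(preds$spec)$y[seq(1, 900, 37)])
  pts <- get_sample_values(preds, pts)
  pts <- get_sample_values(sc$responses, pts)
  ok <- stats::complete.cases(pts)
  X <- pts[ok, preds$band_names]; Y <- pts[ok, c("p95", "cover")]
  m <- train_nn(X, Y, k = 1, ntree = 40, seed = 10)
  out <- predict_targets(m, preds, chunk_rows = 7)
  ids <- band_matrix(out, "nn_id")
  for (b in c("p95", "cover")) {
    got <- band_matrix(out, b)
    fin <- which(is.finite(got) & is.finite(ids))
    # every imputed value is exactly the referenced row's response
    expect_equal(got[fin], Y[[b]][ids[fin]])
  }
})

test_that("chunked prediction is independent of chunk size and tiling", {
  sc <- small_scene(seed = 73, nr = 24, nc = 24)
  preds <- scene_predictors(sc, indices = "NDVI", metrics = c("median", "IQR"))
  pts <- cell_centers(preds$spec)[seq(4, 570, 23), ]
  pts <- get_sample_values(preds, pts)
  pts <- get_sample_values(sc$responses, pts)
  ok <- stats::complete.cases(pts)
  m <- train_nn(pts[ok, preds$band_names], pts[ok, c("p95", "cover")],
                k = 2, ntree = 25, seed = 11)
  whole <- predict_targets(m, preds, chunk_rows = 24)
  for (cr in c(1, 5)) {
    expect_identical(predict_targets(m, preds, chunk_rows = cr)$values,
                     whole$values)
  }
  # tile-then-mosaic execution agrees too
  tiles <- tile(preds, 2, 2)
  mosa <- mosaic(lapply(tiles, function(t) predict_targets(m, t, chunk_rows = 3)))
  expect_equal(mosa$values, whole$values)
  # chunk_rows beyond the raster is clamped, not an error
  expect_identical(predict_targets(m, preds, chunk_rows = 999)$values,
                   whole$values)
})

test_that("NoData predictors propagate to every output band", {
  sc <- small_scene(seed = 74, nr = 20, nc = 20, mask_fraction = 0)
  preds <- scene_predictors(sc, indices = "NDVI", metrics = c("median", "IQR"))
  preds$values[3, 5, 1] <- NA  # knock out one predictor at one cell
  pts <- cell_centers(preds$spec)[seq(2, 390, 17), ]
  pts <- get_sample_values(preds, pts)
  pts <- get_sample_values(sc$responses, pts)
  ok <- stats::complete.cases(pts)
  m <- train_nn(pts[ok, preds$band_names], pts[ok, c("p95", "cover")],
                k = 1, ntree = 20, seed = 12)
  out <- predict_targets(m, preds, chunk_rows = 6)
  expect_true(all(is.na(out$values[3, 5, ])))
  expect_error(predict_targets(m, sc$dem), "do not match")
  expect_error(predict_targets(m, preds, chunk_rows = 0), ">= 1")
})

# --- accuracy ----------------------------------------------------------------

test_that("accuracy statistics follow their defining equations", {
  expect_equal(accuracy(1:10, 1:10)[, c("r2", "rmse", "bias")],
               data.frame(r2 = 1, rmse = 0, bias = 0))
  obs <- c(2, 4, 6, 8)
  expect_equal(accuracy(obs, rep(mean(obs), 4))$r2, 0)  # SSR == SST

  a <- accuracy(c(1, 2, 3), c(2, 2, 2))
  expect_equal(a$ssr, 2); expect_equal(a$sst, 2)
  expect_equal(a$r2, 0)
  expect_equal(a$rmse, sqrt(2 / 3))
  expect_equal(a$bias, 0)
  expect_equal(a$rmse_pct, 100 * sqrt(2 / 3) / 2)
})

test_that("RMSE dominates |bias| and missing pairs are dropped", {
  withr::with_seed(75, {
    for (i in 1:25) {
      obs <- rnorm(20); pred <- rnorm(20)
      a <- accuracy(obs, pred)
      expect_gte(a$rmse, abs(a$bias))
    }
  })
  a <- accuracy(c(1, 2, NA, 4), c(1.1, NA, 3, 4.2))
  expect_equal(a$n, 2L)
  expect_warning(z <- accuracy(c(-1, 1), c(0, 0)), "undefined")
  expect_true(is.na(z$rmse_pct))
})

test_that("accuracy_report returns per-fold and pooled rows", {
  cv <- data.frame(fold = rep(1:2, each = 4), response = "y",
                   observed = c(1, 2, 3, 4, 2, 3, 4, 5),
                   predicted = c(1, 2, 3, 4, 3, 4, 5, 6))
  rep_ <- accuracy_report(cv)
  expect_equal(nrow(rep_), 3)
  expect_equal(rep_$r2[rep_$fold == "1"], 1)
  expect_equal(rep_$bias[rep_$fold == "2"], 1)
  expect_equal(rep_$n[rep_$fold == "all"], 8L)
})

# --- variable importance -----------------------------------------------------

test_that("z-scored importances have mean 0 and unit variance per response", {
  d <- toy_training(n = 60, p = 6, seed = 76, noise = 0.3)
  m <- train_nn(d$X, d$Y, k = 1, ntree = 60, seed = 13)
  vi <- var_imp(m)
  for (r in c("y1", "y2")) {
    z <- vi$scaled[vi$response == r]
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
  msc <- vi[vi$response == "mean", ]
  expect_equal(msc$scaled,
               (vi$scaled[vi$response == "y1"] + vi$scaled[vi$response == "y2"]) / 2)
  expect_error(var_imp(train_nn(d$X, d$Y, method = "euclidean")), "random_forest")
})

test_that("a predictor that copies the response dominates the importances", {
  withr::with_seed(77, {
    n <- 80
    X <- data.frame(A = runif(n), B = runif(n), C = runif(n),
                    D = runif(n), E = runif(n))
    Y <- data.frame(y = X$A)
    wins <- 0L
    for (rep_i in 1:20) {
      m <- train_nn(X, Y, k = 1, ntree = 100, seed = 1000 + rep_i)
      vi <- var_imp(m, scaled = FALSE)
      if (vi$predictor[which.max(vi$raw)] == "A") wins <- wins + 1L
    }
  })
  expect_gte(wins, 19L)
})

# --- scatter report ----------------------------------------------------------

test_that("scatter report writes a non-empty figure per response", {
  d <- toy_training(n = 40, seed = 78)
  fl <- partition(rep(1:2, 20), "kfold", kfold = 5, seed = 14)
  m <- train_nn(d$X, d$Y, k = 3, folds = fl, ntree = 30, seed = 15)
  path <- withr::local_tempfile(fileext = ".png")
  scatter_report(m$cv, path)
  expect_true(file.exists(path))
  expect_gt(file.info(path)$size, 1000)
  g <- attr(scatter_report(m$cv, withr::local_tempfile(fileext = ".png")), "plot")
  expect_s3_class(g, "ggplot")
  expect_error(scatter_report(m$cv[0, ], withr::local_tempfile(fileext = ".png")))
})
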