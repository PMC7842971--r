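#' Train a random-forest-proximity k-NN imputation model
#'
#' Fits the k-nearest-neighbour imputation model used to transfer response
#' variables from reference cells (where e.g. lidar canopy metrics exist) to
#' target cells (predictors only). With `method = "random_forest"` one
#' regression forest is grown per response variable, and the nearness of a
#' target to a reference is the proportion of trees — pooled over all
#' per-response forests — in which the two land in the same terminal node.
#' This supervised, non-Euclidean proximity generally outperforms plain
#' Euclidean or Mahalanobis distances, both of which are also available.
#'
#' When `folds` is supplied, a model is fitted on each fold's training rows
#' and its held-out rows are imputed, producing observed/predicted pairs
#' ready for [accuracy()]; the returned model itself is refit on all rows.
#'
#' @param X Data frame / matrix of predictors at sample points (named
#'   columns; the names define the exact band set required at prediction).
#' @param Y Data frame / matrix of response variables, row-aligned with `X`.
#' @param k Number of nearest references used per target.
#' @param folds Optional fold assignment from [partition()].
#' @param method `"random_forest"`, `"euclidean"` or `"mahalanobis"`.
#' @param ntree Trees per response forest.
#' @param mtry Predictors tried at each split (default
#'   `max(1, floor(p/3))`, the regression-forest convention).
#' @param aggregation For `k > 1`: `"mean"` or `"distance_weighted_mean"`
#'   (default; weights are the proximities).
#' @param scale_predictors Standardize predictors before distance
#'   computation (`"euclidean"` method; ignored for random forest).
#' @param mahalanobis_on `"raw"` or `"standardized"` predictors for the
#'   covariance of the `"mahalanobis"` method.
#' @param seed Integer seed (forest growth and permutation importance).
#' @return An object of class `knn_model`; when `folds` is given it carries
#'   `$cv`, a data.frame of held-out pairs with columns `fold`, `id`,
#'   `response`, `observed`, `predicted`.
#' @export
train_nn <- function(X, Y, k = 1L, folds = NULL,
                     method = c("random_forest", "euclidean", "mahalanobis"),
                     ntree = 200L, mtry = NULL,
                     aggregation = c("distance_weighted_mean", "mean", "nearest"),
                     scale_predictors = TRUE, mahalanobis_on = c("raw", "standardized"),
                     seed = 1L) {
  method <- match.arg(method); aggregation <- match.arg(aggregation)
  mahalanobis_on <- match.arg(mahalanobis_on)
  X <- as.data.frame(X); Y <- as.data.frame(Y)
  stopifnot(nrow(X) == nrow(Y), ncol(Y) >= 1)
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(X) / 3))
  if (mtry > ncol(X)) stop("mtry exceeds the number of predictors")

  drop <- rowSums(is.na(X)) > 0 | rowSums(is.na(Y)) > 0
  if (any(drop)) {
    message(sum(drop), " row(s) with missing values dropped before training")
    X <- X[!drop, , drop = FALSE]; Y <- Y[!drop, , drop = FALSE]
    if (!is.null(folds)) folds$fold <- folds$fold[!drop]
  }
  if (k > nrow(X)) stop("k exceeds the number of training references")

  fit_one <- function(rows, sub_seed) {
    fit_knn_refs(X[rows, , drop = FALSE], Y[rows, , drop = FALSE], k, method,
                 ntree, mtry, aggregation, scale_predictors, mahalanobis_on,
                 sub_seed)
  }

  cv <- NULL
  if (!is.null(folds)) {
    held <- if (folds$scheme == "kfold") seq_len(folds$kfold) else 2L
    out <- list()
    for (f in held) {
      tr <- folds$fold != f
      if (sum(tr) < k) stop("fold ", f, ": fewer training rows than k")
      m_f <- fit_one(which(tr), seed + f)
      pred <- impute(m_f, X[!tr, , drop = FALSE])
      obs <- Y[!tr, , drop = FALSE]
      for (r in names(Y))
        out[[length(out) + 1L]] <- data.frame(
          fold = f, id = which(!tr), response = r,
          observed = obs[[r]], predicted = pred$imputed[[r]])
    }
    cv <- do.call(rbind, out)
  }

  model <- fit_one(seq_len(nrow(X)), seed)
  model$cv <- cv
  model$seed <- seed
  model
}

# fit forests / distance structures on a fixed reference set
fit_knn_refs <- function(X, Y, k, method, ntree, mtry, aggregation,
                         scale_predictors, mahalanobis_on, seed) {
  m <- list(X_ref = X, Y_ref = Y, k = as.integer(k), method = method,
            ntree = as.integer(ntree), mtry = as.integer(mtry),
            aggregation = aggregation, predictor_names = names(X),
            response_names = names(Y))
  if (method == "random_forest") {
    forests <- list(); leaves <- list()
    for (i in seq_along(Y)) {
      d <- cbind(.response = Y[[i]], X)
      rf <- ranger::ranger(dependent.variable.name = ".response", data = d,
                           num.trees = ntree, mtry = mtry, seed = seed + i,
                           num.threads = 1L, importance = "permutation",
                           write.forest = TRUE)
      forests[[names(Y)[i]]] <- rf
      leaves[[i]] <- stats::predict(rf, data = X, type = "terminalNodes",
                                    num.threads = 1L)$predictions
    }
    m$forests <- forests
    m$ref_leaf_nodes <- do.call(cbind, leaves)  # n_ref x (q * ntree)
  } else {
    mu <- colMeans(X); sd_ <- apply(X, 2, stats::sd); sd_[sd_ == 0] <- 1
    m$center <- mu; m$scale <- sd_
    m$scale_predictors <- scale_predictors
    if (method == "mahalanobis") {
      Z <- if (mahalanobis_on == "standardized") scale(as.matrix(X), mu, sd_)
           else as.matrix(X)
      m$mahalanobis_on <- mahalanobis_on
      m$cov_inv <- solve(stats::cov(Z))
    }
  }
  class(m) <- "knn_model"
  m
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("<knn_model> method=%s, k=%d, %d reference(s), %d predictor(s), %d response(s)\n",
              x$method, x$k, nrow(x$X_ref), length(x$predictor_names),
              length(x$response_names)))
  if (x$method == "random_forest")
    cat(sprintf("  %d tree(s) per response forest, mtry=%d, aggregation=%s\n",
                x$ntree, x$mtry, x$aggregation))
  invisible(x)
}

check_predictor_columns <- function(model, X) {
  if (!identical(colnames(X), model$predictor_names)) {
    miss <- setdiff(model$predictor_names, colnames(X))
    extra <- setdiff(colnames(X), model$predictor_names)
    stop("predictor columns do not match the model (order matters). ",
         if (length(miss)) paste0("missing: ", paste(miss, collapse = ", "), ". "),
         if (length(extra)) paste0("unexpected: ", paste(extra, collapse = ", "), ". "),
         "expected: ", paste(model$predictor_names, collapse = ", "))
  }
}

#' Random-forest proximity of targets to all references
#'
#' `proximity(t, r)` is the number of trees, pooled over all per-response
#' forests, in which target `t` falls in the same terminal node as reference
#' `r`, divided by the pooled tree count — a value in `[0, 1]`.
#'
#' @param model A `knn_model` with `method = "random_forest"`.
#' @param X_targets Matrix/data.frame whose columns exactly match the
#'   model's predictor names.
#' @return Numeric matrix `n_targets x n_references`.
#' @export
rf_proximity <- function(model, X_targets) {
  stopifnot(model$method == "random_forest")
  X_targets <- as.data.frame(X_targets)
  check_predictor_columns(model, X_targets)
  tl <- do.call(cbind, lapply(model$forests, function(rf)
    stats::predict(rf, data = X_targets, type = "terminalNodes",
                   num.threads = 1L)$predictions))
  leaf_proximity(tl, model$ref_leaf_nodes)
}

# shared-leaf count between target and reference leaf matrices, / n trees
leaf_proximity <- function(target_leaves, ref_leaves) {
  nt <- nrow(target_leaves); nr <- nrow(ref_leaves)
  ntrees <- ncol(ref_leaves)
  P <- matrix(0L, nt, nr)
  for (tr in seq_len(ntrees)) {
    P <- P + outer(target_leaves[, tr], ref_leaves[, tr], `==`)
  }
  P / ntrees
}

# proximity-like score for the distance methods: larger = nearer
distance_scores <- function(model, X) {
  Xr <- as.matrix(model$X_ref); Xt <- as.matrix(X)
  if (model$method == "euclidean" && isTRUE(model$scale_predictors)) {
    Xr <- scale(Xr, model$center, model$scale)
    Xt <- scale(Xt, model$center, model$scale)
  }
  if (model$method == "mahalanobis") {
    if (identical(model$mahalanobis_on, "standardized")) {
      Xr <- scale(Xr, model$center, model$scale)
      Xt <- scale(Xt, model$center, model$scale)
    }
    S <- model$cov_inv
    D2 <- outer(rowSums((Xt %*% S) * Xt), rowSums((Xr %*% S) * Xr), `+`) -
      2 * Xt %*% S %*% t(Xr)
  } else {
    D2 <- outer(rowSums(Xt^2), rowSums(Xr^2), `+`) - 2 * Xt %*% t(Xr)
  }
  D2[D2 < 0] <- 0
  1 / (1 + sqrt(D2))  # monotone map of distance to a (0, 1] nearness score
}

# k-NN aggregation from a nearness matrix; ties broken by lowest reference ID
aggregate_neighbors <- function(prox, Y_ref, k, aggregation) {
  nt <- nrow(prox); q <- ncol(Y_ref)
  imputed <- as.data.frame(matrix(NA_real_, nt, q))
  names(imputed) <- colnames(Y_ref)
  nn_ids <- matrix(NA_integer_, nt, k)
  degenerate <- 0L
  for (i in seq_len(nt)) {
    p <- prox[i, ]
    if (all(p == 0)) { degenerate <- degenerate + 1L; p <- p + 1 }
    ord <- order(-p, seq_along(p))  # descending nearness, lowest ID on ties
    nn <- ord[seq_len(k)]
    nn_ids[i, ] <- nn
    if (k == 1L) {
      imputed[i, ] <- Y_ref[nn, , drop = FALSE]
    } else if (aggregation == "mean") {
      imputed[i, ] <- colMeans(Y_ref[nn, , drop = FALSE])
    } else {  # distance_weighted_mean
      w <- p[nn]; w <- w / sum(w)
      imputed[i, ] <- colSums(Y_ref[nn, , drop = FALSE] * w)
    }
  }
  if (degenerate > 0L)
    warning(degenerate, " degenerate target(s) with zero proximity to every ",
            "reference; imputed from the lowest-ID references")
  list(imputed = imputed, nn_ids = nn_ids)
}

#' Impute responses for a matrix of targets
#'
#' With `k = 1` each target receives the full response vector of its single
#' nearest reference verbatim (all responses simultaneously from the same
#' reference, preserving among-attribute allometry); with `k > 1` the simple
#' or proximity-weighted mean of the k nearest references, per the model's
#' aggregation setting. Proximity ties are broken by lowest reference ID,
#' making every map bit-reproducible.
#'
#' @param model A `knn_model`.
#' @param X_targets Matrix/data.frame of target predictors (columns must
#'   match the model's predictor names).
#' @return List with `imputed` (data.frame, one column per response),
#'   `nn_ids` (`n_targets x k` matrix of reference row IDs, nearest first)
#'   and `proximity` (the `n_targets x n_references` nearness matrix).
#' @export
impute <- function(model, X_targets) {
  X_targets <- as.data.frame(X_targets)
  check_predictor_columns(model, X_targets)
  prox <- if (model$method == "random_forest") rf_proximity(model, X_targets)
          else distance_scores(model, X_targets)
  res <- aggregate_neighbors(prox, as.matrix(model$Y_ref), model$k,
                             model$aggregation)
  res$proximity <- prox
  res
}

#' Impute response variables wall-to-wall over a predictor raster
#'
#' Runs every cell of `predictors` through the model in horizontal chunks of
#' `chunk_rows` raster rows, bounding peak memory at roughly
#' `chunk_rows * n_cols * pooled_trees` leaf indices plus one
#' `chunk x n_ref` proximity block; the result is bit-identical for any
#' chunk size. Cells with any NoData predictor are NoData in every output
#' band.
#'
#' @param model A `knn_model`.
#' @param predictors A [grid_raster()] whose band names exactly match the
#'   model's predictor names.
#' @param chunk_rows Raster rows per chunk (clamped to the row count).
#' @return A `grid_raster` with one band per response plus an `nn_id` band
#'   holding the nearest reference's row ID.
#' @export
predict_targets <- function(model, predictors, chunk_rows = 64L) {
  if (chunk_rows < 1) stop("`chunk_rows` must be >= 1")
  if (!identical(predictors$band_names, model$predictor_names))
    stop("predictor raster bands do not match model predictors. expected: ",
         paste(model$predictor_names, collapse = ", "), "; got: ",
         paste(predictors$band_names, collapse = ", "))
  s <- predictors$spec
  chunk_rows <- min(as.integer(chunk_rows), s$n_rows)
  q <- length(model$response_names)
  out <- array(NA_real_, c(s$n_rows, s$n_cols, q + 1L))

  starts <- seq(1L, s$n_rows, by = chunk_rows)
  for (r0 in starts) {
    rows <- r0:min(r0 + chunk_rows - 1L, s$n_rows)
    block <- predictors$values[rows, , , drop = FALSE]
    Xb <- matrix(block, nrow = length(rows) * s$n_cols,
                 ncol = n_bands(predictors))
    colnames(Xb) <- predictors$band_names
    ok <- rowSums(is.na(Xb)) == 0L
    if (any(ok)) {
      res <- impute(model, as.data.frame(Xb[ok, , drop = FALSE]))
      blk <- matrix(NA_real_, nrow(Xb), q + 1L)
      blk[ok, seq_len(q)] <- as.matrix(res$imputed)
      blk[ok, q + 1L] <- res$nn_ids[, 1L]
      out[rows, , ] <- array(blk, c(length(rows), s$n_cols, q + 1L))
    }
  }
  grid_raster(out, s, c(model$response_names, "nn_id"), predictors$nodata)
}
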