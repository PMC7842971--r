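#' Imputation accuracy statistics
#'
#' Given observed and imputed values, computes the coefficient of
#' determination \eqn{R^2 = 1 - SSR/SST}, the root mean square error
#' \eqn{RMSE = \sqrt{\frac{1}{n}\sum (\hat y_i - y_i)^2}} and the bias
#' \eqn{\frac{1}{n}\sum (\hat y_i - y_i)}, plus their relative forms
#' (\eqn{100 \cdot stat / \bar y}). Pairs with a missing member are dropped.
#' \eqn{R^2} can be negative (predictions worse than the observed mean);
#' `RMSE >= |bias|` always holds.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2 complete
#'   pairs).
#' @return A one-row `data.frame`: `n`, `r2`, `rmse`, `bias`, `rmse_pct`,
#'   `bias_pct`, `ssr`, `sst`. When `mean(observed) == 0` the relative forms
#'   are `NA` with a warning.
#' @export
accuracy <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- is.finite(observed) & is.finite(predicted)
  y <- observed[ok]; yhat <- predicted[ok]
  if (length(y) < 2) stop("need at least 2 complete observed/predicted pairs")
  ssr <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  rmse <- sqrt(mean((yhat - y)^2))
  bias <- mean(yhat - y)
  ybar <- mean(y)
  if (ybar == 0) {
    warning("mean of observed values is 0; relative RMSE and bias undefined")
    rel <- c(NA_real_, NA_real_)
  } else rel <- 100 * c(rmse, bias) / ybar
  data.frame(n = length(y), r2 = 1 - ssr / sst, rmse = rmse, bias = bias,
             rmse_pct = rel[1], bias_pct = rel[2], ssr = ssr, sst = sst)
}

#' Per-fold and pooled accuracy report from cross-validated pairs
#'
#' @param cv A data.frame of held-out pairs as produced by [train_nn()]
#'   (columns `fold`, `response`, `observed`, `predicted`).
#' @return A `data.frame` with one row per (response, fold) plus one pooled
#'   row per response (`fold = "all"`), carrying the [accuracy()] columns.
#' @export
accuracy_report <- function(cv) {
  stopifnot(all(c("response", "observed", "predicted") %in% names(cv)))
  if (is.null(cv$fold)) cv$fold <- 1L
  rows <- list()
  for (r in unique(cv$response)) {
    d <- cv[cv$response == r, ]
    for (f in sort(unique(d$fold))) {
      a <- accuracy(d$observed[d$fold == f], d$predicted[d$fold == f])
      rows[[length(rows) + 1L]] <- cbind(response = r, fold = as.character(f), a)
    }
    rows[[length(rows) + 1L]] <-
      cbind(response = r, fold = "all", accuracy(d$observed, d$predicted))
  }
  do.call(rbind, rows)
}

#' Predictor importance of a random-forest k-NN model
#'
#' Raw importance of each predictor is the out-of-bag permutation importance
#' of the response forest: the increase in OOB mean square error when that
#' predictor is permuted while the others are left unchanged (computed at
#' fit time under the model seed, one permutation per predictor per forest).
#' With `scaled = TRUE` importances are standardized per response to
#' z-scores (centered by the mean and scaled by the standard deviation of
#' all predictor importances), so a negative scaled importance marks a
#' predictor below the average importance; the mean scaled importance across
#' responses is also returned.
#'
#' @param model A `knn_model` with `method = "random_forest"`.
#' @param scaled Return z-scored importances alongside raw values.
#' @return A `data.frame` with columns `predictor`, `response`, `raw` and
#'   (when scaled) `scaled`, plus rows `response = "mean"` holding the mean
#'   scaled importance per predictor.
#' @export
var_imp <- function(model, scaled = TRUE) {
  if (model$method != "random_forest")
    stop("variable importance requires method = 'random_forest'")
  out <- list()
  sc <- list()
  for (r in names(model$forests)) {
    raw <- model$forests[[r]]$variable.importance
    d <- data.frame(predictor = names(raw), response = r, raw = as.numeric(raw))
    if (scaled) {
      if (length(raw) < 2) {
        warning("z-scored importance undefined for a single predictor; set to 0")
        d$scaled <- 0
      } else if (stats::sd(raw) == 0) {
        warning("all predictor importances equal for response '", r,
                "'; z-scores set to 0")
        d$scaled <- 0
      } else d$scaled <- as.numeric(scale(raw))
    }
    out[[r]] <- d
    if (scaled) sc[[r]] <- d$scaled
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (scaled) {
    msc <- rowMeans(do.call(cbind, sc))
    res <- rbind(res, data.frame(predictor = out[[1]]$predictor,
                                 response = "mean", raw = NA_real_,
                                 scaled = msc))
  }
  res
}

#' Observed-versus-predicted scatterplots
#'
#' One panel per response with the 1:1 line (dashed), the best linear fit
#' (solid) and the pooled accuracy metrics annotated; cross-validation folds
#' are pooled and colored by fold.
#'
#' @param cv Held-out pairs as produced by [train_nn()] (columns `fold`,
#'   `response`, `observed`, `predicted`).
#' @param out_path Image path (extension selects the device, e.g. `.png`).
#' @param width,height Plot size in inches.
#' @return `out_path`, invisibly; the ggplot object as attribute `"plot"`.
#' @export
scatter_report <- function(cv, out_path, width = 5, height = 4.5) {
  stopifnot(nrow(cv) > 0)
  if (is.null(cv$fold)) cv$fold <- 1L
  rep_ <- accuracy_report(cv)
  ann <- rep_[rep_$fold == "all", ]
  ann$label <- sprintf("R² = %.2f\nRMSE%% = %.1f\nbias%% = %.1f",
                       ann$r2, ann$rmse_pct, ann$bias_pct)
  pos <- do.call(rbind, lapply(split(cv, cv$response), function(d)
    data.frame(response = d$response[1], x = min(d$observed, na.rm = TRUE),
               y = max(d$predicted, na.rm = TRUE))))
  ann <- merge(ann, pos, by = "response")
  g <- ggplot2::ggplot(cv, ggplot2::aes(x = observed, y = predicted)) +
    ggplot2::geom_point(ggplot2::aes(color = factor(fold)), alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "red", linewidth = 0.6) +
    ggplot2::geom_text(data = ann, ggplot2::aes(x = x, y = y, label = label),
                       hjust = 0, vjust = 1, size = 3) +
    ggplot2::facet_wrap(~response, scales = "free") +
    ggplot2::labs(x = "Observed", y = "Predicted", color = "Fold") +
    ggplot2::theme_bw()
  n_panel <- length(unique(cv$response))
  ggplot2::ggsave(out_path, g, width = width * max(1, n_panel), height = height,
                  dpi = 120)
  attr(out_path, "plot") <- g
  invisible(out_path)
}
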