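#' Sample design parameters
#'
#' @param n Requested sample size.
#' @param n_strata Number of k-means strata.
#' @param min_dist Minimum pairwise distance between sampled cell centroids,
#'   in map units (0 disables the constraint).
#' @param seed Integer seed fixing every random draw of the design.
#' @param max_attempts Candidate draws allowed before declaring a stratum
#'   quota unreachable (default `50 * n`).
#' @return An object of class `sample_design`.
#' @export
sample_design <- function(n, n_strata, min_dist = 0, seed = 1L,
                          max_attempts = NULL) {
  stopifnot(n >= n_strata, n_strata >= 1, min_dist >= 0)
  structure(list(n = as.integer(n), n_strata = as.integer(n_strata),
                 min_dist = as.numeric(min_dist), seed = as.integer(seed),
                 max_attempts = if (is.null(max_attempts)) 50L * as.integer(n)
                                else as.integer(max_attempts)),
            class = "sample_design")
}

#' Stratify response rasters by k-means clustering
#'
#' Standardizes each response band to zero mean and unit variance over the
#' finite cells (so mixed-unit attributes such as height in metres and cover
#' in percent weigh equally), then clusters the cell value vectors with
#' k-means (Lloyd's algorithm, `nstart` seeded restarts). Strata are
#' relabelled in ascending order of the first band's cluster mean, so labels
#' are stable and reproducible given the seed. NoData cells stay NoData.
#'
#' @param responses A [grid_raster()] of response variables.
#' @param n_strata Number of clusters.
#' @param seed Integer seed.
#' @param nstart Number of random restarts.
#' @param centers Optional matrix of initial cluster centers in
#'   *standardized* units (rows = strata); when given, a single Lloyd run
#'   from exactly these centers is performed.
#' @param scaling `"standardize"` (default) or `"minmax"`.
#' @return List with `strata` (a one-band `grid_raster` of integer labels in
#'   `1..n_strata`) and `centers` (per-stratum mean vectors on the original
#'   response scale).
#' @export
kmeans_stratify <- function(responses, n_strata, seed = 1L, nstart = 10L,
                            centers = NULL, scaling = c("standardize", "minmax")) {
  scaling <- match.arg(scaling)
  nb <- n_bands(responses)
  V <- matrix(responses$values, ncol = nb)
  colnames(V) <- responses$band_names
  ok <- rowSums(!is.finite(V)) == 0L
  if (sum(ok) < n_strata) stop("fewer finite cells than strata")
  X <- V[ok, , drop = FALSE]
  if (nrow(unique(X)) < n_strata) stop("fewer distinct finite cells than strata")
  Z <- if (scaling == "standardize") scale(X) else
    apply(X, 2, function(z) (z - min(z)) / max(max(z) - min(z), .Machine$double.eps))
  Z[!is.finite(Z)] <- 0  # constant band degenerates to zero contribution

  km <- withr::with_seed(seed, {
    if (is.null(centers))
      stats::kmeans(Z, centers = n_strata, nstart = nstart,
                    iter.max = 100L, algorithm = "Lloyd")
    else
      stats::kmeans(Z, centers = centers, iter.max = 100L, algorithm = "Lloyd")
  })
  # stable labels: ascending mean of band 1
  ord <- order(km$centers[, 1])
  relab <- integer(n_strata); relab[ord] <- seq_len(n_strata)
  lab <- relab[km$cluster]

  labs <- rep(NA_real_, nrow(V)); labs[ok] <- lab
  strata <- grid_raster(matrix(labs, responses$spec$n_rows, responses$spec$n_cols),
                        responses$spec, "stratum", responses$nodata)
  ctrs <- matrix(vapply(seq_len(n_strata),
                        function(s) colMeans(X[lab == s, , drop = FALSE]),
                        numeric(nb)),
                 nrow = n_strata, ncol = nb, byrow = TRUE,
                 dimnames = list(seq_len(n_strata), responses$band_names))
  list(strata = strata, centers = ctrs)
}

#' Largest-remainder apportionment of a sample across strata
#'
#' @param counts Named vector of stratum cell counts.
#' @param n Total sample size.
#' @return Integer quotas summing to `n`, each within 1 of exact
#'   proportionality.
#' @export
apportion_sample <- function(counts, n) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  exact <- n * counts / sum(counts)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(exact - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1L
  }
  stats::setNames(as.integer(base), names(counts))
}

#' Draw a stratified random sample with a minimum-distance constraint
#'
#' Per-stratum quotas are the largest-remainder apportionment of `design$n`
#' by stratum cell counts, so the sample mirrors each stratum's presence
#' across the reference area. Cells are then drawn uniformly at random
#' within each stratum, in a seeded randomized order, and accepted greedily
#' only if their centroid lies at least `design$min_dist` (Euclidean, map
#' units) from *every* previously accepted point. If a quota cannot be
#' filled within `design$max_attempts` candidate draws the function returns
#' fewer points and warns, naming the stratum and shortfall.
#'
#' @param strata One-band label [grid_raster()] from [kmeans_stratify()].
#' @param design A [sample_design()].
#' @return A `data.frame` of sample points with columns `id`, `x`, `y`,
#'   `row`, `col`, `stratum`; points lie on cell centers.
#' @export
draw_sample <- function(strata, design) {
  stopifnot(inherits(design, "sample_design"))
  lab <- band_matrix(strata, 1L)
  if (!any(is.finite(lab))) stop("strata raster is empty (all NoData)")
  cells <- which(is.finite(lab), arr.ind = TRUE)
  labs <- lab[cells]
  counts <- table(factor(labs, levels = sort(unique(labs))))
  quota <- apportion_sample(as.vector(counts), design$n)
  names(quota) <- names(counts)

  ctr <- cell_centers(strata$spec, cells[, 1], cells[, 2])
  acc_x <- numeric(0); acc_y <- numeric(0)
  acc_idx <- integer(0); attempts_left <- design$max_attempts

  withr::with_seed(design$seed, {
    for (s in names(quota)) {
      idx_s <- sample(which(labs == as.numeric(s)))  # randomized candidate order
      got <- 0L; i <- 1L
      while (got < quota[[s]] && i <= length(idx_s) && attempts_left > 0L) {
        cand <- idx_s[i]; i <- i + 1L; attempts_left <- attempts_left - 1L
        if (design$min_dist > 0 && length(acc_x)) {
          d2 <- (acc_x - ctr$x[cand])^2 + (acc_y - ctr$y[cand])^2
          if (min(d2) < design$min_dist^2) next
        }
        acc_idx <- c(acc_idx, cand)
        acc_x <- c(acc_x, ctr$x[cand]); acc_y <- c(acc_y, ctr$y[cand])
        got <- got + 1L
      }
      if (got < quota[[s]])
        warning(sprintf(
          "stratum %s: drew %d of %d requested points (min_dist = %g too restrictive)",
          s, got, quota[[s]], design$min_dist))
    }
  })
  data.frame(id = seq_along(acc_idx),
             x = ctr$x[acc_idx], y = ctr$y[acc_idx],
             row = ctr$row[acc_idx], col = ctr$col[acc_idx],
             stratum = as.integer(labs[acc_idx]))
}

#' Extract raster values at sample points
#'
#' Reads the containing cell of each point (no interpolation — points are
#' cell centroids by construction) and appends one named column per band of
#' `source`. Points outside the raster extent, or on NoData cells, get `NA`
#' and are retained; out-of-extent points additionally trigger a warning.
#'
#' @param source A [grid_raster()].
#' @param points Sample points `data.frame` (needs `x`, `y`) on the same CRS.
#' @param crs_id Optional CRS of the points; checked against `source` when
#'   given.
#' @return `points` with the band columns appended.
#' @export
get_sample_values <- function(source, points, crs_id = NULL) {
  if (!is.null(crs_id) && crs_id != source$spec$crs_id)
    stop("points CRS '", crs_id, "' does not match raster CRS '",
         source$spec$crs_id, "'")
  idx <- cell_index(source$spec, points$x, points$y)
  if (anyNA(idx$row))
    warning(sum(is.na(idx$row)), " point(s) outside the raster extent; values set NA")
  for (b in seq_len(n_bands(source))) {
    v <- rep(NA_real_, nrow(points))
    ok <- !is.na(idx$row)
    v[ok] <- band_matrix(source, b)[cbind(idx$row[ok], idx$col[ok])]
    points[[source$band_names[b]]] <- v
  }
  points
}

#' Stratum-balanced fold assignment
#'
#' Splits sample points into cross-validation folds (or a train/test
#' holdout) while keeping each k-means stratum's representation balanced
#' across folds: within every stratum the points are shuffled (seeded), each
#' fold receives an equal base share, and the remainder goes one-each to the
#' currently smallest folds — so per-stratum fold sizes differ by at most 1,
#' and so do total fold sizes. The held-out sets therefore span the full
#' structural range of the sample.
#'
#' @param strata_labels Integer stratum label per point.
#' @param scheme `"kfold"` or `"holdout"`.
#' @param kfold Number of folds (scheme `"kfold"`).
#' @param train_fraction Fraction assigned to training (scheme `"holdout"`).
#' @param seed Integer seed.
#' @return List with `fold` (integer per point: fold index, or 1 = train /
#'   2 = test for holdout), `scheme`, `kfold`, `seed`.
#' @export
partition <- function(strata_labels, scheme = c("kfold", "holdout"),
                      kfold = 5L, train_fraction = 0.8, seed = 1L) {
  scheme <- match.arg(scheme)
  n <- length(strata_labels)
  strata <- sort(unique(strata_labels))
  if (scheme == "kfold") {
    stopifnot(kfold >= 2)
    small <- min(table(strata_labels))
    if (kfold > small)
      warning("kfold exceeds the smallest stratum size (", small,
              "); some folds will lack that stratum")
    fold <- integer(n)
    totals <- integer(kfold)
    withr::with_seed(seed, {
      for (s in strata) {
        pts <- sample(which(strata_labels == s))
        base <- length(pts) %/% kfold; rem <- length(pts) %% kfold
        # remainder to the currently smallest folds (ties -> lowest index)
        extra <- order(totals, seq_len(kfold))[seq_len(rem)]
        sizes <- rep(base, kfold); sizes[extra] <- base + 1L
        f <- rep(seq_len(kfold), times = sizes)
        fold[pts] <- f
        totals <- totals + sizes
      }
    })
    list(fold = fold, scheme = "kfold", kfold = as.integer(kfold), seed = seed)
  } else {
    stopifnot(train_fraction > 0, train_fraction < 1)
    fold <- integer(n)
    withr::with_seed(seed, {
      for (s in strata) {
        pts <- sample(which(strata_labels == s))
        n_test <- max(1L, ceiling(length(pts) * (1 - train_fraction)))
        if (n_test >= length(pts)) n_test <- length(pts) - 1L
        fold[pts] <- c(rep(2L, n_test), rep(1L, length(pts) - n_test))
      }
    })
    list(fold = fold, scheme = "holdout", kfold = 2L, seed = seed,
         train_fraction = train_fraction)
  }
}

#' Write / read sample points as CSV
#'
#' @param points Sample points `data.frame`.
#' @param path CSV path.
#' @return `write_sample_points` returns `path` invisibly;
#'   `read_sample_points` the data.frame.
#' @export
write_sample_points <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_points
#' @export
read_sample_points <- function(path) utils::read.csv(path)
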