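#' Validate a pipeline configuration
#'
#' A pipeline config is a named list (or a YAML/JSON file parsing to one)
#' with `output_dir`, `seed`, `stages` (an ordered subset of
#' `fixture, preprocess, indices, temporal, sample, partition, train,
#' accuracy, varimp, impute`) and one optional parameter block per stage.
#' Inputs come either from the `fixture` stage (synthetic scene) or from
#' an `inputs` block of raster paths. In YAML configs the requested sample
#' size is spelled `n_sample` (YAML 1.1 reads a bare `n` key as a boolean). Validation checks stage dependencies
#' and the existence of every referenced input path before any computation,
#' and errors name the offending field or path.
#'
#' @param config Named list or path to a YAML/JSON config file.
#' @return The normalized config list, invisibly.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("fixture", "preprocess", "indices", "temporal", "sample",
             "partition", "train", "accuracy", "varimp", "impute")
  if (is.null(config$output_dir)) stop("config field missing: output_dir")
  if (is.null(config$stages)) stop("config field missing: stages")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1L

  deps <- list(indices = character(0), temporal = "indices",
               sample = character(0), partition = "sample",
               train = c("temporal", "sample", "partition"),
               accuracy = "train", varimp = "train",
               impute = c("train", "temporal"))
  have_inputs <- !is.null(config$inputs) || "fixture" %in% config$stages
  for (st in config$stages) {
    need <- deps[[st]]
    miss <- setdiff(need, config$stages)
    if (length(miss))
      stop("stage '", st, "' requires upstream stage(s): ",
           paste(miss, collapse = ", "))
  }
  if (any(config$stages != "fixture") && !have_inputs)
    stop("config needs either a 'fixture' stage or an 'inputs' block")
  if (!is.null(config$inputs)) {
    for (nm in names(config$inputs)) {
      v <- config$inputs[[nm]]
      paths <- if (is.list(v) && !is.null(v$paths)) v$paths else v
      if (is.character(paths))
        for (pth in paths) if (!file.exists(pth))
          stop("inputs$", nm, ": path does not exist: ", pth)
    }
  }
  invisible(config)
}

cfg_get <- function(config, stage, field, default) {
  v <- config[[stage]][[field]]
  if (is.null(v)) default else v
}

#' Run the imputation workflow from a declarative config
#'
#' Executes the configured stages in order — synthetic fixture generation,
#' spectral indices, temporal summary metrics, structure-guided sampling,
#' fold partitioning, k-NN model training with cross-validation, accuracy
#' and importance reporting, and wall-to-wall imputation — writing every
#' artifact under `output_dir` and returning a manifest with paths, MD5
#' checksums of the text artifacts and per-stage summaries. Every random
#' stage derives its seed from the config, so re-running an unchanged
#' config reproduces identical artifacts.
#'
#' @param config Config list or file path; see [validate_config()].
#' @return Manifest list: `artifacts` (data.frame of `stage`, `path`,
#'   `md5`), `summaries` (per-stage list), `config_seed`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  art <- list(); summ <- list()
  note <- function(stage, path) art[[length(art) + 1L]] <<-
    data.frame(stage = stage, path = path)

  state <- list()  # in-memory objects flowing between stages
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    if (!is.null(inp$time_series))
      state$ts <- raster_time_series(lapply(inp$time_series$paths, read_raster),
                                     inp$time_series$years)
    for (nm in c("dem", "slope", "responses", "mask"))
      if (!is.null(inp[[nm]])) state[[nm]] <- read_raster(inp[[nm]])
  }

  for (st in config$stages) {
    if (st == "fixture") {
      prm <- do.call(scene_params,
                     c(config$fixture[setdiff(names(config$fixture), "seed")],
                       list(seed = cfg_get(config, "fixture", "seed", seed))))
      sc <- make_scene(prm)
      state$ts <- sc$ts; state$dem <- sc$dem; state$slope <- sc$slope
      state$mask <- sc$mask; state$responses <- sc$responses
      state$truth <- sc$truth
      p <- file.path(out_dir, "responses.json"); write_raster(sc$responses, p)
      note(st, p)
      p <- file.path(out_dir, "dem.json"); write_raster(sc$dem, p); note(st, p)
      summ[[st]] <- list(n_years = length(sc$ts$years),
                         grid = c(prm$n_rows, prm$n_cols))
    } else if (st == "indices") {
      idx <- cfg_get(config, "indices", "indices", c("NDVI", "TCB", "TCG", "TCW"))
      bm <- do.call(band_map, as.list(cfg_get(
        config, "indices", "bands",
        list(blue = 1, green = 2, red = 3, nir = 4, swir1 = 5, swir2 = 6))))
      state$index_ts <- raster_time_series(
        lapply(state$ts$layers, calc_indices, indices = idx, bands = bm),
        state$ts$years)
      summ[[st]] <- list(indices = idx)
    } else if (st == "temporal") {
      mets <- cfg_get(config, "temporal", "metrics", c("median", "IQR", "theil_sen"))
      tm <- temporal_summary(state$index_ts, mets,
                             min_valid = cfg_get(config, "temporal", "min_valid", 3L))
      anc <- Filter(Negate(is.null), list(DEM = state$dem, DEM_slope = state$slope))
      v <- array(c(tm$values, unlist(lapply(anc, function(a) a$values))),
                 c(tm$spec$n_rows, tm$spec$n_cols, n_bands(tm) + length(anc)))
      state$predictors <- grid_raster(v, tm$spec, c(tm$band_names, names(anc)))
      p <- file.path(out_dir, "predictors.json")
      write_raster(state$predictors, p); note(st, p)
      summ[[st]] <- list(bands = state$predictors$band_names)
    } else if (st == "sample") {
      resp <- state$responses
      if (!is.null(state$mask)) resp <- match_extent(resp, state$mask, mask_nodata = TRUE)
      km <- kmeans_stratify(resp, cfg_get(config, "sample", "n_strata", 5L),
                            seed = cfg_get(config, "sample", "seed", seed))
      # YAML 1.1 parses a bare `n:` key as a boolean, so the config key is
      # `n_sample`; plain-list configs may still say `n`
      n_req <- cfg_get(config, "sample", "n",
                       cfg_get(config, "sample", "n_sample", 230L))
      des <- sample_design(n_req,
                           cfg_get(config, "sample", "n_strata", 5L),
                           cfg_get(config, "sample", "min_dist", 75),
                           seed = cfg_get(config, "sample", "seed", seed))
      pts <- draw_sample(km$strata, des)
      pts <- get_sample_values(state$responses, pts)
      state$points <- pts
      p <- file.path(out_dir, "sample_points.csv")
      write_sample_points(pts, p); note(st, p)
      summ[[st]] <- list(n_points = nrow(pts),
                         per_stratum = as.list(table(pts$stratum)))
    } else if (st == "partition") {
      state$folds <- partition(state$points$stratum, scheme = "kfold",
                               kfold = cfg_get(config, "partition", "kfold", 5L),
                               seed = cfg_get(config, "partition", "seed", seed))
      state$points$fold <- state$folds$fold
      summ[[st]] <- list(fold_sizes = as.list(table(state$folds$fold)))
    } else if (st == "train") {
      pts <- get_sample_values(state$predictors, state$points)
      Xn <- state$predictors$band_names
      Yn <- state$responses$band_names
      model <- train_nn(pts[Xn], pts[Yn],
                        k = cfg_get(config, "train", "k", 1L),
                        folds = state$folds,
                        ntree = cfg_get(config, "train", "ntree", 200L),
                        mtry = cfg_get(config, "train", "mtry", NULL),
                        aggregation = cfg_get(config, "train", "aggregation",
                                              "distance_weighted_mean"),
                        seed = cfg_get(config, "train", "seed", seed))
      state$model <- model
      p <- file.path(out_dir, "cv_pairs.csv")
      utils::write.csv(model$cv, p, row.names = FALSE); note(st, p)
      summ[[st]] <- list(k = model$k, ntree = model$ntree, mtry = model$mtry,
                         n_ref = nrow(model$X_ref))
    } else if (st == "accuracy") {
      rep_ <- accuracy_report(state$model$cv)
      p <- file.path(out_dir, "accuracy.csv")
      utils::write.csv(rep_, p, row.names = FALSE); note(st, p)
      state$accuracy <- rep_
      pooled <- rep_[rep_$fold == "all", ]
      summ[[st]] <- stats::setNames(as.list(round(pooled$r2, 4)), pooled$response)
    } else if (st == "varimp") {
      vi <- var_imp(state$model, scaled = TRUE)
      p <- file.path(out_dir, "importance.csv")
      utils::write.csv(vi, p, row.names = FALSE); note(st, p)
      state$importance <- vi
      summ[[st]] <- list(top = vi$predictor[which.max(
        ifelse(is.na(vi$raw), -Inf, vi$raw))])
    } else if (st == "impute") {
      imp <- predict_targets(state$model, state$predictors,
                             chunk_rows = cfg_get(config, "impute", "chunk_rows", 64L))
      state$imputed <- imp
      p <- file.path(out_dir, "imputed.json"); write_raster(imp, p); note(st, p)
      summ[[st]] <- list(bands = imp$band_names)
    }
  }

  artifacts <- do.call(rbind, art)
  if (!is.null(artifacts)) {
    extra <- list()
    for (pth in artifacts$path) if (grepl("\\.json$", pth)) {
      hdr <- jsonlite::read_json(pth, simplifyVector = TRUE)
      if (identical(hdr$format, "forstruct_stack"))
        extra[[length(extra) + 1L]] <-
          data.frame(stage = artifacts$stage[artifacts$path == pth],
                     path = file.path(dirname(pth), hdr$files))
    }
    artifacts <- rbind(artifacts, do.call(rbind, extra))
    artifacts$md5 <- unname(tools::md5sum(artifacts$path))
  }
  manifest <- list(artifacts = artifacts, summaries = summ, config_seed = seed)
  jsonlite::write_json(
    list(config_seed = seed,
         artifacts = artifacts,
         summaries = summ),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  manifest$state <- state
  invisible(manifest)
}
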