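#' Pipeline configuration
#'
#' Nested configuration for the full recognition pipeline
#' (simulate -> binarize -> segment -> featurize -> learn -> encode ->
#' classify -> evaluate). Every section is validated up front and unknown
#' keys are rejected, so a typo cannot silently fall back to a default.
#'
#' @param synth Arguments for [synth_image_config()].
#' @param preprocessing List: `opening_radius`, `min_seed_distance`,
#'   `min_area`, `roi_shape`.
#' @param features List: `feature` (one of `"raw"`, `"hog"`, `"gist"`,
#'   `"sift"`), `raw_shape`, `standardize`.
#' @param tsc Arguments for [tsc_config()] plus `enabled` (set `FALSE` for
#'   the no-sparse-coding ablation arm, feeding the features directly to
#'   the classifier).
#' @param svm Arguments for [svm_config()].
#' @param evaluation List: `train_frames`, the number of leading frames
#'   used for training (temporal prefix split; the remainder is the test
#'   set).
#' @param run_seed Integer master seed; stage seeds derive from it.
#' @param output_dir Optional directory for stage artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = list(), preprocessing = list(),
                            features = list(), tsc = list(), svm = list(),
                            evaluation = list(), run_seed = 1L,
                            output_dir = NULL) {
  defaults <- list(
    preprocessing = list(opening_radius = 2, min_seed_distance = 15,
                         min_area = 30, roi_shape = c(32, 32)),
    features = list(feature = "raw", raw_shape = c(9, 6), standardize = TRUE),
    tsc = list(enabled = TRUE, lambda = 0.1, gamma = 0.1, epsilon = 1e-2,
               C = 1, grid_rows = 8, grid_cols = 8, group_size = 2,
               wraparound = TRUE, batch_size = 64, max_outer_iters = 30,
               max_inner_iters = 100, tol_rel = 1e-6, step_init = 1.0,
               seed = NULL),
    svm = list(delta = NULL, C_svm = 10),
    evaluation = list(train_frames = NULL)
  )
  check_keys <- function(given, allowed, section) {
    bad <- setdiff(names(given), allowed)
    if (length(bad)) {
      abort(sprintf("unknown %s config key(s): %s", section,
                    paste(bad, collapse = ", ")))
    }
  }
  check_keys(synth, names(formals(synth_image_config)), "synth")
  for (sec in names(defaults)) {
    check_keys(get(sec), names(defaults[[sec]]), sec)
  }
  cfg <- list(
    synth = synth,
    preprocessing = modifyList(defaults$preprocessing, preprocessing),
    features = modifyList(defaults$features, features),
    tsc = modifyList(defaults$tsc, tsc),
    svm = modifyList(defaults$svm, svm),
    evaluation = modifyList(defaults$evaluation, evaluation),
    run_seed = as.integer(run_seed),
    output_dir = output_dir
  )
  if (!cfg$features$feature %in% c("raw", "hog", "gist", "sift")) {
    abort("features$feature must be one of raw, hog, gist, sift")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with the sections of [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

extract_feature <- function(patch, cfg) {
  switch(cfg$feature,
         raw = raw_feature(patch, cfg$raw_shape),
         hog = hog_feature(patch),
         gist = gist_feature(patch),
         sift = sift_feature(patch))
}

# Match segmented regions to ground-truth nuclei by nearest centroid
# (within max_dist px); unmatched regions are dropped.
match_regions_to_truth <- function(regions, truth, max_dist = 15) {
  if (nrow(regions) == 0 || nrow(truth) == 0) return(integer(0))
  vapply(seq_len(nrow(regions)), function(i) {
    d <- sqrt((truth$row - 1 - regions$row[i])^2 + (truth$col - 1 - regions$col[i])^2)
    j <- which.min(d)
    if (d[j] <= max_dist) j else NA_integer_
  }, integer(1))
}

#' Run the full phase-recognition pipeline on synthetic frames
#'
#' Generates labeled scenes, segments every frame (Otsu binarization +
#' seeded watershed), extracts ROI patches and the configured feature, and
#' splits the per-nucleus samples by frame order into a temporal-prefix
#' training set and a held-out test set. With the sparse-coding stage
#' enabled, a topographic dictionary is learned on the training features
#' and both sets are encoded; the codes (otherwise the features) are fed to
#' the one-vs-rest RBF SVM. Returns the evaluation report on the test set.
#'
#' @param config A [pipeline_config()].
#' @param scenes Optional pre-generated scene list (bypasses the synth
#'   stage; must carry ground-truth `cells` tables).
#' @return A list of class `topo_run`: `metrics` ([metrics_report()] on the
#'   test set), `predictions` tibble, `tsc_fit` (or `NULL` on the ablation
#'   arm), `svm`, `manifest` (per-stage timing and artifact digests when
#'   `output_dir` is set), and `config`.
#' @export
run_pipeline <- function(config, scenes = NULL) {
  cfg <- config
  t_all <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    t_all[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  scenes <- scenes %||% stage("simulate", {
    sc <- cfg$synth
    sc$seed <- sc$seed %||% cfg$run_seed
    generate_cell_frames(do.call(synth_image_config, sc))
  })
  n_frames <- length(scenes)

  samples <- stage("segment+featurize", {
    pp <- cfg$preprocessing
    dplyr::bind_rows(lapply(seq_len(n_frames), function(f) {
      sc <- scenes[[f]]
      mask <- binarize(sc$frame, opening_radius = pp$opening_radius)
      labels <- segment_nuclei(sc$frame, mask, pp$min_seed_distance, pp$min_area)
      rois <- extract_rois(sc$frame, labels, pp$roi_shape)
      if (length(rois) == 0) return(NULL)
      regs <- region_table(labels)
      hit <- match_regions_to_truth(regs, sc$cells)
      keep <- which(!is.na(hit))
      if (!length(keep)) return(NULL)
      tibble::tibble(
        frame_id = f,
        cell_id = regs$cell_id[keep],
        phase = as.character(sc$cells$phase[hit[keep]]),
        feature = lapply(keep, function(i) extract_feature(rois[[i]], cfg$features))
      )
    }))
  })
  if (is.null(samples) || nrow(samples) == 0) abort("pipeline produced no nuclei")

  n_train_frames <- cfg$evaluation$train_frames %||% ceiling(2 * n_frames / 3)
  is_train <- samples$frame_id <= n_train_frames
  if (!any(is_train) || all(is_train)) {
    abort("temporal split left an empty training or test set")
  }
  x_train_raw <- do.call(cbind, samples$feature[is_train])
  x_test_raw <- do.call(cbind, samples$feature[!is_train])
  attr(x_train_raw, "feature_name") <- attr(samples$feature[[1]], "feature_name")
  attr(x_test_raw, "feature_name") <- attr(samples$feature[[1]], "feature_name")

  if (isTRUE(cfg$features$standardize)) {
    x_train <- assemble_feature_matrix(samples$feature[is_train], standardize = TRUE)
    x_test <- apply_standardization(x_test_raw, x_train)
  } else {
    x_train <- x_train_raw
    x_test <- x_test_raw
  }

  fit <- NULL
  if (isTRUE(cfg$tsc$enabled)) {
    # one global scale puts every training column inside the unit code-norm
    # ball while preserving relative sample magnitudes (a class cue)
    g_scale <- max(sqrt(colSums(x_train^2)))
    xs_train <- x_train / g_scale
    xs_test <- x_test / g_scale
    fit <- stage("learn+encode", {
      targs <- cfg$tsc
      targs$enabled <- NULL
      targs$batch_size <- min(targs$batch_size, ncol(xs_train))
      targs$seed <- targs$seed %||% (cfg$run_seed + 1L)
      tsc_learn(xs_train, do.call(tsc_config, targs))
    })
    z_train <- fit$codes
    z_test <- encode(fit$dictionary, xs_test, fit$V, fit$config)$codes
  } else {
    z_train <- x_train
    z_test <- x_test
  }

  model <- stage("classify", {
    sargs <- cfg$svm
    sargs$seed <- cfg$run_seed + 2L
    train_svm(z_train, samples$phase[is_train], do.call(svm_config, sargs))
  })
  pred <- predict(model, z_test)

  metrics <- stage("evaluate", {
    metrics_report(samples$phase[!is_train], as.character(pred))
  })
  predictions <- tibble::tibble(
    frame_id = samples$frame_id[!is_train],
    cell_id = samples$cell_id[!is_train],
    true = samples$phase[!is_train],
    predicted = as.character(pred))

  manifest <- list(timing = tibble::tibble(stage = names(t_all),
                                           seconds = unlist(t_all)),
                   run_seed = cfg$run_seed,
                   package_version = as.character(utils::packageVersion("topocode")),
                   artifacts = NULL)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      predictions = write_table_txt(predictions,
                                    file.path(cfg$output_dir, "predictions.tsv")),
      metrics = write_table_txt(metrics, file.path(cfg$output_dir, "metrics.tsv")))
    if (!is.null(fit)) {
      paths <- c(paths, dictionary = write_matrix(
        fit$dictionary, file.path(cfg$output_dir, "dictionary.bin"),
        tag = "dictionary"))
    }
    manifest$artifacts <- tibble::tibble(
      name = names(paths), path = unname(paths),
      md5 = unname(tools::md5sum(unname(paths))))
  }

  structure(list(metrics = metrics, predictions = predictions,
                 tsc_fit = fit, svm = model, manifest = manifest,
                 config = cfg,
                 arm = if (isTRUE(cfg$tsc$enabled)) "tsc" else "no-tsc"),
            class = "topo_run")
}

#' @export
print.topo_run <- function(x, ...) {
  acc <- x$metrics$accuracy[x$metrics$class == "overall"]
  cat(sprintf("Phase-recognition run (%s arm): %d test nuclei, multi-class accuracy %.3f (error rate %.3f)\n",
              x$arm, nrow(x$predictions), acc, 1 - acc))
  invisible(x)
}
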