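# Gradient-boosted decision-tree classifiers, one per N-phosphorylation
# type, trained on the per-type default feature combinations.

# Feature combinations selected per site type (model-selection result the
# pipeline reproduces): pHis and pArg use AAC+HQI8, pLys uses all three.
DEFAULT_COMBOS <- list(pHis = c("AAC", "HQI8"),
                       pLys = c("AAC", "HQI8", "BLOSUM62"),
                       pArg = c("AAC", "HQI8"))

#' Default feature combination for a site type
#'
#' @param site_type One of `"pHis"`, `"pLys"`, `"pArg"`.
#' @return Character vector of feature-set names.
#' @export
default_combo <- function(site_type) {
  stopifnot(site_type %in% names(DEFAULT_COMBOS))
  DEFAULT_COMBOS[[site_type]]
}

default_gbdt_params <- function() {
  list(objective = "binary:logistic", eta = 0.1, max_depth = 4L,
       min_child_weight = 1, subsample = 1, colsample_bytree = 1,
       tree_method = "hist", nthread = 1L)
}

#' A small default hyperparameter grid for GBDT tuning
#'
#' Tree count, depth and learning rate; searched by mean k-fold
#' cross-validated AUC when passed to [train_model()].
#'
#' @return Data frame with columns `nrounds`, `max_depth`, `eta`.
#' @export
default_hyper_grid <- function() {
  expand.grid(nrounds = c(100L, 200L), max_depth = c(3L, 4L, 6L),
              eta = c(0.05, 0.1))
}

dataset_fingerprint <- function(examples, seed) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(examples$peptide, examples$label, sep = "\t"), f)
  list(md5 = unname(tools::md5sum(f)), n = nrow(examples), seed = seed)
}

fit_gbdt <- function(features, labels, params, nrounds, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(features, label = labels)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = nrounds, verbose = 0)
}

#' Train a gradient-boosted classifier for one site type
#'
#' Encodes the examples' windows with the site type's feature combination
#' and fits a boosted-tree ensemble. When a hyperparameter grid is given,
#' the grid point with the highest mean k-fold cross-validated AUC on the
#' training data is selected before the final refit on all of it.
#'
#' @param examples Example data frame with `peptide` and `label` columns
#'   containing both classes.
#' @param site_type One of `"pHis"`, `"pLys"`, `"pArg"`.
#' @param combo Feature combination; defaults to the site type's.
#' @param nrounds Number of boosting rounds.
#' @param params Booster parameters (merged over the defaults).
#' @param hyper_grid Optional data frame of candidate `nrounds`,
#'   `max_depth`, `eta` values.
#' @param cv_folds Folds used for grid selection.
#' @param seed Seed controlling all randomness of the fit.
#' @return A `model_bundle`: booster plus its combo, hyperparameters,
#'   cutoff, training fingerprint and package version.
#' @export
train_model <- function(examples, site_type, combo = default_combo(site_type),
                        nrounds = 200L, params = list(), hyper_grid = NULL,
                        cv_folds = 10L, seed = 1L) {
  stopifnot(all(c("peptide", "label") %in% names(examples)))
  if (length(unique(examples$label)) < 2L) {
    stop("training data must contain both classes")
  }
  full_params <- utils::modifyList(default_gbdt_params(), params)
  features <- encode_windows(examples$peptide, combo)
  labels <- examples$label

  if (!is.null(hyper_grid)) {
    set.seed(seed)
    fold_id <- stratified_folds(labels, cv_folds)
    score_point <- function(g) {
      aucs <- vapply(seq_len(cv_folds), function(k) {
        tr <- fold_id != k
        p <- utils::modifyList(full_params,
                               list(max_depth = g$max_depth, eta = g$eta))
        fit <- fit_gbdt(features[tr, , drop = FALSE], labels[tr], p,
                        g$nrounds, seed + k)
        pred <- predict(fit, xgboost::xgb.DMatrix(
          features[!tr, , drop = FALSE]))
        auc_score(labels[!tr], pred)
      }, numeric(1L))
      mean(aucs)
    }
    cv_auc <- vapply(seq_len(nrow(hyper_grid)),
                     function(i) score_point(hyper_grid[i, ]), numeric(1L))
    best <- hyper_grid[which.max(cv_auc), ]
    nrounds <- best$nrounds
    full_params <- utils::modifyList(full_params,
                                     list(max_depth = best$max_depth,
                                          eta = best$eta))
  }

  booster <- fit_gbdt(features, labels, full_params, nrounds, seed)
  structure(list(site_type = site_type,
                 combo = attr(features, "combo"),
                 booster = booster,
                 nrounds = nrounds,
                 params = full_params,
                 cutoff = 0.5,
                 feature_names = colnames(features),
                 fingerprint = dataset_fingerprint(examples, seed),
                 version = as.character(packageVersion("npsite"))),
            class = "model_bundle")
}

#' Predict phosphosite probabilities with a trained bundle
#'
#' @param object A `model_bundle`.
#' @param peptides Character vector of peptide windows (or an example data
#'   frame with a `peptide` column).
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.model_bundle <- function(object, peptides, ...) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  features <- encode_windows(peptides, object$combo)
  stopifnot(identical(colnames(features), object$feature_names))
  predict(object$booster, xgboost::xgb.DMatrix(features))
}

#' @export
print.model_bundle <- function(x, ...) {
  cat("N-phosphosite GBDT bundle\n",
      "  type:    ", x$site_type, "\n",
      "  combo:   ", paste(x$combo, collapse = "+"),
      " (", length(x$feature_names), " features)\n",
      "  rounds:  ", x$nrounds, " depth ", x$params$max_depth,
      " eta ", x$params$eta, "\n",
      "  trained: n=", x$fingerprint$n, " md5=",
      substr(x$fingerprint$md5, 1, 8), " seed=", x$fingerprint$seed, "\n",
      sep = "")
  invisible(x)
}

evaluate_on <- function(bundle, examples, cutoff = bundle$cutoff) {
  prob <- predict(bundle, examples)
  cm <- confusion_counts(examples$label, as.integer(prob > cutoff))
  c(metrics_from_confusion(cm), auc = auc_score(examples$label, prob))
}

#' Repeated hold-out evaluation
#'
#' For each of `n_repeats` seeded stratified splits, trains on the training
#' fraction, scores the held-out part at the probability cutoff, and reports
#' all six confusion metrics plus threshold-free AUC as mean +/- sd.
#'
#' @param examples Example data frame (`peptide`, `label`).
#' @param site_type Site type; sets the default feature combination.
#' @param plan A [split_plan()].
#' @param combo,nrounds,params Passed to [train_model()].
#' @param cutoff Probability cutoff for hard calls.
#' @return A [metrics_report()] over the repeats.
#' @export
evaluate_repeated <- function(examples, site_type, plan = split_plan(),
                              combo = default_combo(site_type),
                              nrounds = 200L, params = list(), cutoff = 0.5) {
  splits <- split_dataset(examples$label, plan)
  rows <- lapply(seq_along(splits), function(r) {
    sp <- splits[[r]]
    bundle <- train_model(examples[sp$train, , drop = FALSE], site_type,
                          combo = combo, nrounds = nrounds, params = params,
                          seed = plan$seed * 1000L + r)
    evaluate_on(bundle, examples[sp$test, , drop = FALSE], cutoff)
  })
  metrics_report(as.data.frame(do.call(rbind, rows)))
}

#' Repeated stratified k-fold cross-validation
#'
#' Out-of-fold predictions are pooled within each repeat (every training
#' example is predicted exactly once per repeat), metrics are computed per
#' repeat, and mean +/- sd across repeats is reported.
#'
#' @param examples Example data frame (`peptide`, `label`).
#' @param site_type Site type; sets the default feature combination.
#' @param k Number of folds.
#' @param repeats Number of shuffled repeats.
#' @param seed Top-level seed.
#' @param combo,nrounds,params Passed to [train_model()].
#' @param cutoff Probability cutoff for hard calls.
#' @return A [metrics_report()] over the repeats.
#' @export
cross_validate <- function(examples, site_type, k = 10L, repeats = 10L,
                           seed = 1L, combo = default_combo(site_type),
                           nrounds = 200L, params = list(), cutoff = 0.5) {
  labels <- examples$label
  if (min(table(labels)) < k) stop("fewer examples in a class than folds")
  rows <- lapply(seq_len(repeats), function(r) {
    set.seed(seed * 1000L + r)
    fold_id <- stratified_folds(labels, k)
    prob <- numeric(length(labels))
    for (f in seq_len(k)) {
      tr <- fold_id != f
      bundle <- train_model(examples[tr, , drop = FALSE], site_type,
                            combo = combo, nrounds = nrounds, params = params,
                            seed = seed * 1000L + r * 100L + f)
      prob[!tr] <- predict(bundle, examples[!tr, , drop = FALSE])
    }
    cm <- confusion_counts(labels, as.integer(prob > cutoff))
    c(metrics_from_confusion(cm), auc = auc_score(labels, prob))
  })
  metrics_report(as.data.frame(do.call(rbind, rows)))
}

#' Save a trained model bundle
#'
#' The bundle is written with its feature combination, hyperparameters,
#' training fingerprint and package version; [load_bundle()] refuses to load
#' a bundle written by an incompatible major version.
#'
#' @param bundle A `model_bundle`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  obj <- unclass(bundle)
  obj$booster_raw <- xgboost::xgb.save.raw(bundle$booster)
  obj$booster <- NULL
  saveRDS(obj, path)
  invisible(path)
}

#' Load a trained model bundle
#'
#' @param path Path written by [save_bundle()].
#' @return A `model_bundle`.
#' @export
load_bundle <- function(path) {
  obj <- readRDS(path)
  here <- package_version(as.character(packageVersion("npsite")))
  there <- package_version(obj$version)
  if (there$major != here$major) {
    stop("bundle written by incompatible package version ", obj$version)
  }
  obj$booster <- xgboost::xgb.load.raw(obj$booster_raw)
  obj$booster_raw <- NULL
  structure(obj, class = "model_bundle")
}
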