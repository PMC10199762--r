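ALGORITHMS <- c("random_forest", "extra_trees", "gradient_boosting",
                "additive_boosting", "svm")

#' Train a classifier on a feature matrix
#'
#' Supported algorithms: `random_forest` and `extra_trees` (probability
#' forests via ranger, impurity importance recorded), `gradient_boosting`
#' (xgboost, depth-3 trees), `additive_boosting` (xgboost restricted to
#' depth-1 stumps — a boosted generalized additive model, directly
#' interpretable through per-feature response curves), and `svm` (RBF
#' kernel with probability outputs via e1071). Hyperparameters default to
#' the library defaults with a fixed seed and are recorded in the bundle.
#'
#' @param matrix Numeric feature matrix (rows = peptides).
#' @param labels Binary labels (epitope = positive).
#' @param algorithm One of the algorithm ids above.
#' @param features Feature names to train on (default: all columns).
#' @param hyperparameters Named list overriding algorithm defaults
#'   (`num.trees` for forests; `nrounds`, `eta`, `max_depth` for
#'   boosting; `cost`, `gamma` for svm).
#' @param seed Integer seed; training is reproducible under it.
#' @param threshold Decision threshold stored with the bundle.
#' @return A `model_bundle`: `algorithm`, `features`, `model` (opaque
#'   fitted state), `hyperparameters`, `seed`, `threshold`,
#'   `aat_fingerprint` (copied from the matrix, if present).
#' @export
train_model <- function(matrix, labels, algorithm = "random_forest",
                        features = colnames(matrix),
                        hyperparameters = list(), seed = 1L,
                        threshold = 0.5) {
  if (!algorithm %in% ALGORITHMS)
    stop("unknown algorithm ", sQuote(algorithm), "; available: ",
         paste(ALGORITHMS, collapse = ", "), call. = FALSE)
  missing <- setdiff(features, colnames(matrix))
  if (length(missing) > 0L)
    stop("feature matrix is missing column(s): ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  y <- as_binary_labels(labels)
  x <- matrix[, features, drop = FALSE]
  hp <- hyperparameters
  model <- switch(
    algorithm,
    random_forest = ,
    extra_trees = {
      hp$num.trees <- hp$num.trees %||% 500L
      args <- list(x = as.data.frame(x, check.names = FALSE),
                   y = factor(y, levels = c(0, 1)),
                   probability = TRUE, importance = "impurity",
                   num.trees = hp$num.trees, seed = seed,
                   num.threads = 1L)
      if (algorithm == "extra_trees") args$splitrule <- "extratrees"
      do.call(ranger::ranger, args)
    },
    gradient_boosting = ,
    additive_boosting = {
      hp$nrounds <- hp$nrounds %||% 150L
      hp$eta <- hp$eta %||% 0.1
      hp$max_depth <- hp$max_depth %||%
        if (algorithm == "additive_boosting") 1L else 3L
      dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = hp$eta,
                      max_depth = hp$max_depth, nthread = 1L, seed = seed),
        data = dm, nrounds = hp$nrounds, verbose = 0)
    },
    svm = {
      hp$cost <- hp$cost %||% 1
      with_seed(seed, e1071::svm(
        x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
        cost = hp$cost, kernel = "radial"))
    })
  structure(list(algorithm = algorithm, features = features, model = model,
                 hyperparameters = hp, seed = as.integer(seed),
                 threshold = threshold,
                 aat_fingerprint = attr(matrix, "aat_fingerprint")),
            class = "model_bundle")
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict epitope scores from a trained bundle
#'
#' Scores are predicted epitope-class probabilities in \[0, 1\]. The
#' matrix must contain every feature the bundle was trained on (extra
#' columns are ignored); a missing feature is an error naming it. When
#' both the bundle and the matrix carry an AAT-scale fingerprint they must
#' match — featurizing a test set with a scale refit on it would leak.
#'
#' @param bundle A `model_bundle` from [train_model()].
#' @param matrix Feature matrix to score.
#' @return Numeric vector of scores, one per row, named by row names.
#' @export
predict_scores <- function(bundle, matrix) {
  stopifnot(inherits(bundle, "model_bundle"))
  missing <- setdiff(bundle$features, colnames(matrix))
  if (length(missing) > 0L)
    stop("matrix is missing selected feature(s): ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  fp_m <- attr(matrix, "aat_fingerprint")
  if (!is.null(bundle$aat_fingerprint) && !is.null(fp_m) &&
      !identical(bundle$aat_fingerprint, fp_m))
    stop("AAT-scale fingerprint mismatch: the matrix was featurized with ",
         "a different scale than the model was trained with (refitting ",
         "the scale on evaluation data leaks labels)", call. = FALSE)
  x <- matrix[, bundle$features, drop = FALSE]
  scores <- switch(
    bundle$algorithm,
    random_forest = ,
    extra_trees = {
      p <- stats::predict(bundle$model,
                          data = as.data.frame(x, check.names = FALSE),
                          num.threads = 1L)$predictions
      p[, "1"]
    },
    gradient_boosting = ,
    additive_boosting = stats::predict(bundle$model, x),
    svm = {
      p <- attr(stats::predict(bundle$model, x, probability = TRUE),
                "probabilities")
      p[, "1"]
    })
  stats::setNames(pmin(1, pmax(0, as.numeric(scores))), rownames(matrix))
}

#' @export
predict.model_bundle <- function(object, newdata, ...) {
  predict_scores(object, newdata)
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %s, %d feature(s), seed %d\n",
              x$algorithm, length(x$features), x$seed))
  invisible(x)
}

#' @keywords internal
#' @noRd
make_stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      rows <- which(y == cls)
      if (length(rows) < k)
        stop("class with ", length(rows), " member(s) cannot fill ", k,
             " folds; use a smaller k", call. = FALSE)
      fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Trains and evaluates the chosen algorithm on stratified folds and
#' reports per-fold and aggregate metrics. The fold assignment and all
#' training is reproducible under `seed`. The matrix must have been built
#' leakage-free (any training-data-fitted component, such as the AAT
#' scale, fit on data disjoint from what the CV metrics will be read as
#' generalization evidence for); [run_pipeline()] handles the record-level
#' version with per-split AAT refitting.
#'
#' @inheritParams train_model
#' @param k Number of folds (default 10).
#' @return List of class `cv_report`: `folds` (list of
#'   [compute_metrics()] reports), `mean` and `sd` (named vectors over
#'   mcc, roc_auc, f1, balanced_accuracy), `fold_assignment`.
#' @export
cross_validate <- function(matrix, labels, algorithm = "random_forest",
                           k = 10L, seed = 1L, features = colnames(matrix),
                           hyperparameters = list(), threshold = 0.5) {
  stopifnot(k >= 2L)
  y <- as_binary_labels(labels)
  fold <- make_stratified_folds(y, k, seed)
  reports <- lapply(seq_len(k), function(i) {
    tr <- fold != i
    if (length(unique(y[!tr])) < 2L)
      stop("fold ", i, " has a single class; use a smaller k", call. = FALSE)
    b <- train_model(matrix[tr, , drop = FALSE], y[tr], algorithm,
                     features = features, hyperparameters = hyperparameters,
                     seed = seed + i, threshold = threshold)
    compute_metrics(y[!tr],
                    predict_scores(b, matrix[!tr, , drop = FALSE]),
                    threshold)
  })
  keys <- c("mcc", "roc_auc", "f1", "balanced_accuracy")
  vals <- vapply(reports, function(r) unlist(r[keys]), numeric(4))
  structure(list(folds = reports,
                 mean = rowMeans(vals),
                 sd = apply(vals, 1L, stats::sd),
                 fold_assignment = fold, k = k, algorithm = algorithm,
                 seed = as.integer(seed)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold, %s\n", x$k, x$algorithm))
  for (m in names(x$mean))
    cat(sprintf("  %-18s %.3f +/- %.3f\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' Leakage-free cross-validation over peptide records
#'
#' Record-level k-fold cross-validation in which every training-data-
#' fitted featurization component is refit inside each fold: the AAT
#' antigenicity-ratio scale is estimated from the fold's training records
#' only, and both partitions are featurized with that fold-local scale.
#' Feature groups that depend on no fitted state (signatures, CTD,
#' profiles, taxonomy) are computed once and reused across folds.
#' This is the CV to quote as generalization evidence; matrix-level
#' [cross_validate()] over AAT features would leak the validation fold's
#' triplet counts into its own features.
#'
#' @inheritParams cross_validate
#' @param records A labeled `peptide_records` data frame
#'   (epitope/non_epitope only).
#' @param sig_config A [signature_config()].
#' @param groups Feature groups (as in [featurize()]).
#' @param pseudocount AAT pseudocount.
#' @return A `cv_report`, as from [cross_validate()].
#' @export
cross_validate_records <- function(records, algorithm = "random_forest",
                                   k = 10L, seed = 1L,
                                   sig_config = signature_config(),
                                   groups = c("signatures", "aat", "ctd",
                                              "profiles", "taxonomy"),
                                   pseudocount = 1,
                                   hyperparameters = list(),
                                   threshold = 0.5) {
  stopifnot(k >= 2L)
  y <- as_binary_labels(records$label)
  static_groups <- setdiff(groups, "aat")
  m_static <- if (length(static_groups) > 0L)
    featurize(records, NULL, sig_config, groups = static_groups)
  else NULL
  fold <- make_stratified_folds(y, k, seed)
  reports <- lapply(seq_len(k), function(i) {
    tr <- fold != i
    m <- m_static
    if ("aat" %in% groups) {
      scale_i <- fit_aat_scale(
        records$sequence[tr & y == 1], records$sequence[tr & y == 0],
        pseudocount)
      aat <- t(vapply(records$sequence, aat_features,
                      c(AAT_max = 0, AAT_min = 0, AAT_sum = 0,
                        AAT_mean = 0),
                      scale = scale_i))
      rownames(aat) <- records$id
      m <- if (is.null(m)) aat else cbind(m, aat)
    }
    b <- train_model(m[tr, , drop = FALSE], y[tr], algorithm,
                     hyperparameters = hyperparameters, seed = seed + i,
                     threshold = threshold)
    compute_metrics(y[!tr], predict_scores(b, m[!tr, , drop = FALSE]),
                    threshold)
  })
  keys <- c("mcc", "roc_auc", "f1", "balanced_accuracy")
  vals <- vapply(reports, function(r) unlist(r[keys]), numeric(4))
  structure(list(folds = reports, mean = rowMeans(vals),
                 sd = apply(vals, 1L, stats::sd),
                 fold_assignment = fold, k = k, algorithm = algorithm,
                 seed = as.integer(seed)),
            class = "cv_report")
}

#' Greedy forward feature selection
#'
#' Starts from the empty set and repeatedly adds the feature whose
#' addition maximizes cross-validated MCC, stopping when no candidate
#' improves the score by more than `tolerance` for `patience` consecutive
#' rounds. The empty model scores 0 (the MCC of any constant predictor),
#' so constant features are never selected. Ties break by higher gain,
#' then column order — deterministic under `seed`.
#'
#' @inheritParams cross_validate
#' @param tolerance Minimum MCC gain counted as an improvement
#'   (default 1e-4).
#' @param patience Number of consecutive gainless rounds before stopping
#'   (default 1).
#' @param max_features Optional cap on the number of selected features.
#' @return Character vector of selected feature names, in selection order,
#'   with attribute `"scores"` (CV MCC after each addition).
#' @export
greedy_forward_select <- function(matrix, labels,
                                  algorithm = "random_forest", k = 5L,
                                  seed = 1L, tolerance = 1e-4,
                                  patience = 1L, max_features = Inf,
                                  hyperparameters = list()) {
  stopifnot(ncol(matrix) >= 2L)
  y <- as_binary_labels(labels)
  candidates <- colnames(matrix)
  selected <- character(0)
  scores <- numeric(0)
  current <- 0  # MCC of the trivial (featureless) predictor
  stalls <- 0L
  while (length(candidates) > 0L && length(selected) < max_features) {
    gains <- vapply(candidates, function(f) {
      if (stats::sd(matrix[, f]) == 0 && length(selected) == 0L)
        return(-Inf)  # constant feature alone: untrainable, no gain
      cv <- cross_validate(matrix, y, algorithm, k = k, seed = seed,
                           features = c(selected, f),
                           hyperparameters = hyperparameters)
      cv$mean[["mcc"]]
    }, numeric(1))
    best <- which.max(gains)  # first max = column-order tie-break
    if (gains[best] - current > tolerance) {
      selected <- c(selected, candidates[best])
      scores <- c(scores, gains[best])
      current <- gains[best]
      candidates <- candidates[-best]
      stalls <- 0L
    } else {
      stalls <- stalls + 1L
      if (stalls >= patience) break
      candidates <- candidates[-best]
    }
  }
  attr(selected, "scores") <- scores
  selected
}
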