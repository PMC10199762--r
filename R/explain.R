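#' Feature importance for a trained bundle
#'
#' Two methods are built in. `"gini"` reads the impurity-based importance
#' of tree ensembles (ranger impurity for forests, xgboost gain for
#' boosted models) and normalizes it to sum to 1, so values are directly
#' comparable shares of the model's decision. `"permutation"` measures,
#' for every column of the supplied matrix, the mean drop in MCC when
#' that column is shuffled (`n_shuffles` seeded shuffles) — a
#' model-agnostic, SHAP-style ranking; features the model never uses
#' score 0. `"shap"` is reserved for an exact SHAP backend and currently
#' raises an informative unavailability error.
#'
#' @param bundle A `model_bundle`.
#' @param matrix Feature matrix (required for `"permutation"`).
#' @param labels Labels matching `matrix` (required for `"permutation"`).
#' @param method `"gini"`, `"permutation"` or `"shap"`.
#' @param n_shuffles Shuffles per feature for the permutation method.
#' @param seed Seed for the shuffles.
#' @return A data frame of class `importance_report` with columns
#'   `feature`, `importance`, sorted by decreasing importance; attribute
#'   `"method"`, and for `"gini"` the normalization invariant
#'   `sum(importance) == 1`.
#' @export
feature_importance <- function(bundle, matrix = NULL, labels = NULL,
                               method = c("gini", "permutation", "shap"),
                               n_shuffles = 5L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(bundle, "model_bundle"))
  if (method == "shap")
    stop("SHAP importance is unavailable: no SHAP backend is installed; ",
         "use method = \"permutation\" for a model-agnostic ranking",
         call. = FALSE)
  if (method == "gini") {
    imp <- switch(
      bundle$algorithm,
      random_forest = ,
      extra_trees = bundle$model$variable.importance,
      gradient_boosting = ,
      additive_boosting = {
        tab <- xgboost::xgb.importance(model = bundle$model)
        v <- stats::setNames(rep(0, length(bundle$features)),
                             bundle$features)
        v[tab$Feature] <- tab$Gain
        v
      },
      stop("gini importance is only defined for tree-ensemble ",
           "algorithms, not ", sQuote(bundle$algorithm), call. = FALSE))
    imp <- pmax(imp, 0)
    if (sum(imp) > 0) imp <- imp / sum(imp)
  } else {
    if (is.null(matrix) || is.null(labels))
      stop("permutation importance needs a matrix and labels", call. = FALSE)
    y <- as_binary_labels(labels)
    base <- compute_metrics(y, predict_scores(bundle, matrix),
                            bundle$threshold)$mcc
    cols <- colnames(matrix)
    imp <- stats::setNames(numeric(length(cols)), cols)
    for (f in cols) {
      if (!f %in% bundle$features) next  # unused by the model: exactly 0
      drops <- vapply(seq_len(n_shuffles), function(s) {
        perm <- matrix
        perm[, f] <- with_seed(seed * 1000L + s + match(f, cols),
                               sample(perm[, f]))
        base - compute_metrics(y, predict_scores(bundle, perm),
                               bundle$threshold)$mcc
      }, numeric(1))
      imp[f] <- mean(drops)
    }
  }
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- method
  class(out) <- c("importance_report", "data.frame")
  out
}

#' Single-feature response curve (partial dependence)
#'
#' Clamp-and-average curve: for each grid value the feature is clamped to
#' that value across the whole matrix and the mean predicted epitope
#' probability is recorded. For additive models this recovers the
#' feature's shape function up to a constant; for forests it is the usual
#' partial-dependence summary.
#'
#' @param bundle A `model_bundle`.
#' @param matrix Background feature matrix.
#' @param feature Feature name (must be in the bundle's selected set).
#' @param grid Numeric grid of feature values; default: 25 equally spaced
#'   points over the feature's observed range.
#' @return A data frame with columns `value` and `mean_score`.
#' @export
response_curve <- function(bundle, matrix, feature, grid = NULL) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (!feature %in% bundle$features)
    stop("feature ", sQuote(feature), " is not in the model's selected set",
         call. = FALSE)
  if (is.null(grid)) {
    rng <- range(matrix[, feature])
    grid <- if (diff(rng) == 0) rng[1L] else
      seq(rng[1L], rng[2L], length.out = 25L)
  }
  mean_score <- vapply(grid, function(v) {
    clamped <- matrix
    clamped[, feature] <- v
    mean(predict_scores(bundle, clamped))
  }, numeric(1))
  data.frame(value = grid, mean_score = mean_score)
}
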