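#' Configuration of an end-to-end pipeline run
#'
#' Bundles every stage's parameters: where the labeled table comes from
#' (a file path, a `peptide_records` object passed to [run_pipeline()],
#' or the synthetic generator), curation settings, featurization
#' settings, and modeling settings. Fully serializable; a JSON copy is
#' written into the run's output directory.
#'
#' @param input_path Optional path to a labeled peptide table; `NULL`
#'   means records are supplied directly or simulated.
#' @param synthetic Optional [synthetic_spec()] used when no input is
#'   given.
#' @param curation A [curation_config()].
#' @param sig_config A [signature_config()].
#' @param feature_groups Feature groups passed to [featurize()].
#' @param algorithm Classifier id (see [train_model()]).
#' @param k Cross-validation folds.
#' @param select Run greedy forward feature selection before the final
#'   fit (default `FALSE`; selection is expensive at full feature width).
#' @param pseudocount AAT pseudocount.
#' @param seed Master seed for training.
#' @param threshold Decision threshold.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_path = NULL, synthetic = synthetic_spec(),
                       curation = curation_config(),
                       sig_config = signature_config(),
                       feature_groups = c("signatures", "aat", "ctd",
                                          "profiles", "taxonomy"),
                       algorithm = "random_forest", k = 5L,
                       select = FALSE, pseudocount = 1, seed = 1L,
                       threshold = 0.5) {
  structure(list(input_path = input_path, synthetic = synthetic,
                 curation = curation, sig_config = sig_config,
                 feature_groups = feature_groups, algorithm = algorithm,
                 k = as.integer(k), select = isTRUE(select),
                 pseudocount = pseudocount, seed = as.integer(seed),
                 threshold = threshold),
            class = "run_config")
}

#' @keywords internal
#' @noRd
metrics_to_list <- function(r) {
  lapply(unclass(r), function(v) if (is.numeric(v)) round(v, 10) else v)
}

#' Run the full pipeline: curate, featurize, train, evaluate, explain
#'
#' Stages: (1) load or simulate the labeled table; (2) curate it into
#' train and test sets; (3) fit the AAT scale on the training split only
#' and featurize both splits with it; (4) optionally run greedy forward
#' feature selection; (5) cross-validate and train the classifier on the
#' training matrix; (6) evaluate on the blind test matrix; (7) write
#' Gini importances. All artifacts land in `out_dir`: `config.json`,
#' `curation_report.json`, `features/{train,test}.csv`,
#' `model/bundle.rds`, `reports/cv_metrics.json`,
#' `reports/test_metrics.json`, `reports/importance.csv`. Deterministic
#' given the config's seeds: reruns produce byte-identical reports.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param records Optional `peptide_records` overriding file/synthetic
#'   input.
#' @return Invisibly, a list with `bundle`, `cv`, `test_metrics`,
#'   `report`, `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir, records = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "features"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "model"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "reports"), showWarnings = FALSE)

  if (is.null(records)) {
    records <- if (!is.null(config$input_path))
      read_peptide_table(config$input_path)
    else generate_synthetic(config$synthetic)
  }
  jsonlite::write_json(
    rapply(unclass(config), unclass, how = "replace"),
    file.path(out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)

  cur <- curate(records, config$curation)
  jsonlite::write_json(unclass(cur$report)[c("counts_per_step",
                                             "removed_dual_class",
                                             "clusters_formed", "engine")],
                       file.path(out_dir, "curation_report.json"),
                       auto_unbox = TRUE, digits = NA)
  train_rec <- cur$train; test_rec <- cur$test
  if (nrow(train_rec) == 0L || nrow(test_rec) == 0L)
    stop("curation left an empty train or test split", call. = FALSE)

  scale <- fit_aat_scale(
    train_rec$sequence[train_rec$label == "epitope"],
    train_rec$sequence[train_rec$label == "non_epitope"],
    config$pseudocount)
  m_train <- featurize(train_rec, scale, config$sig_config,
                       groups = config$feature_groups)
  m_test <- featurize(test_rec, scale, config$sig_config,
                      groups = config$feature_groups)
  write_feature_matrix(m_train, file.path(out_dir, "features", "train.csv"))
  write_feature_matrix(m_test, file.path(out_dir, "features", "test.csv"))

  feats <- colnames(m_train)
  if (config$select)
    feats <- greedy_forward_select(m_train, train_rec$label,
                                   config$algorithm, k = config$k,
                                   seed = config$seed)
  cv <- if (config$select)
    cross_validate(m_train, train_rec$label, config$algorithm,
                   k = config$k, seed = config$seed, features = feats,
                   threshold = config$threshold)
  else
    cross_validate_records(train_rec, config$algorithm, k = config$k,
                           seed = config$seed,
                           sig_config = config$sig_config,
                           groups = config$feature_groups,
                           pseudocount = config$pseudocount,
                           threshold = config$threshold)
  bundle <- train_model(m_train, train_rec$label, config$algorithm,
                        features = feats, seed = config$seed,
                        threshold = config$threshold)
  save_bundle(bundle, file.path(out_dir, "model", "bundle.rds"))

  test_metrics <- compute_metrics(test_rec$label,
                                  predict_scores(bundle, m_test),
                                  config$threshold)
  jsonlite::write_json(list(mean = as.list(round(cv$mean, 10)),
                            sd = as.list(round(cv$sd, 10)), k = cv$k,
                            algorithm = cv$algorithm),
                       file.path(out_dir, "reports", "cv_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(metrics_to_list(test_metrics),
                       file.path(out_dir, "reports", "test_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  imp <- tryCatch(feature_importance(bundle, method = "gini"),
                  error = function(e) NULL)
  if (!is.null(imp))
    utils::write.csv(imp, file.path(out_dir, "reports", "importance.csv"),
                     row.names = FALSE)
  invisible(list(bundle = bundle, cv = cv, test_metrics = test_metrics,
                 report = cur$report, out_dir = out_dir))
}
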