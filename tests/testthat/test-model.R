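test_that("metrics reproduce worked confusion-matrix examples", {
  y <- c(rep(1, 5), rep(0, 5))
  perfect <- compute_metrics(y, c(rep(1, 5), rep(0, 5)))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$roc_auc, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$balanced_accuracy, 1)

  # TP=4 FP=1 TN=4 FN=1 -> MCC = 15/25 = 0.6
  r <- compute_metrics(y, c(1, 1, 1, 1, 0.4, 0.6, 0, 0, 0, 0))
  expect_equal(r$mcc, 0.6)
  expect_equal(c(r$tp, r$fp, r$tn, r$fn), c(4L, 1L, 4L, 1L))

  tied <- compute_metrics(y, rep(0.5, 10))
  expect_equal(tied$roc_auc, 0.5)

  single <- compute_metrics(rep(1, 4), c(0.9, 0.8, 0.2, 0.7))
  expect_true(is.na(single$roc_auc))
})

test_that("MCC equals the phi-coefficient oracle on all confusion matrices with n <= 8", {
  for (n in 2:8) {
    combos <- expand.grid(tp = 0:n, fp = 0:n, tn = 0:n, fn = 0:n)
    combos <- combos[rowSums(combos) == n, ]
    for (i in seq_len(nrow(combos))) {
      cc <- combos[i, ]
      y <- c(rep(1, cc$tp), rep(0, cc$fp), rep(0, cc$tn), rep(1, cc$fn))
      pred <- c(rep(1, cc$tp), rep(1, cc$fp), rep(0, cc$tn), rep(0, cc$fn))
      got <- compute_metrics(y, pred, threshold = 0.5)$mcc
      want <- brute_mcc(y, pred)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("rank AUC equals the exhaustive pair-counting oracle with ties", {
  set.seed(33)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    scores <- round(runif(n), sample(c(1, 2, 8), 1))  # force ties sometimes
    expect_equal(compute_metrics(y, scores)$roc_auc, brute_auc(y, scores),
                 tolerance = 1e-12)
  }
})

test_that("a majority-class predictor scores MCC 0 and balanced accuracy 0.5 on 1:6 data", {
  y <- rep(c(1, 0), c(100, 600))
  r <- compute_metrics(y, rep(0, 700))
  expect_identical(r$mcc, 0)
  expect_equal(r$balanced_accuracy, 0.5)
})

test_that("training and prediction are reproducible and guard their features", {
  toy <- toy_selection_matrix(n = 80, n_noise = 4)
  for (alg in c("random_forest", "extra_trees", "gradient_boosting",
                "additive_boosting", "svm")) {
    b <- train_model(toy$matrix, toy$labels, alg,
                     hyperparameters = list(num.trees = 100, nrounds = 30),
                     seed = 3)
    s <- predict_scores(b, toy$matrix)
    expect_true(all(s >= 0 & s <= 1))
    expect_identical(predict_scores(b, toy$matrix), s)
    m <- compute_metrics(toy$labels, s)
    expect_equal(m$mcc, 1, tolerance = 1e-8)
    b2 <- train_model(toy$matrix, toy$labels, alg,
                      hyperparameters = list(num.trees = 100, nrounds = 30),
                      seed = 3)
    expect_equal(predict_scores(b2, toy$matrix), s, tolerance = 1e-12)
  }
  expect_error(train_model(toy$matrix, toy$labels, "nosuch"), "unknown algorithm")
  b <- train_model(toy$matrix, toy$labels, "random_forest",
                   hyperparameters = list(num.trees = 50))
  expect_error(predict_scores(b, toy$matrix[, -1, drop = FALSE]), "signal")
})

test_that("cross-validation is stratified, seeded and errors on degenerate folds", {
  toy <- toy_selection_matrix(n = 60, n_noise = 2)
  cv1 <- cross_validate(toy$matrix, toy$labels, "random_forest", k = 5,
                        seed = 2, hyperparameters = list(num.trees = 50))
  cv2 <- cross_validate(toy$matrix, toy$labels, "random_forest", k = 5,
                        seed = 2, hyperparameters = list(num.trees = 50))
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_equal(cv1$mean, cv2$mean, tolerance = 1e-12)
  expect_equal(cv1$mean[["mcc"]], 1, tolerance = 0.05)  # separable toy
  for (i in 1:5) {
    tab <- table(toy$labels, cv1$fold_assignment)
    expect_true(all(tab > 0))
  }
  y_rare <- c(1, rep(0, 59))
  expect_error(cross_validate(toy$matrix, y_rare, k = 5), "smaller k")
})

test_that("shuffled labels yield null cross-validated MCC", {
  set.seed(17)
  n <- 300
  m <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  y <- sample(rep(c(1, 0), c(50, 250)))
  cv <- cross_validate(m, y, "random_forest", k = 5, seed = 1,
                       hyperparameters = list(num.trees = 100))
  expect_lt(abs(cv$mean[["mcc"]]), 0.15)
})

test_that("duplicated noise cannot leak into CV metrics", {
  set.seed(19)
  n <- 200
  noise <- rnorm(n)
  m <- cbind(noise1 = noise, noise2 = noise, noise3 = rnorm(n))
  rownames(m) <- sprintf("r%03d", 1:n)
  y <- rep(c(1, 0), c(40, 160))
  cv <- cross_validate(m, y, "random_forest", k = 5, seed = 4,
                       hyperparameters = list(num.trees = 100))
  expect_lt(abs(cv$mean[["mcc"]]), 0.2)
})

test_that("greedy forward selection finds the planted predictor and stops", {
  toy <- toy_selection_matrix(n = 60, n_noise = 8, seed = 13)
  sel <- greedy_forward_select(toy$matrix, toy$labels, k = 3, seed = 5,
                               hyperparameters = list(num.trees = 50))
  expect_equal(sel[1], "signal")
  expect_lte(length(sel), 3L)
  sel2 <- greedy_forward_select(toy$matrix, toy$labels, k = 3, seed = 5,
                                hyperparameters = list(num.trees = 50))
  expect_identical(sel, sel2)
})

test_that("all-constant features yield an empty selection; duplicates picked once", {
  m <- matrix(1, nrow = 30, ncol = 3,
              dimnames = list(NULL, c("c1", "c2", "c3")))
  y <- rep(c(1, 0), 15)
  expect_length(greedy_forward_select(m, y, k = 3, seed = 1), 0L)

  toy <- toy_selection_matrix(n = 40, n_noise = 1, seed = 2)
  dup <- cbind(toy$matrix, signal_copy = toy$matrix[, "signal"])
  sel <- greedy_forward_select(dup, toy$labels, k = 3, seed = 2,
                               hyperparameters = list(num.trees = 50))
  expect_equal(sum(sel %in% c("signal", "signal_copy")), 1L)
  expect_equal(sel[1], "signal")  # column-order tie-break
})
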