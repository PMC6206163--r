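make_matrix_ds <- function(x, labels) {
  enhancerwalk:::new_labeled_dataset(
    x, paste0("s", seq_len(nrow(x))), labels)
}

test_that("fit_pca honors the variance target on the covariance eigenstructure", {
  # data exactly on a line in 3-D: one component explains everything
  set.seed(81)
  t <- rnorm(40)
  X <- cbind(a = t, b = 2 * t, c = -t)
  p <- fit_pca(X)
  expect_equal(p$n_kept, 1)
  expect_equal(p$explained_variance_ratios[1], 1.0, tolerance = 1e-12)

  # explained ratios equal eigenvalues/trace from an independent eigensolve
  X2 <- matrix(rnorm(500), nrow = 50, ncol = 10)
  p2 <- fit_pca(X2)
  ev <- eigen(cov(X2), symmetric = TRUE)$values
  expect_equal(p2$explained_variance_ratios, ev / sum(ev),
               tolerance = 1e-10)

  # minimal count reaching 95%
  cum <- cumsum(p2$explained_variance_ratios)
  expect_gte(cum[p2$n_kept], 0.95)
  if (p2$n_kept > 1) expect_lt(cum[p2$n_kept - 1], 0.95)

  expect_error(fit_pca(matrix(1, nrow = 5, ncol = 3)), "degenerate")
})

test_that("PCA reconstruction error is bounded by the discarded variance", {
  set.seed(82)
  X <- matrix(rnorm(600), nrow = 60) %*% diag(c(5, 3, 2, 1, 0.5, 0.2,
                                                0.1, 0.05, 0.02, 0.01))
  p <- fit_pca(X, variance_target = 0.95)
  Z <- predict(p, X)
  Xhat <- Z %*% t(p$rotation)
  Xc <- sweep(X, 2, p$center, "-")
  err_ratio <- sum((Xc - Xhat)^2) / sum(Xc^2)
  expect_lte(err_ratio, 1 - 0.95 + 1e-9)
})

test_that("bagged trees overfit separable data and are seed-deterministic", {
  set.seed(83)
  n <- 60
  X <- cbind(f1 = c(rnorm(n / 2, 3), rnorm(n / 2, -3)),
             f2 = rnorm(n))
  labels <- rep(c("positive", "negative"), each = n / 2)
  ds <- make_matrix_ds(X, labels)
  m <- train_bagged(ds, seed = 1)
  expect_length(m$learners, 30)
  p <- predict_proba(m, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(mean((p >= 0.5) == (labels == "positive")), 1.0)

  m2 <- train_bagged(ds, seed = 1)
  expect_identical(predict_proba(m2, X), p)
  m3 <- train_bagged(ds, seed = 2)
  expect_false(identical(m3$learners, m$learners))

  ds1 <- make_matrix_ds(X, rep("positive", n))
  expect_error(train_bagged(ds1, seed = 1), "both classes")
})

test_that("bagged probability equals the brute-force per-tree vote tally", {
  set.seed(84)
  X <- matrix(rnorm(200), ncol = 2,
              dimnames = list(NULL, c("f1", "f2")))
  labels <- ifelse(X[, 1] + rnorm(100, sd = 0.5) > 0, "positive",
                   "negative")
  ds <- make_matrix_ds(X, labels)
  m <- train_bagged(ds, seed = 3)
  p <- predict_proba(m, X)
  scores <- predict(m$pca, X)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  votes <- sapply(m$learners, function(tr) {
    as.character(predict(tr, as.data.frame(scores), type = "class"))
  })
  tally <- rowMeans(votes == "positive")
  expect_equal(p, tally, tolerance = 1e-12)
  # majority-vote label flips exactly at the threshold
  lab <- predict(m, X, type = "label")
  expect_identical(lab, ifelse(tally >= 0.5, "positive", "negative"))
})

test_that("predict_proba rejects schema mismatches by name", {
  set.seed(85)
  X <- matrix(rnorm(100), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
  ds <- make_matrix_ds(X, rep(c("positive", "negative"), 25))
  m <- train_bagged(ds, seed = 4)
  bad <- X
  colnames(bad) <- c("f1", "oops")
  expect_error(predict_proba(m, bad), "f2")
})

test_that("RUSBoost balances classes per round and boosts minority recall", {
  set.seed(86)
  n_min <- 12; n_maj <- 600
  X <- cbind(f1 = c(rnorm(n_min, 1.2), rnorm(n_maj, -1.2)),
             f2 = c(rnorm(n_min), rnorm(n_maj)))
  labels <- c(rep("positive", n_min), rep("negative", n_maj))
  ds <- make_matrix_ds(X, labels)
  m <- train_rusboost(ds, seed = 5)
  expect_equal(m$kind, "rusboost")
  expect_true(all(m$rounds$n_minority == n_min))
  expect_true(all(m$rounds$n_majority_sampled == n_min))
  expect_equal(length(m$learners), nrow(m$rounds))
  expect_length(m$learner_weights, length(m$learners))

  m2 <- train_rusboost(ds, seed = 5)
  expect_identical(predict_proba(m2, X), predict_proba(m, X))

  # minority recall vs a single unweighted tree on the raw imbalance
  p <- predict_proba(m, X)
  recall_boost <- mean(p[labels == "positive"] >= 0.5)
  scores <- predict(m$pca, X)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  df <- as.data.frame(scores)
  df$.y <- factor(labels, levels = c("negative", "positive"))
  single <- rpart::rpart(.y ~ ., df, method = "class")
  pred_single <- predict(single, df, type = "class")
  recall_single <- mean(pred_single[labels == "positive"] == "positive")
  expect_gte(recall_boost, recall_single)
})

test_that("ROC/AUC: anchors, Mann-Whitney equivalence, pROC cross-check", {
  # perfectly ranked
  ev <- evaluate_scores(c(0.9, 0.8, 0.2, 0.1),
                        c("positive", "positive", "negative", "negative"))
  expect_equal(ev$auc, 1.0)
  # uninformative
  ev2 <- evaluate_scores(rep(0.5, 10), rep(c("positive", "negative"), 5))
  expect_equal(ev2$auc, 0.5)

  set.seed(87)
  scores <- round(runif(200), 2)  # rounded to force ties
  labels <- sample(c("positive", "negative"), 200, replace = TRUE)
  ev3 <- evaluate_scores(scores, labels)
  expect_equal(ev3$auc, mann_whitney_auc(scores, labels),
               tolerance = 1e-12)
  # ROC path is monotone from (0,0) to (1,1)
  rp <- ev3$roc_points
  expect_equal(rp$fpr[1], 0); expect_equal(rp$tpr[1], 0)
  expect_equal(rp$fpr[nrow(rp)], 1); expect_equal(rp$tpr[nrow(rp)], 1)
  expect_true(all(diff(rp$fpr) >= 0) && all(diff(rp$tpr) >= 0))

  skip_if_not_installed("pROC")
  proc_auc <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c("negative", "positive"), direction = "<", quiet = TRUE)))
  expect_equal(ev3$auc, proc_auc, tolerance = 1e-12)

  expect_error(evaluate_scores(1:4 / 4, rep("positive", 4)), "one class")
})

test_that("pipeline on an easy synthetic setting reaches high held-out AUC", {
  # scaled-down version of the full study condition (shorter sequences,
  # fewer samples) for fast routine checking
  recs <- simulate_labeled_set(40, 160, length = 500, seed = 88)
  ds <- build_dataset(recs)
  sp <- split_dataset(ds, 0.25, seed = 88)
  m <- train_bagged(sp$train, seed = 88)
  ev <- evaluate_scores(predict_proba(m, sp$test), sp$test$labels)
  expect_gt(ev$auc, 0.9)
})

test_that("model save/load round-trip predicts bit-identically", {
  set.seed(89)
  X <- matrix(rnorm(300), ncol = 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  labels <- ifelse(X[, 1] > 0, "positive", "negative")
  ds <- make_matrix_ds(X, labels)
  m <- train_bagged(ds, seed = 6)
  p_before <- predict_proba(m, X)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m_back <- load_model(path)
  expect_identical(predict_proba(m_back, X), p_before)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$kind, "bagged")
  expect_equal(meta$n_learners, 30)
  expect_equal(meta$pca_n_kept, m$pca$n_kept)

  bad <- tempfile(fileext = ".rds")
  writeLines("not a model", bad)
  expect_error(load_model(bad), "corrupted|not an enhancerwalk")
  expect_error(load_model(tempfile()), "not found")
})

test_that("cross-validation refits per fold and reports sane metrics", {
  set.seed(90)
  X <- cbind(f1 = c(rnorm(30, 2), rnorm(60, -2)), f2 = rnorm(90))
  labels <- c(rep("positive", 30), rep("negative", 60))
  ds <- make_matrix_ds(X, labels)
  cv <- cross_validate(ds, k = 3, kind = "bagged", seed = 7)
  expect_equal(nrow(cv), 3)
  expect_true(all(cv$auc >= 0 & cv$auc <= 1))
  expect_gt(mean(cv$auc), 0.9)
})
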