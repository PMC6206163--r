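# PCA + tree-ensemble classifiers: bagged decision trees and RUSBoost,
# with ROC/AUC evaluation and model persistence.

#' Fit a PCA transform keeping a variance target
#'
#' Principal components of the centered (by default unstandardized)
#' feature matrix; keeps the minimal number of leading components whose
#' cumulative explained-variance ratio reaches `variance_target`.
#'
#' @param X Numeric feature matrix (samples x features), no missing
#'   values, >= 2 rows.
#' @param variance_target Cumulative explained-variance target (default
#'   0.95).
#' @param standardize Scale features to unit variance before PCA (default
#'   `FALSE`; count-scale features are left on their natural scale).
#' @return Object of class `pca_transform`: list with `center`, `scale`,
#'   `rotation` (kept components), `explained_variance_ratios` (all
#'   components), `n_kept`, `variance_target`.
#' @export
fit_pca <- function(X, variance_target = 0.95, standardize = FALSE) {
  stopifnot(is.matrix(X), nrow(X) >= 2L, !anyNA(X))
  total_var <- sum(apply(X, 2, var))
  if (total_var == 0) stop("degenerate input: all rows identical")
  pr <- prcomp(X, center = TRUE, scale. = standardize)
  ratios <- pr$sdev^2 / sum(pr$sdev^2)
  cum <- cumsum(ratios)
  n_kept <- which(cum >= variance_target - 1e-12)[1]
  if (is.na(n_kept)) n_kept <- length(ratios)
  structure(list(center = pr$center,
                 scale = if (standardize) pr$scale else NULL,
                 rotation = pr$rotation[, seq_len(n_kept), drop = FALSE],
                 explained_variance_ratios = ratios,
                 n_kept = n_kept,
                 variance_target = variance_target),
            class = "pca_transform")
}

#' @export
print.pca_transform <- function(x, ...) {
  cat(sprintf("<pca_transform> %d component(s) kept (%.1f%% variance)\n",
              x$n_kept,
              100 * sum(x$explained_variance_ratios[seq_len(x$n_kept)])))
  invisible(x)
}

#' Project a feature matrix onto a fitted PCA basis
#'
#' @param object A [fit_pca()] result.
#' @param newdata Numeric matrix with the same columns as the training
#'   matrix.
#' @param ... Unused.
#' @return Score matrix (samples x kept components).
#' @export
predict.pca_transform <- function(object, newdata, ...) {
  Z <- sweep(newdata, 2, object$center, "-")
  if (!is.null(object$scale)) Z <- sweep(Z, 2, object$scale, "/")
  Z %*% object$rotation
}

check_two_classes <- function(labels) {
  tab <- table(labels)
  if (!all(c("positive", "negative") %in% names(tab))) {
    stop("training data must contain both classes")
  }
  tab
}

new_model <- function(kind, pca, learners, feature_names, seed,
                      learner_weights = NULL, learning_rate = NULL,
                      rounds = NULL) {
  structure(list(kind = kind, pca = pca, learners = learners,
                 learner_weights = learner_weights,
                 learning_rate = learning_rate, seed = seed,
                 feature_names = feature_names, threshold = 0.5,
                 rounds = rounds,
                 package_version = as.character(packageVersion("enhancerwalk"))),
            class = "enhancer_model")
}

#' @export
print.enhancer_model <- function(x, ...) {
  cat(sprintf("<enhancer_model> %s: %d tree(s) on %d principal component(s)\n",
              x$kind, length(x$learners), x$pca$n_kept))
  invisible(x)
}

full_tree_control <- rpart::rpart.control(cp = 0, minsplit = 2L,
                                          minbucket = 1L, xval = 0L,
                                          maxsurrogate = 0L,
                                          usesurrogate = 0L)

fit_tree <- function(scores, y, weights = NULL) {
  df <- as.data.frame(scores)
  df$.y <- factor(y, levels = c("negative", "positive"))
  rpart::rpart(.y ~ ., data = df, method = "class", weights = weights,
               control = full_tree_control)
}

tree_votes <- function(tree, scores) {
  as.character(predict(tree, as.data.frame(scores), type = "class"))
}

#' Train a bagged decision-tree ensemble
#'
#' PCA (fit on the training partition only) followed by `n_learners`
#' full-depth classification trees, each grown on a bootstrap resample of
#' size n drawn with replacement. The positive-class score of a sample is
#' the fraction of trees voting positive.
#'
#' @param train A `labeled_dataset` containing both classes.
#' @param n_learners Number of trees (default 30).
#' @param seed Optional integer seed; same seed gives an identical model.
#' @param variance_target PCA explained-variance target (default 0.95).
#' @param standardize Standardize features before PCA (default `FALSE`).
#' @return An `enhancer_model` of kind `"bagged"`.
#' @export
train_bagged <- function(train, n_learners = 30L, seed = NULL,
                         variance_target = 0.95, standardize = FALSE) {
  stopifnot(inherits(train, "labeled_dataset"))
  check_two_classes(train$labels)
  if (!is.null(seed)) set.seed(seed)
  pca <- fit_pca(train$x, variance_target, standardize)
  scores <- predict(pca, train$x)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  n <- nrow(scores)
  learners <- lapply(seq_len(n_learners), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    fit_tree(scores[idx, , drop = FALSE], train$labels[idx])
  })
  new_model("bagged", pca, learners, train$feature_names,
            seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Train a RUSBoost ensemble
#'
#' Boosting with per-round random undersampling: each round keeps every
#' minority-class sample and a uniform random subset of the majority
#' class of equal size (exact 1:1 balance), fits a full-depth tree under
#' the current AdaBoost.M1 weights, and updates weights on the full
#' training set. Learner weights are scaled by `learning_rate`. Boosting
#' halts early if a round's weighted error reaches 0.5; prediction is the
#' weighted vote of the completed rounds.
#'
#' @param train A `labeled_dataset` containing both classes.
#' @param n_learners Maximum boosting rounds (default 30).
#' @param learning_rate Multiplier on the learner weights (default 0.1).
#' @param seed Optional integer seed.
#' @param variance_target,standardize PCA options as in [train_bagged()].
#' @return An `enhancer_model` of kind `"rusboost"`; `$rounds` records the
#'   per-round class counts and weighted errors.
#' @export
train_rusboost <- function(train, n_learners = 30L, learning_rate = 0.1,
                           seed = NULL, variance_target = 0.95,
                           standardize = FALSE) {
  stopifnot(inherits(train, "labeled_dataset"))
  tab <- check_two_classes(train$labels)
  if (!is.null(seed)) set.seed(seed)
  pca <- fit_pca(train$x, variance_target, standardize)
  scores <- predict(pca, train$x)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  n <- nrow(scores)
  minority <- names(tab)[which.min(tab)]
  min_idx <- which(train$labels == minority)
  maj_idx <- which(train$labels != minority)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  rounds <- list()
  for (b in seq_len(n_learners)) {
    sel <- c(min_idx, sample(maj_idx, length(min_idx)))
    tree <- fit_tree(scores[sel, , drop = FALSE], train$labels[sel],
                     weights = w[sel] / sum(w[sel]))
    pred <- tree_votes(tree, scores)
    miss <- pred != train$labels
    err <- sum(w[miss])
    if (err >= 0.5) break  # remaining rounds unused
    err_c <- max(err, 1e-10)
    alpha <- learning_rate * log((1 - err_c) / err_c)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
    learners[[b]] <- tree
    alphas[b] <- alpha
    rounds[[b]] <- data.frame(round = b,
                              n_minority = length(min_idx),
                              n_majority_sampled = length(sel) - length(min_idx),
                              weighted_error = err)
  }
  if (length(learners) == 0L) {
    stop("boosting failed: first round's weighted error >= 0.5")
  }
  new_model("rusboost", pca, learners, train$feature_names,
            seed = if (is.null(seed)) NA_integer_ else seed,
            learner_weights = alphas, learning_rate = learning_rate,
            rounds = do.call(rbind, rounds))
}

#' Positive-class score of samples under a trained model
#'
#' Projects the feature matrix onto the model's PCA basis and aggregates
#' the base trees: vote fraction for bagging, normalized weighted vote for
#' RUSBoost. Scores lie in \[0, 1\]; the hard label is positive when the
#' score reaches the threshold (default 0.5).
#'
#' @param model An `enhancer_model`.
#' @param X Numeric matrix whose columns match the model's feature
#'   registry (a `labeled_dataset` is also accepted).
#' @return Numeric vector of positive-class scores.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "enhancer_model"))
  if (inherits(X, "labeled_dataset")) X <- X$x
  if (is.null(colnames(X)) ||
      !identical(colnames(X), model$feature_names)) {
    missing <- setdiff(model$feature_names, colnames(X))
    stop("feature schema mismatch",
         if (length(missing)) paste0("; missing: ",
                                     paste(head(missing, 5),
                                           collapse = ", ")) else
           "; column order differs from the model registry")
  }
  scores <- predict(model$pca, X)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  votes <- vapply(model$learners,
                  function(tr) tree_votes(tr, scores) == "positive",
                  logical(nrow(scores)))
  votes <- matrix(votes, nrow = nrow(scores))
  if (model$kind == "bagged") {
    rowMeans(votes)
  } else {
    as.vector(votes %*% model$learner_weights) / sum(model$learner_weights)
  }
}

#' @export
predict.enhancer_model <- function(object, newdata,
                                   type = c("prob", "label"),
                                   threshold = NULL, ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") return(p)
  if (is.null(threshold)) threshold <- object$threshold
  ifelse(p >= threshold, "positive", "negative")
}

#' ROC curve, AUC and accuracy of scores against labels
#'
#' The ROC is traced by sweeping every distinct score as a threshold
#' (descending), starting at (0, 0) and ending at (1, 1); the AUC is the
#' trapezoidal area under it (equal to the Mann-Whitney concordance
#' probability, ties counted one half). Accuracy is computed at
#' `threshold`.
#'
#' @param scores Numeric scores (higher = more enhancer-like).
#' @param labels Labels: `"positive"`/`"negative"` (or logical/0-1).
#' @param threshold Hard-call threshold for accuracy (default 0.5).
#' @return Object of class `evaluation_report`: list with `auc`,
#'   `accuracy`, `roc_points` (data frame fpr/tpr), `threshold`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  y <- normalize_labels(labels)
  if (length(unique(y)) < 2L) stop("AUC undefined: only one class present")
  P <- sum(y == 1)
  N <- sum(y == 0)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  # cumulative counts at each distinct threshold
  keep <- c(diff(ss) != 0, TRUE)
  tpr <- c(0, cumsum(ys == 1)[keep] / P)
  fpr <- c(0, cumsum(ys == 0)[keep] / N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  acc <- mean((scores >= threshold) == (y == 1))
  structure(list(auc = auc, accuracy = acc,
                 roc_points = data.frame(fpr = fpr, tpr = tpr),
                 threshold = threshold),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> AUC = %.4f, accuracy = %.1f%% at %.2f\n",
              x$auc, 100 * x$accuracy, x$threshold))
  invisible(x)
}

normalize_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  stopifnot(all(labels %in% c("positive", "negative")))
  as.integer(labels == "positive")
}

#' k-fold cross-validated evaluation
#'
#' Optional evaluation mode: stratified k folds; PCA and ensemble are
#' refit inside each training fold and scored on the held-out fold.
#'
#' @param ds A `labeled_dataset`.
#' @param k Number of folds (default 10).
#' @param kind `"bagged"` or `"rusboost"`.
#' @param seed Optional integer seed.
#' @param ... Passed to the trainer.
#' @return Data frame with one row per fold: `fold`, `auc`, `accuracy`.
#' @export
cross_validate <- function(ds, k = 10L, kind = c("bagged", "rusboost"),
                           seed = NULL, ...) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  fold_of <- integer(nrow(ds$x))
  for (cl in unique(ds$labels)) {
    idx <- sample(which(ds$labels == cl))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  trainer <- if (kind == "bagged") train_bagged else train_rusboost
  rows <- lapply(seq_len(k), function(f) {
    tr_idx <- which(fold_of != f)
    te_idx <- which(fold_of == f)
    tr <- new_labeled_dataset(ds$x[tr_idx, , drop = FALSE],
                              ds$ids[tr_idx], ds$labels[tr_idx])
    m <- trainer(tr, ...)
    p <- predict_proba(m, ds$x[te_idx, , drop = FALSE])
    ev <- evaluate_scores(p, ds$labels[te_idx])
    data.frame(fold = f, auc = ev$auc, accuracy = ev$accuracy)
  })
  do.call(rbind, rows)
}

#' Save a trained model with a JSON sidecar
#'
#' Serializes the model to `path` and writes `<path>.json` describing it
#' (kind, learner count, seed, PCA components kept, feature-registry
#' hash, package version).
#'
#' @param model An `enhancer_model`.
#' @param path Output path (e.g. `model.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "enhancer_model"))
  saveRDS(model, path)
  meta <- list(kind = model$kind,
               n_learners = length(model$learners),
               seed = model$seed,
               pca_n_kept = model$pca$n_kept,
               n_features = length(model$feature_names),
               feature_name_hash = rlang::hash(model$feature_names),
               package_version = model$package_version)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Path given to [save_model()].
#' @return The `enhancer_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  model <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupted or unreadable model file: ", path)
  })
  if (!inherits(model, "enhancer_model")) {
    stop("file is not an enhancerwalk model archive: ", path)
  }
  model
}
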