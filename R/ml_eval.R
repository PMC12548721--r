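# Cross-validation harness: macro-averaged classification metrics with
# one-vs-rest AUROC / AUPRC, R-squared regression, stratified folds, and the
# scrambled-label negative control.

# Mann-Whitney AUROC for one positive class, ties handled via average ranks
.binary_auroc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# step-wise average precision (no interpolation): sum over threshold steps of
# (recall increment) x (precision at that threshold)
.average_precision <- function(scores, positive) {
  n1 <- sum(positive)
  if (n1 == 0 || all(positive)) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- positive[o]
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- c(s[-1] != s[-length(s)], TRUE)   # evaluate at distinct thresholds
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Macro-averaged classification metrics
#'
#' One-vs-rest AUROC and AUPRC (step-wise average precision) averaged over
#' classes, plus accuracy and unweighted macro precision, recall and F1.
#' Classes absent from the true labels are excluded from the macro averages
#' with a message.
#'
#' @param true_labels True class labels (factor or character).
#' @param predicted_labels Predicted class labels.
#' @param class_scores Numeric score matrix, one column per class, column
#'   names matching the class labels (required for the AUC metrics; may be
#'   `NULL` to skip them).
#' @return Named numeric vector: `roc_auc`, `prc_auc`, `accuracy`,
#'   `precision`, `recall`, `f1` (AUCs `NA` when scores are omitted).
#' @export
macro_classification_metrics <- function(true_labels, predicted_labels,
                                         class_scores = NULL) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  stopifnot(length(true_labels) == length(predicted_labels))
  classes <- sort(unique(true_labels))
  if (length(classes) < 2L) stop("need at least 2 classes in true labels", call. = FALSE)
  if (!is.null(class_scores)) {
    class_scores <- as.matrix(class_scores)
    stopifnot(nrow(class_scores) == length(true_labels),
              !is.null(colnames(class_scores)))
    extra <- setdiff(colnames(class_scores), classes)
    if (length(extra) > 0) {
      message("class(es) absent from true labels excluded from macro average: ",
              paste(extra, collapse = ", "))
    }
  }
  prec <- rec <- f1 <- roc <- prc <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(true_labels == cl & predicted_labels == cl)
    fp <- sum(true_labels != cl & predicted_labels == cl)
    fn <- sum(true_labels == cl & predicted_labels != cl)
    prec[i] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[i] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[i] <- if (prec[i] + rec[i] == 0) 0 else 2 * prec[i] * rec[i] / (prec[i] + rec[i])
    if (!is.null(class_scores)) {
      pos <- true_labels == cl
      roc[i] <- .binary_auroc(class_scores[, cl], pos)
      prc[i] <- .average_precision(class_scores[, cl], pos)
    } else {
      roc[i] <- NA_real_; prc[i] <- NA_real_
    }
  }
  c(roc_auc = mean(roc), prc_auc = mean(prc),
    accuracy = mean(true_labels == predicted_labels),
    precision = mean(prec), recall = mean(rec), f1 = mean(f1))
}

#' Evaluation configuration
#'
#' Bundles the harness parameters. Defaults reproduce the benchmark setup:
#' hidden layers 512/256/128/64/32, 5-fold cross-validation for
#' classification, 3-fold for regression, no feature scaling, no tuning.
#'
#' @param hidden_layers MLP hidden-layer widths.
#' @param n_folds_classification,n_folds_regression Fold counts.
#' @param seed Master seed; all randomness in a run flows from it.
#' @param scrambled If `TRUE`, labels are permuted once globally (dataset
#'   level, before folding) as a negative control.
#' @param standardize If `TRUE`, features are standardized using training-fold
#'   statistics (off by default).
#' @param max_iter,batch_size,learning_rate,alpha Passed to [mlp_fit()].
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(hidden_layers = c(512L, 256L, 128L, 64L, 32L),
                        n_folds_classification = 5L, n_folds_regression = 3L,
                        seed = 42L, scrambled = FALSE, standardize = FALSE,
                        max_iter = 200L, batch_size = 200L,
                        learning_rate = 1e-3, alpha = 1e-4) {
  structure(list(hidden_layers = hidden_layers,
                 n_folds_classification = as.integer(n_folds_classification),
                 n_folds_regression = as.integer(n_folds_regression),
                 seed = as.integer(seed), scrambled = isTRUE(scrambled),
                 standardize = isTRUE(standardize),
                 max_iter = as.integer(max_iter),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, alpha = alpha),
            class = "eval_config")
}

.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.standardize_pair <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"))
}

.cv_report <- function(per_fold, scrambled, task, n) {
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold),
                 sd = apply(per_fold, 2, stats::sd),
                 scrambled = scrambled, task = task, n = n),
            class = "electrum_cv")
}

#' @export
print.electrum_cv <- function(x, ...) {
  cat("<electrum_cv> ", x$task, if (x$scrambled) " (scrambled-label control)",
      ", ", nrow(x$per_fold), " folds, n = ", x$n, "\n", sep = "")
  if (x$task == "classification") {
    for (m in colnames(x$per_fold)) {
      cat(sprintf("  %-9s %5.1f%% ± %.2f\n", m, 100 * x$mean[m], 100 * x$sd[m]))
    }
  } else {
    cat(sprintf("  R²  %.3f ± %.3f\n", x$mean["r2"], x$sd["r2"]))
  }
  invisible(x)
}

#' Cross-validated MLP classification
#'
#' Stratified k-fold cross-validation of the benchmark MLP. With
#' `config$scrambled` the labels are permuted once at dataset level (same
#' seed) before folding, giving the chance-level negative control. Runs are
#' fully deterministic given the configuration seed.
#'
#' @param features Numeric feature matrix (e.g. from
#'   [fingerprint_matrix()]).
#' @param labels Class labels, one per row.
#' @param config An [eval_config()].
#' @return An `electrum_cv` report: per-fold metrics plus mean and sd.
#' @export
crossval_classify <- function(features, labels, config = eval_config()) {
  x <- as.matrix(features)
  labels <- factor(labels)
  stopifnot(nrow(x) == length(labels))
  k <- config$n_folds_classification
  set.seed(config$seed)
  if (config$scrambled) labels <- sample(labels)
  small <- table(labels) < k
  if (any(small)) {
    stop("class(es) too small to stratify into ", k, " folds: ",
         paste(names(which(small)), collapse = ", "),
         "; consider filter_by_class_support()", call. = FALSE)
  }
  fold <- .stratified_folds(labels, k)
  per_fold <- matrix(NA_real_, k, 6,
                     dimnames = list(NULL, c("roc_auc", "prc_auc", "accuracy",
                                             "precision", "recall", "f1")))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    if (config$standardize) {
      sp <- .standardize_pair(xtr, xte); xtr <- sp$train; xte <- sp$test
    }
    fit <- mlp_fit(xtr, labels[tr], hidden = config$hidden_layers,
                   task = "classification", seed = config$seed + f,
                   max_iter = config$max_iter, batch_size = config$batch_size,
                   learning_rate = config$learning_rate, alpha = config$alpha)
    prob <- predict(fit, xte, type = "prob")
    pred <- predict(fit, xte, type = "class")
    per_fold[f, ] <- macro_classification_metrics(labels[te], pred, prob)
  }
  .cv_report(per_fold, config$scrambled, "classification", nrow(x))
}

#' Cross-validated MLP regression
#'
#' k-fold (default 3) cross-validation reporting the coefficient of
#' determination R-squared on each held-out fold.
#'
#' @param features Numeric feature matrix.
#' @param targets Numeric target vector.
#' @param config An [eval_config()]; `n_folds_regression` controls the folds
#'   and `scrambled` permutes the targets once before folding.
#' @return An `electrum_cv` report with per-fold `r2`.
#' @export
crossval_regress <- function(features, targets, config = eval_config()) {
  x <- as.matrix(features)
  targets <- as.numeric(targets)
  stopifnot(nrow(x) == length(targets))
  if (stats::sd(targets) == 0) {
    stop("constant target: R-squared is undefined", call. = FALSE)
  }
  k <- config$n_folds_regression
  if (nrow(x) < 3L * k) stop("need at least ", 3L * k, " samples", call. = FALSE)
  set.seed(config$seed)
  if (config$scrambled) targets <- sample(targets)
  fold <- sample(rep_len(seq_len(k), nrow(x)))
  per_fold <- matrix(NA_real_, k, 1, dimnames = list(NULL, "r2"))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    if (config$standardize) {
      sp <- .standardize_pair(xtr, xte); xtr <- sp$train; xte <- sp$test
    }
    fit <- mlp_fit(xtr, targets[tr], hidden = config$hidden_layers,
                   task = "regression", seed = config$seed + f,
                   max_iter = config$max_iter, batch_size = config$batch_size,
                   learning_rate = config$learning_rate, alpha = config$alpha)
    pred <- predict(fit, xte)
    yte <- targets[te]
    per_fold[f, 1] <- 1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
  }
  .cv_report(per_fold, config$scrambled, "regression", nrow(x))
}
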