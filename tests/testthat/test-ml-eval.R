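test_that("macro metrics match hand-computed values on a 3-class table", {
  true <- c("a", "a", "a", "b", "b", "c")
  pred <- c("a", "b", "a", "b", "c", "c")
  m <- macro_classification_metrics(true, pred)
  # per class: a: P=1, R=2/3; b: P=1/2, R=1/2; c: P=1/2, R=1
  expect_equal(unname(m["precision"]), (1 + 0.5 + 0.5) / 3)
  expect_equal(unname(m["recall"]), (2 / 3 + 0.5 + 1) / 3)
  expect_equal(unname(m["f1"]), (0.8 + 0.5 + 2 / 3) / 3)
  expect_equal(unname(m["accuracy"]), 4 / 6)
})

test_that("AUROC and AUPRC match hand-derived values and the rank oracle", {
  scores <- c(0.9, 0.8, 0.4, 0.1)
  truth <- c("p", "n", "p", "n")
  sc <- cbind(p = scores, n = 1 - scores)
  m <- macro_classification_metrics(truth, ifelse(scores > 0.5, "p", "n"), sc)
  # positives ranked 4 and 2 of 4: AUC = (6 - 3) / 4
  # one-vs-rest over both classes is symmetric here
  expect_equal(unname(m["roc_auc"]), 0.75)
  # step-wise AP for class p: 0.5*1 + 0.5*(2/3) = 5/6; for class n the same
  expect_equal(unname(m["prc_auc"]), 5 / 6)

  # cross-check AUROC against pROC on random data; with two classes scored
  # s and 1 - s the two one-vs-rest AUCs coincide, so macro == binary AUC
  requireNamespace("pROC")
  set.seed(31)
  for (i in 1:5) {
    s <- runif(60)
    y <- sample(c("x", "y"), 60, replace = TRUE)
    ours <- macro_classification_metrics(y, ifelse(s > 0.5, "x", "y"),
                                         cbind(x = s, y = 1 - s))
    ref <- as.numeric(pROC::auc(pROC::roc(y == "x", s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(unname(ours["roc_auc"]), ref, tolerance = 1e-10)
  }
})

test_that("degenerate scorers hit the textbook endpoints", {
  y <- rep(c("a", "b"), each = 10)
  perfect <- cbind(a = rep(c(1, 0), each = 10), b = rep(c(0, 1), each = 10))
  m <- macro_classification_metrics(y, y, perfect)
  expect_equal(unname(m[c("roc_auc", "precision", "recall", "f1")]),
               c(1, 1, 1, 1))
  flat <- cbind(a = rep(0.5, 20), b = rep(0.5, 20))
  m2 <- macro_classification_metrics(y, sample(y), flat)
  expect_equal(unname(m2["roc_auc"]), 0.5)
  expect_error(macro_classification_metrics(rep("a", 5), rep("a", 5)),
               "at least 2 classes")
  expect_message(
    macro_classification_metrics(y, y, cbind(perfect, c = runif(20))),
    "absent from true labels")
})

test_that("the MLP recovers separable structure and is deterministic", {
  set.seed(41)
  n <- 200
  x <- matrix(rnorm(n * 10), n)
  y <- factor(ifelse(x[, 1] + x[, 2] > 0, "pos", "neg"))
  cfg <- eval_config(hidden_layers = c(32L, 16L), seed = 7, max_iter = 100)
  cv <- crossval_classify(x, y, cfg)
  expect_gte(unname(cv$mean["accuracy"]), 0.9)
  expect_gte(unname(cv$mean["roc_auc"]), 0.95)
  cv2 <- crossval_classify(x, y, cfg)
  expect_identical(cv$per_fold, cv2$per_fold)
})

test_that("scrambled labels drive performance to chance", {
  set.seed(43)
  n <- 200
  x <- matrix(rnorm(n * 10), n)
  y <- factor(ifelse(x[, 1] > 0, "pos", "neg"))
  cv <- crossval_classify(x, y, eval_config(hidden_layers = c(32L, 16L),
                                            seed = 7, max_iter = 60,
                                            scrambled = TRUE))
  expect_lt(abs(unname(cv$mean["roc_auc"]) - 0.5), 0.1)
})

test_that("small classes trigger the stratification error", {
  x <- matrix(rnorm(40), 20)
  y <- factor(c(rep("a", 17), rep("b", 3)))
  expect_error(crossval_classify(x, y, eval_config()), "filter_by_class_support")
})

test_that("regression recovers linear signal and rejects constant targets", {
  set.seed(47)
  n <- 150
  x <- matrix(rpois(n * 20, 2), n)
  y <- x[, 1:5] %*% c(2, -1, 0.5, 1, -2)
  cfg <- eval_config(hidden_layers = c(32L, 16L), seed = 9, max_iter = 200)
  cv <- crossval_regress(x, as.numeric(y), cfg)
  expect_gte(unname(cv$mean["r2"]), 0.9)
  expect_equal(nrow(cv$per_fold), 3L)

  noise <- rnorm(n)
  cvn <- crossval_regress(x, noise, cfg)
  expect_lte(unname(cvn$mean["r2"]), 0.1)

  expect_error(crossval_regress(x, rep(1, n), cfg), "constant target")
  cv2 <- crossval_regress(x, as.numeric(y), cfg)
  expect_identical(cv$per_fold, cv2$per_fold)
})

test_that("scrambled runs do not beat true-label runs on signal-bearing data", {
  set.seed(53)
  n <- 120
  x <- matrix(rnorm(n * 8), n)
  y <- factor(ifelse(x[, 1] + 0.5 * x[, 2] > 0, "u", "v"))
  gaps <- vapply(1:5, function(s) {
    cfg_t <- eval_config(hidden_layers = c(16L, 8L), seed = s)
    cfg_s <- eval_config(hidden_layers = c(16L, 8L), seed = s, scrambled = TRUE)
    unname(crossval_classify(x, y, cfg_t)$mean["roc_auc"] -
             crossval_classify(x, y, cfg_s)$mean["roc_auc"])
  }, numeric(1))
  expect_gt(mean(gaps), 0.2)
  expect_true(all(gaps > 0))
})
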