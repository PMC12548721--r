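# Minimal multilayer perceptron in base R matrix ops: ReLU hidden layers,
# softmax/cross-entropy or identity/squared-error head, Adam updates with L2
# penalty, minibatches, and tolerance-based stopping. Defaults mirror the
# widely used scikit-learn MLP defaults (lr 1e-3, batch 200, alpha 1e-4,
# max 200 epochs, tol 1e-4 over 10 stagnant epochs) so that "no tuning"
# evaluations are reproducible.

.relu <- function(x) { x[x < 0] <- 0; x }

.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fit a multilayer perceptron
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Labels: factor/character for classification, numeric for
#'   regression.
#' @param hidden Integer vector of hidden-layer widths; the default
#'   `c(512, 256, 128, 64, 32)` is the benchmark architecture.
#' @param task `"classification"` or `"regression"` (inferred from `y` when
#'   omitted).
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @param max_iter Maximum number of epochs.
#' @param batch_size Minibatch size (capped at the sample count).
#' @param learning_rate Adam step size.
#' @param alpha L2 penalty coefficient.
#' @param tol,n_iter_no_change Stop when the epoch loss has not improved by
#'   more than `tol` for `n_iter_no_change` consecutive epochs.
#' @return Object of class `electrum_mlp` with weight matrices, the class
#'   levels (classification) and the per-epoch loss curve.
#' @export
mlp_fit <- function(x, y, hidden = c(512L, 256L, 128L, 64L, 32L),
                    task = NULL, seed = 1L, max_iter = 200L,
                    batch_size = 200L, learning_rate = 1e-3, alpha = 1e-4,
                    tol = 1e-4, n_iter_no_change = 10L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(task)) {
    task <- if (is.numeric(y)) "regression" else "classification"
  }
  task <- match.arg(task, c("classification", "regression"))
  if (task == "classification") {
    y <- factor(y)
    classes <- levels(y)
    if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
    Y <- matrix(0, n, length(classes))
    Y[cbind(seq_len(n), as.integer(y))] <- 1
    n_out <- length(classes)
  } else {
    classes <- NULL
    Y <- matrix(as.numeric(y), ncol = 1)
    n_out <- 1L
  }

  dims <- c(ncol(x), hidden, n_out)
  L <- length(dims) - 1L
  set.seed(seed)
  W <- vector("list", L); B <- vector("list", L)
  mW <- vector("list", L); vW <- vector("list", L)
  mB <- vector("list", L); vB <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1L]))
    W[[l]] <- matrix(runif(dims[l] * dims[l + 1L], -lim, lim), dims[l], dims[l + 1L])
    B[[l]] <- numeric(dims[l + 1L])
    mW[[l]] <- matrix(0, dims[l], dims[l + 1L]); vW[[l]] <- mW[[l]]
    mB[[l]] <- numeric(dims[l + 1L]); vB[[l]] <- mB[[l]]
  }

  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  batch_size <- min(batch_size, n)
  best <- Inf; stagnant <- 0L
  loss_curve <- numeric(0)

  for (epoch in seq_len(max_iter)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    for (bs in seq(1L, n, by = batch_size)) {
      idx <- perm[bs:min(bs + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]; yb <- Y[idx, , drop = FALSE]
      m <- length(idx)
      # forward
      A <- vector("list", L + 1L); A[[1L]] <- xb
      for (l in seq_len(L)) {
        z <- sweep(A[[l]] %*% W[[l]], 2, B[[l]], "+")
        A[[l + 1L]] <- if (l < L) .relu(z) else z
      }
      if (task == "classification") {
        P <- .softmax_rows(A[[L + 1L]])
        loss <- -sum(yb * log(pmax(P, 1e-12))) / m
        delta <- (P - yb) / m
      } else {
        P <- A[[L + 1L]]
        loss <- 0.5 * sum((P - yb)^2) / m
        delta <- (P - yb) / m
      }
      l2 <- 0
      for (l in seq_len(L)) l2 <- l2 + sum(W[[l]]^2)
      epoch_loss <- epoch_loss + (loss + alpha * l2 / (2 * m)) * m
      # backward + Adam
      step <- step + 1L
      corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
      for (l in L:1) {
        gW <- crossprod(A[[l]], delta) + (alpha / m) * W[[l]]
        gB <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
        }
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
        mB[[l]] <- b1 * mB[[l]] + (1 - b1) * gB
        vB[[l]] <- b2 * vB[[l]] + (1 - b2) * gB^2
        W[[l]] <- W[[l]] - learning_rate * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
        B[[l]] <- B[[l]] - learning_rate * (mB[[l]] / corr1) / (sqrt(vB[[l]] / corr2) + eps)
      }
    }
    epoch_loss <- epoch_loss / n
    loss_curve <- c(loss_curve, epoch_loss)
    if (epoch_loss < best - tol) {
      best <- epoch_loss; stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant >= n_iter_no_change) break
    }
  }

  structure(list(weights = W, biases = B, task = task, classes = classes,
                 hidden = hidden, loss_curve = loss_curve),
            class = "electrum_mlp")
}

#' Predict from a fitted MLP
#'
#' @param object An `electrum_mlp`.
#' @param newdata Feature matrix.
#' @param type `"prob"` (class-probability matrix), `"class"` (labels) or
#'   `"response"` (numeric predictions; regression default).
#' @param ... Unused.
#' @return Matrix, factor or numeric vector depending on `type` and task.
#' @export
predict.electrum_mlp <- function(object, newdata,
                                 type = c("prob", "class", "response"), ...) {
  type <- match.arg(type)
  A <- as.matrix(newdata)
  L <- length(object$weights)
  for (l in seq_len(L)) {
    z <- sweep(A %*% object$weights[[l]], 2, object$biases[[l]], "+")
    A <- if (l < L) .relu(z) else z
  }
  if (object$task == "regression") return(as.numeric(A))
  P <- .softmax_rows(A)
  colnames(P) <- object$classes
  if (type == "class") {
    factor(object$classes[max.col(P, ties.method = "first")], levels = object$classes)
  } else P
}

#' @export
print.electrum_mlp <- function(x, ...) {
  cat("<electrum_mlp> ", x$task, ", hidden layers ",
      paste(x$hidden, collapse = "/"),
      if (!is.null(x$classes)) paste0(", ", length(x$classes), " classes"),
      ", ", length(x$loss_curve), " epochs (final loss ",
      format(tail(x$loss_curve, 1), digits = 4), ")\n", sep = "")
  invisible(x)
}
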