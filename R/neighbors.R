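# Manhattan-distance similarity and exact k-nearest-neighbor graphs over
# fingerprint space. Exact search (blocked brute force) rather than an
# approximate index: the datasets handled here are desk-scale and exactness
# keeps the graph oracle-testable.

#' Manhattan (L1) distance between two fingerprint vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Sum of absolute coordinate differences.
#' @export
manhattan_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("dimension mismatch: ", length(a), " vs ", length(b), call. = FALSE)
  }
  sum(abs(a - b))
}

#' Exact k-nearest-neighbor graph under Manhattan distance
#'
#' Each point receives its `min(k, n - 1)` exact nearest neighbors; ties at
#' equal distance are broken toward the lower index, so the graph is fully
#' deterministic. No self-edges.
#'
#' @param fingerprints Numeric matrix (one row per point) or list of
#'   equal-length vectors.
#' @param k Number of outgoing edges per point (default 20).
#' @param block Number of query rows processed per sweep (memory knob).
#' @return Object of class `electrum_knn`: list with `n_points`, `k` and
#'   `edges` (data.frame `source`, `target`, `distance`).
#' @export
knn_graph <- function(fingerprints, k = 20L, block = 64L) {
  if (is.list(fingerprints) && !is.data.frame(fingerprints)) {
    fingerprints <- do.call(rbind, fingerprints)
  }
  x <- as.matrix(fingerprints)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  keff <- min(k, n - 1L)
  xt <- t(x)
  src <- integer(n * keff); tgt <- integer(n * keff); dst <- numeric(n * keff)
  pos <- 0L
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    for (i in rows) {
      d <- colSums(abs(xt - x[i, ]))
      d[i] <- Inf                      # no self-edge
      nb <- order(d, seq_len(n))[seq_len(keff)]
      idx <- pos + seq_len(keff)
      src[idx] <- i; tgt[idx] <- nb; dst[idx] <- d[nb]
      pos <- pos + keff
    }
  }
  structure(list(n_points = n, k = as.integer(k),
                 edges = data.frame(source = src, target = tgt, distance = dst)),
            class = "electrum_knn")
}

#' @export
print.electrum_knn <- function(x, ...) {
  cat("<electrum_knn> ", x$n_points, " points, k = ", x$k, ", ",
      nrow(x$edges), " directed edges, mean distance ",
      format(mean(x$edges$distance), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write a k-NN graph as a delimited edge list
#'
#' Plain `source,target,distance` CSV consumable by external layout or
#' visualization tools (e.g. tree-map style embeddings of chemical space).
#'
#' @param graph An `electrum_knn`.
#' @param path Output file path.
#' @export
write_knn_edges <- function(graph, path) {
  stopifnot(inherits(graph, "electrum_knn"))
  utils::write.csv(graph$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a k-NN edge list written by [write_knn_edges()]
#'
#' @param path Edge-list CSV path.
#' @param n_points,k Graph dimensions to restore (inferred from the edges
#'   when omitted).
#' @return An `electrum_knn`.
#' @export
read_knn_edges <- function(path, n_points = NULL, k = NULL) {
  edges <- utils::read.csv(path)
  stopifnot(all(c("source", "target", "distance") %in% names(edges)))
  if (is.null(n_points)) n_points <- max(edges$source, edges$target)
  if (is.null(k)) k <- max(table(edges$source))
  structure(list(n_points = as.integer(n_points), k = as.integer(k),
                 edges = edges), class = "electrum_knn")
}
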