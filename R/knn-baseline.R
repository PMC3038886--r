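#' Nearest-neighbor baseline with asymptotic confident predictability
#'
#' A 3-nearest-neighbor majority-vote classifier in the same pair-difference
#' feature space, used as the comparison baseline for the kernel method.
#' Its confident-predictability rule is only asymptotically justified (it
#' assumes the true class-1 probability is at most 0.30 or at least 0.70
#' for every patient, and a virtually infinite sample): a prediction is CP
#' exactly when all neighbors agree.
#'
#' @param query numeric feature vector.
#' @param train_features N x k matrix of training feature vectors.
#' @param train_labels length-N vector of 0/1 labels.
#' @param n_neighbors odd neighbor count (default 3; even values rejected
#'   so the majority is always defined).
#' @return a `knn_prediction`: `class_call` (majority label), `cp_flag`
#'   (unanimity), `neighbor_labels`, `neighbor_index` (ties among
#'   equidistant neighbors broken by lowest training index).
#' @export
knn_predict <- function(query, train_features, train_labels,
                        n_neighbors = 3L) {
  check_scalar(n_neighbors, "n_neighbors", lower = 1)
  n_neighbors <- as.integer(n_neighbors)
  if (n_neighbors %% 2L == 0L) {
    stop("n_neighbors must be odd so the majority vote is always defined")
  }
  train_features <- as_point_matrix(train_features, length(query))
  n <- nrow(train_features)
  if (n < n_neighbors) {
    stop(sprintf("need at least %d training points, have %d", n_neighbors, n))
  }
  y <- as.integer(train_labels)
  if (length(y) != n || anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop("labels must be 0/1 and match the training rows")
  }
  d <- sqrt(rowSums(sweep(train_features, 2L, query)^2))
  idx <- order(d, seq_len(n), method = "radix")[seq_len(n_neighbors)]
  labs <- y[idx]
  structure(
    list(
      class_call = as.integer(sum(labs) * 2L > n_neighbors),
      cp_flag = all(labs == labs[1L]),
      neighbor_labels = labs,
      neighbor_index = idx
    ),
    class = "knn_prediction"
  )
}

#' @export
print.knn_prediction <- function(x, ...) {
  cat(sprintf(
    "knn_prediction: class = %d, confidently predictable = %s (labels %s)\n",
    x$class_call, x$cp_flag, paste(x$neighbor_labels, collapse = ",")
  ))
  invisible(x)
}
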