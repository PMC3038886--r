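# Shared fixtures and independent oracles for the test suite.

# Small random labeled dataset; tie_digits > 0 rounds intensities to force
# tied values, exercising the strict-inequality and average-rank conventions.
random_dataset <- function(n_genes, n_samples, seed, tie_digits = NULL) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  if (!is.null(tie_digits)) v <- round(v, tie_digits)
  labels <- sample(rep(c(0L, 1L), length.out = n_samples))
  expression_dataset(v, labels = labels)
}

# Dataset built from an explicit matrix and labels, with default ids.
make_dataset <- function(values, labels) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expression_dataset(values, labels = labels)
}

# ---- independent k-TSP oracle -------------------------------------------
# Scores every unordered pair by explicit per-sample counting loops, picks
# the orientation (prefer p0 >= p1, then larger delta, then smaller leading
# id), sorts, and runs the greedy disjoint scan. Shares no code with the
# production selector beyond base R.
brute_force_ktsp <- function(dataset, k) {
  ids <- dataset$gene_ids
  v <- dataset$values
  idx0 <- which(dataset$labels == 0L)
  idx1 <- which(dataset$labels == 1L)
  freq_less <- function(a, b, idx) {
    cnt <- 0L
    for (m in idx) if (v[a, m] < v[b, m]) cnt <- cnt + 1L
    cnt / length(idx)
  }
  recs <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      orient <- function(a, b) {
        p0 <- freq_less(a, b, idx0)
        p1 <- freq_less(a, b, idx1)
        list(gene_a = a, gene_b = b, p0 = p0, p1 = p1, delta = abs(p0 - p1))
      }
      fwd <- orient(ids[i], ids[j])
      bwd <- orient(ids[j], ids[i])
      pick <- if ((fwd$p0 >= fwd$p1) != (bwd$p0 >= bwd$p1)) {
        if (fwd$p0 >= fwd$p1) fwd else bwd
      } else if (fwd$delta != bwd$delta) {
        if (fwd$delta > bwd$delta) fwd else bwd
      } else fwd  # ids[i] < ids[j] lexicographically by construction
      ra <- rank(v[ids[i], ], ties.method = "average")
      rb <- rank(v[ids[j], ], ties.method = "average")
      d <- ra - rb
      pick$gamma <- abs(mean(d[idx0]) - mean(d[idx1]))
      recs[[length(recs) + 1L]] <- pick
    }
  }
  tab <- do.call(rbind, lapply(recs, as.data.frame))
  tab <- tab[order(-tab$delta, -tab$gamma, tab$gene_a, tab$gene_b,
                   method = "radix"), ]
  used <- character(0)
  out <- list()
  for (r in seq_len(nrow(tab))) {
    if (tab$gene_a[r] %in% used || tab$gene_b[r] %in% used) next
    out[[length(out) + 1L]] <- tab[r, ]
    used <- c(used, tab$gene_a[r], tab$gene_b[r])
    if (length(out) == k) break
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("gene_a", "gene_b", "delta", "gamma", "p0", "p1")]
}

# Random geometry for tikhonov path-equivalence checks, generated the way
# the estimator generates it: sigma comes from the fraction rule (fractions
# spanning the sweep range 0.2-1.4) and the neighborhood is the i nearest
# of a larger training cloud, so M stays in the regime the method visits.
random_fit_instance <- function(seed) {
  set.seed(seed)
  k <- sample(1:10, 1)
  n <- sample(5:25, 1)
  i <- sample(1:n, 1)
  query <- rnorm(k)
  pts <- matrix(rnorm(n * k), n, k)
  d <- sqrt(rowSums(sweep(pts, 2, query)^2))
  sigma <- runif(1, 0.2, 1.4) * max(d)
  ord <- order(d)
  alpha <- runif(1, 0.2, 0.8)
  list(query = query, neighbors = pts[ord[seq_len(i)], , drop = FALSE],
       sigma = sigma, M = m_bound(d[ord[i]], sigma, alpha))
}

# Labeled feature-space training set (no expression step) for estimator
# property tests.
random_training <- function(seed, n = 15, k = 4) {
  set.seed(seed)
  list(query = rnorm(k),
       features = matrix(rnorm(n * k), n, k),
       labels = sample(rep(c(0L, 1L), length.out = n)))
}

expect_prediction_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$f_raw, b$f_raw, tolerance = tol)
  expect_equal(a$rmse_bound, b$rmse_bound, tolerance = tol)
  expect_identical(a$class_call, b$class_call)
  expect_identical(a$cp_flag, b$cp_flag)
  expect_equal(a$ci_low, b$ci_low, tolerance = tol)
  expect_equal(a$ci_high, b$ci_high, tolerance = tol)
  expect_identical(a$fit$i, b$fit$i)
  expect_equal(a$fit$radius, b$fit$radius, tolerance = tol)
}
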