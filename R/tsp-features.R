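#' k-Top-Scoring-Pairs feature selection
#'
#' The k-TSP selector ranks every unordered gene pair by the between-class
#' difference of ordering frequencies and keeps the top k pairs subject to
#' gene disjointness. For a pair (a, b) and class c, `p_c` is the fraction
#' of class-c samples in which the intensity of `a` is strictly below the
#' intensity of `b` (ties count as "not less"). The primary score is
#' `delta = |p0 - p1|`; ties are broken by `gamma`, the absolute
#' between-class difference of mean per-gene rank differences, then
#' lexicographically by gene id. Selected pairs are oriented so `p0 >= p1`,
#' making the feature `a - b` tend larger in class 1 (cancer).
#'
#' @name tsp_features
NULL

class_indices <- function(dataset) {
  if (is.null(dataset$labels)) stop("dataset has no labels; attach them first")
  idx0 <- which(dataset$labels == 0L)
  idx1 <- which(dataset$labels == 1L)
  if (!length(idx0) || !length(idx1)) {
    stop("both classes must be present (0 = normal, 1 = cancer)")
  }
  list(idx0 = idx0, idx1 = idx1)
}

require_genes <- function(dataset, genes) {
  missing <- setdiff(genes, dataset$gene_ids)
  if (length(missing)) {
    stop("gene id(s) not in dataset: ", paste(missing, collapse = ", "))
  }
}

#' Pair ordering score for one oriented gene pair
#'
#' @param dataset labeled [expression_dataset()].
#' @param gene_a,gene_b gene ids (direction matters: the counted event is
#'   `value(gene_a) < value(gene_b)`).
#' @return list with `delta`, `p0`, `p1`.
#' @export
pair_score <- function(dataset, gene_a, gene_b) {
  require_genes(dataset, c(gene_a, gene_b))
  cls <- class_indices(dataset)
  a <- dataset$values[gene_a, ]
  b <- dataset$values[gene_b, ]
  p0 <- mean(a[cls$idx0] < b[cls$idx0])
  p1 <- mean(a[cls$idx1] < b[cls$idx1])
  list(delta = abs(p0 - p1), p0 = p0, p1 = p1)
}

#' Rank-based tie-break score for a gene pair
#'
#' Each gene's intensities are replaced by their ranks across the N patients
#' (average ranks for ties); the score is the absolute difference between the
#' class means of the per-patient rank difference. Symmetric in orientation.
#'
#' @inheritParams pair_score
#' @return scalar `gamma` in rank units.
#' @export
rank_tiebreak_score <- function(dataset, gene_a, gene_b) {
  require_genes(dataset, c(gene_a, gene_b))
  cls <- class_indices(dataset)
  ra <- rank(dataset$values[gene_a, ], ties.method = "average")
  rb <- rank(dataset$values[gene_b, ], ties.method = "average")
  d <- ra - rb
  abs(mean(d[cls$idx0]) - mean(d[cls$idx1]))
}

# All-pairs class-conditional counts of the event value(i) < value(j),
# returned as G x G matrices of relative frequencies.
all_pair_frequencies <- function(values, idx) {
  g <- nrow(values)
  acc <- matrix(0L, g, g)
  for (m in idx) {
    acc <- acc + outer(values[, m], values[, m], "<")
  }
  acc / length(idx)
}

#' Select the top k disjoint scoring pairs
#'
#' Scores all G(G-1)/2 unordered pairs, sorts by (delta desc, gamma desc,
#' gene ids asc), then greedily scans the sorted list taking a pair only if
#' neither of its genes has been used before, until k pairs are selected.
#'
#' @param dataset labeled [expression_dataset()] with G >= 2k genes.
#' @param k number of disjoint pairs (default 10).
#' @return a `tsp_model`: list with `pairs` (data.frame of gene_a, gene_b,
#'   delta, gamma, p0, p1 in rank order) and `k`.
#' @export
select_top_k_disjoint <- function(dataset, k = 10L) {
  check_scalar(k, "k", lower = 1)
  k <- as.integer(k)
  cls <- class_indices(dataset)
  g <- length(dataset$gene_ids)
  if (g < 2L * k) {
    stop(sprintf("need at least 2k = %d genes, dataset has %d", 2L * k, g))
  }
  v <- dataset$values
  p0m <- all_pair_frequencies(v, cls$idx0)
  p1m <- all_pair_frequencies(v, cls$idx1)
  # gamma decomposes over genes: mean class-0 rank minus mean class-1 rank
  ranks <- t(apply(v, 1L, rank, ties.method = "average"))
  if (ncol(v) == 1L) ranks <- t(ranks)  # apply() drops dims for N = 1
  s <- rowMeans(ranks[, cls$idx0, drop = FALSE]) -
    rowMeans(ranks[, cls$idx1, drop = FALSE])

  ut <- which(upper.tri(p0m), arr.ind = TRUE)
  i <- ut[, 1L]; j <- ut[, 2L]
  ids <- dataset$gene_ids
  # choose orientation per unordered pair: prefer p0 >= p1, then larger
  # delta, then the lexicographically smaller leading gene id
  fwd <- cbind(p0 = p0m[ut], p1 = p1m[ut])                    # (i, j)
  rev <- cbind(p0 = p0m[cbind(j, i)], p1 = p1m[cbind(j, i)])  # (j, i)
  d_fwd <- abs(fwd[, 1L] - fwd[, 2L])
  d_rev <- abs(rev[, 1L] - rev[, 2L])
  ok_fwd <- fwd[, 1L] >= fwd[, 2L]
  ok_rev <- rev[, 1L] >= rev[, 2L]
  lex_fwd <- ids[i] <= ids[j]
  use_fwd <- ifelse(ok_fwd != ok_rev, ok_fwd,
             ifelse(d_fwd != d_rev, d_fwd > d_rev, lex_fwd))
  cand <- data.frame(
    gene_a = ifelse(use_fwd, ids[i], ids[j]),
    gene_b = ifelse(use_fwd, ids[j], ids[i]),
    delta = ifelse(use_fwd, d_fwd, d_rev),
    gamma = abs(s[i] - s[j]),
    p0 = ifelse(use_fwd, fwd[, 1L], rev[, 1L]),
    p1 = ifelse(use_fwd, fwd[, 2L], rev[, 2L]),
    stringsAsFactors = FALSE
  )
  ord <- order(-cand$delta, -cand$gamma, cand$gene_a, cand$gene_b,
               method = "radix")
  cand <- cand[ord, , drop = FALSE]

  used <- character(0)
  take <- integer(0)
  for (r in seq_len(nrow(cand))) {
    if (cand$gene_a[r] %in% used || cand$gene_b[r] %in% used) next
    take <- c(take, r)
    used <- c(used, cand$gene_a[r], cand$gene_b[r])
    if (length(take) == k) break
  }
  if (length(take) < k) {
    stop(sprintf("only %d disjoint pairs available, requested k = %d",
                 length(take), k))
  }
  pairs <- cand[take, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, k = k), class = "tsp_model")
}

#' @export
print.tsp_model <- function(x, ...) {
  cat(sprintf("tsp_model: %d disjoint gene pairs\n", x$k))
  print(x$pairs, digits = 4)
  invisible(x)
}

#' Pair-difference feature transform for one sample
#'
#' @param sample_values named numeric vector mapping gene id to intensity;
#'   must cover every gene used by the model.
#' @param model a `tsp_model`.
#' @return numeric feature vector of length `model$k`, component t equal to
#'   `sample_values[gene_a_t] - sample_values[gene_b_t]`.
#' @export
tsp_transform <- function(sample_values, model) {
  stopifnot(inherits(model, "tsp_model"))
  need <- unique(c(model$pairs$gene_a, model$pairs$gene_b))
  missing <- setdiff(need, names(sample_values))
  if (length(missing)) {
    stop("sample is missing gene(s): ", paste(missing, collapse = ", "))
  }
  unname(sample_values[model$pairs$gene_a] - sample_values[model$pairs$gene_b])
}

#' Pair-difference feature matrix for a whole dataset
#'
#' @param dataset an [expression_dataset()] (labels not required).
#' @param model a `tsp_model`.
#' @return N x k numeric matrix, rownames = sample ids, one column per pair.
#' @export
feature_matrix <- function(dataset, model) {
  stopifnot(inherits(model, "tsp_model"))
  require_genes(dataset, unique(c(model$pairs$gene_a, model$pairs$gene_b)))
  f <- t(dataset$values[model$pairs$gene_a, , drop = FALSE] -
           dataset$values[model$pairs$gene_b, , drop = FALSE])
  dimnames(f) <- list(dataset$sample_ids, NULL)
  f
}

#' Serialize / restore a selected pair signature
#'
#' @param model a `tsp_model`.
#' @param path JSON file path.
#' @export
write_tsp_model <- function(model, path) {
  stopifnot(inherits(model, "tsp_model"))
  jsonlite::write_json(list(k = model$k, pairs = model$pairs), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tsp_model
#' @export
read_tsp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- as.data.frame(obj$pairs, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "delta", "gamma", "p0", "p1")
  if (!all(need %in% names(pairs))) {
    stop("not a tsp_model JSON file: ", path)
  }
  structure(list(pairs = pairs[need], k = as.integer(obj$k)),
            class = "tsp_model")
}
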