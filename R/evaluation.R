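#' Leave-one-out cross-validation of the individualized classifier
#'
#' For each sample in turn: k-TSP feature selection is re-run on the other
#' N - 1 samples only (so the held-out profile never influences its own
#' feature space), all samples are mapped to pair-difference features, and
#' the held-out sample is predicted with the requested method.
#'
#' @param dataset labeled [expression_dataset()] with at least two samples
#'   per class.
#' @param config a [minimax_config()]; `config$k` pairs are selected in
#'   every fold (folds that cannot supply k disjoint pairs fail loudly).
#' @param method `"kernel"` (local minimax) or `"knn"` (3-NN baseline).
#' @param n_neighbors neighbor count for `method = "knn"`.
#' @param verbose emit per-fold progress on stderr.
#' @return list with `predictions` (named list, one per sample) and
#'   `summary` (a [summarize_cohort()] result against the true labels).
#' @export
loocv <- function(dataset, config = minimax_config(),
                  method = c("kernel", "knn"), n_neighbors = 3L,
                  verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$labels)) stop("dataset has no labels")
  n <- length(dataset$sample_ids)
  if (min(table(factor(dataset$labels, levels = c(0L, 1L)))) < 2L) {
    stop("need at least 2 samples per class for leave-one-out")
  }
  predictions <- vector("list", n)
  names(predictions) <- dataset$sample_ids
  for (j in seq_len(n)) {
    sid <- dataset$sample_ids[j]
    train <- expression_dataset(dataset$values[, -j, drop = FALSE],
                                labels = dataset$labels[-j])
    if (length(unique(train$labels)) < 2L) {
      stop(sprintf("fold '%s': training set contains a single class", sid))
    }
    model <- select_top_k_disjoint(train, config$k)
    feats <- feature_matrix(train, model)
    qf <- tsp_transform(dataset$values[, j], model)
    predictions[[j]] <- if (method == "kernel") {
      minimax_estimate(qf, feats, train$labels, config)
    } else {
      knn_predict(qf, feats, train$labels, n_neighbors)
    }
    if (verbose) {
      message(sprintf("fold %d/%d (%s): class %d%s", j, n, sid,
                      predictions[[j]]$class_call,
                      if (predictions[[j]]$cp_flag) " [CP]" else ""))
    }
  }
  list(predictions = predictions,
       summary = summarize_cohort(predictions, dataset$labels, config))
}

#' Cohort summary of confident predictability and error
#'
#' Counts confidently predictable (CP) patients, classification errors
#' among the CP patients, and total classification errors; class calls come
#' from the unadjusted estimate at threshold 0.5 (or the majority vote for
#' the k-NN baseline). With zero CP patients the error-in-CP percentage is
#' undefined and reported as NA (printed as an em dash), not 0.
#'
#' @param predictions non-empty named list of predictions.
#' @param truth 0/1 vector of true labels, named by sample id or in the
#'   same order as `predictions`.
#' @param config optional [minimax_config()] echoed into the summary so a
#'   report is reproducible from its own header.
#' @return a `cohort_summary` list of counts and percentages.
#' @export
summarize_cohort <- function(predictions, truth, config = NULL) {
  if (!length(predictions)) stop("empty prediction list")
  if (!is.null(names(truth)) && !is.null(names(predictions))) {
    missing <- setdiff(names(predictions), names(truth))
    if (length(missing)) {
      stop("truth missing for: ", paste(missing, collapse = ", "))
    }
    truth <- truth[names(predictions)]
  }
  if (length(truth) != length(predictions)) {
    stop("truth does not match predictions")
  }
  truth <- as.integer(truth)
  calls <- vapply(predictions, function(p) p$class_call, integer(1))
  cp <- vapply(predictions, function(p) p$cp_flag, logical(1))
  n <- length(predictions)
  cp_count <- sum(cp)
  errors_in_cp <- sum(cp & calls != truth)
  total_errors <- sum(calls != truth)
  structure(
    list(
      n = n,
      cp_count = cp_count,
      cp_percent = 100 * cp_count / n,
      errors_in_cp = errors_in_cp,
      error_in_cp_percent = if (cp_count > 0) 100 * errors_in_cp / cp_count
                            else NA_real_,
      total_errors = total_errors,
      total_error_percent = 100 * total_errors / n,
      config = if (is.null(config)) NULL else unclass(config)
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  ecp <- if (is.na(x$error_in_cp_percent)) "—"
         else sprintf("%.2f%%", x$error_in_cp_percent)
  cat(sprintf(
    "cohort of %d: CP %d (%.1f%%), errors in CP %d (%s), total errors %d (%.2f%%)\n",
    x$n, x$cp_count, x$cp_percent, x$errors_in_cp, ecp,
    x$total_errors, x$total_error_percent
  ))
  if (!is.null(x$config)) {
    cat(sprintf(
      "  config: sigma_fraction %.2f, alpha %.2f, beta %.2f, p %.2f, e %.2f, k %d\n",
      x$config$sigma_fraction, x$config$alpha, x$config$beta,
      x$config$p_threshold, x$config$adjustment_e, x$config$k
    ))
  }
  invisible(x)
}

#' Cohort-level bandwidth sweep
#'
#' Runs leave-one-out cross-validation at each sigma fraction in the grid
#' and tabulates %CP, %error-in-CP and %total error. Feature selection does
#' not depend on sigma, so it is performed once per fold and reused across
#' the whole grid.
#'
#' @inheritParams loocv
#' @param fractions positive grid of sigma fractions (default 0.2-1.4).
#' @return data.frame with one row per fraction: `fraction`, `cp_percent`,
#'   `error_in_cp_percent`, `total_error_percent`.
#' @export
cohort_sigma_sweep <- function(dataset, config = minimax_config(),
                               fractions = seq(0.2, 1.4, by = 0.1)) {
  if (!length(fractions)) stop("empty fraction grid")
  if (any(fractions <= 0)) stop("fractions must be positive")
  stopifnot(inherits(dataset, "expression_dataset"))
  n <- length(dataset$sample_ids)
  folds <- lapply(seq_len(n), function(j) {
    train <- expression_dataset(dataset$values[, -j, drop = FALSE],
                                labels = dataset$labels[-j])
    model <- select_top_k_disjoint(train, config$k)
    list(feats = feature_matrix(train, model),
         labels = train$labels,
         query = tsp_transform(dataset$values[, j], model))
  })
  rows <- lapply(fractions, function(fr) {
    cfg <- config
    cfg$sigma_fraction <- fr
    preds <- lapply(folds, function(f) {
      minimax_estimate(f$query, f$feats, f$labels, cfg)
    })
    names(preds) <- dataset$sample_ids
    s <- summarize_cohort(preds, dataset$labels, cfg)
    data.frame(fraction = fr, cp_percent = s$cp_percent,
               error_in_cp_percent = s$error_in_cp_percent,
               total_error_percent = s$total_error_percent)
  })
  do.call(rbind, rows)
}
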