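#' Configuration for the local minimax kernel estimator
#'
#' @param sigma_fraction Gaussian bandwidth as a fraction of the distance
#'   from the query to its furthest training point (> 0; 0.5 and 0.7 are
#'   the reference settings).
#' @param alpha prior constant of the probability model class, in (0, 1);
#'   0.5 minimizes the smoothness bound and is the default.
#' @param beta one-sided confidence-interval miss level in (0, 0.5);
#'   0.10 gives 90% one-sided intervals.
#' @param p_threshold confident-predictability level p in (0, 0.5]: a
#'   patient is CP when the clipped interval lies inside [0, p] or
#'   [1 - p, 1].
#' @param adjustment_e resampling adjustment e in [0, 0.5]: labels Y are
#'   replaced by e + (1 - 2e)Y inside the reported estimate to compensate
#'   for label reuse during feature selection. Never affects class calls
#'   or interval widths.
#' @param k number of top-scoring pairs (features) to select.
#' @return a `minimax_config` list.
#' @export
minimax_config <- function(sigma_fraction = 0.5, alpha = 0.5, beta = 0.10,
                           p_threshold = 0.35, adjustment_e = 0, k = 10L) {
  check_scalar(sigma_fraction, "sigma_fraction", lower = 0, open_lower = TRUE)
  check_scalar(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_scalar(beta, "beta", 0, 0.5, open_lower = TRUE, open_upper = TRUE)
  check_scalar(p_threshold, "p_threshold", 0, 0.5, open_lower = TRUE)
  check_scalar(adjustment_e, "adjustment_e", 0, 0.5)
  check_scalar(k, "k", lower = 1)
  structure(
    list(sigma_fraction = sigma_fraction, alpha = alpha, beta = beta,
         p_threshold = p_threshold, adjustment_e = adjustment_e,
         k = as.integer(k)),
    class = "minimax_config"
  )
}

#' Gaussian kernel
#'
#' `K(z, x) = exp(-||x - z||^2 / (2 sigma^2))` with the Euclidean norm.
#'
#' @param u,v points in R^k.
#' @param sigma bandwidth (> 0).
#' @return kernel value in (0, 1].
#' @export
gaussian_kernel <- function(u, v, sigma) {
  check_scalar(sigma, "sigma", lower = 0, open_lower = TRUE)
  if (length(u) != length(v)) stop("points have different dimensions")
  exp(-sum((u - v)^2) / (2 * sigma^2))
}

# Kernel matrix between row sets of x and y (y = NULL means x vs x).
gaussian_kernel_matrix <- function(x, y = NULL, sigma) {
  if (is.null(y)) y <- x
  sq <- outer(rowSums(x^2), rep(1, nrow(y))) +
    outer(rep(1, nrow(x)), rowSums(y^2)) - 2 * tcrossprod(x, y)
  sq[sq < 0] <- 0  # numerical negatives on coincident points
  exp(-sq / (2 * sigma^2))
}

#' Query-local kernel bandwidth
#'
#' `sigma = sigma_fraction` times the distance from the query to its
#' furthest training point.
#'
#' @param query numeric vector in feature space.
#' @param train numeric matrix of training points (rows).
#' @param sigma_fraction positive fraction.
#' @return bandwidth sigma.
#' @export
bandwidth_from_query <- function(query, train, sigma_fraction = 0.5) {
  check_scalar(sigma_fraction, "sigma_fraction", lower = 0, open_lower = TRUE)
  train <- as_point_matrix(train, length(query))
  d <- sqrt(rowSums(sweep(train, 2L, query)^2))
  if (max(d) == 0) {
    stop("all training points coincide with the query; bandwidth undefined")
  }
  sigma_fraction * max(d)
}

as_point_matrix <- function(x, k = NULL) {
  if (is.null(dim(x))) {
    if (is.null(k) || length(x) == k) {
      x <- matrix(x, nrow = 1L)        # a single point
    } else if (k == 1L) {
      x <- matrix(x, ncol = 1L)        # many 1-d points
    } else {
      stop(sprintf("cannot interpret a length-%d vector as points in R^%d",
                   length(x), k))
    }
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' Smoothness bound M for a neighborhood ball
#'
#' For the ball V of radius r about the query, the estimator's model class
#' (probability functions `alpha + (1 - alpha) f1 - alpha f2` with each
#' `f_l` a positive kernel sum on V, bounded in (0, 1)) has kernel norm of
#' `f - alpha` bounded by
#' `M = sqrt(alpha^2 + (1 - alpha)^2) * c^(-1/2)` where
#' `c = max_{x in V} min_{y in V} K(y, x)`. For the Gaussian kernel on a
#' ball the max-min has the closed form `c = exp(-r^2 / (2 sigma^2))`
#' (inner maximum at the center, minimum at the antipodal boundary point),
#' hence `M = sqrt(alpha^2 + (1 - alpha)^2) * exp(r^2 / (4 sigma^2))`.
#'
#' @param radius ball radius r >= 0 (distance to the i-th nearest point).
#' @param sigma kernel bandwidth (> 0).
#' @param alpha prior constant in (0, 1).
#' @return the bound M (>= sqrt(1/2) for alpha = 0.5; non-decreasing in r).
#' @export
m_bound <- function(radius, sigma, alpha = 0.5) {
  check_scalar(radius, "radius", lower = 0)
  check_scalar(sigma, "sigma", lower = 0, open_lower = TRUE)
  check_scalar(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  sqrt(alpha^2 + (1 - alpha)^2) * exp(radius^2 / (4 * sigma^2))
}

check_distinct_points <- function(pts, what = "training points") {
  if (anyDuplicated(round(pts, 12))) {
    stop("coincident ", what,
         " make the kernel system singular; deduplicate them first")
  }
}

#' Improved Tikhonov fit on a fixed neighborhood (ridge form)
#'
#' Production path: solves the i x i kernel-ridge system
#' `(K + gamma I) w = kvec` with `gamma = (0.5 / M)^2`, where K is the
#' neighbor kernel matrix and kvec the query-to-neighbor kernel vector; the
#' minimax MSE bound is `M^2 (1 - kvec' w)`. Algebraically identical to the
#' direct (i+1) x (i+1) inverse formulation in [tikhonov_fit_direct()],
#' which is retained as an independent oracle.
#'
#' @param query numeric vector.
#' @param neighbors i x k matrix of distinct training points.
#' @param sigma kernel bandwidth.
#' @param M smoothness bound from [m_bound()].
#' @return list with `weights` (length i), `mse_bound` and `gamma`.
#' @export
tikhonov_fit <- function(query, neighbors, sigma, M) {
  check_scalar(M, "M", lower = 0, open_lower = TRUE)
  neighbors <- as_point_matrix(neighbors, length(query))
  check_distinct_points(neighbors, "neighbors")
  kmat <- gaussian_kernel_matrix(neighbors, sigma = sigma)
  kvec <- drop(gaussian_kernel_matrix(neighbors,
                                      matrix(query, nrow = 1L), sigma))
  gamma <- (0.5 / M)^2
  w <- unname(drop(solve(kmat + diag(gamma, nrow(kmat)), kvec)))
  mse <- unname(M^2 * (1 - sum(kvec * w)))
  if (mse < -1e-8) stop("negative MSE bound; numerically singular system")
  list(weights = w, mse_bound = max(mse, 0), gamma = gamma)
}

#' Improved Tikhonov fit via the direct (i+1) x (i+1) inverse
#'
#' Oracle path: builds `A = sigma* + M^2 K*` over the query plus its i
#' neighbors, with `sigma* = diag(0, 0.25, ..., 0.25)` (Bernoulli noise
#' variance bound 0.25) and K* the full kernel matrix; then
#' `mse = 1 / [A^-1]_{00}` and the weight vector is minus the first row of
#' `A^-1` times mse, whose leading entry is identically -1.
#'
#' @inheritParams tikhonov_fit
#' @return list with `weights`, `mse_bound`, `w0` (the leading -1 entry,
#'   returned for verification).
#' @export
tikhonov_fit_direct <- function(query, neighbors, sigma, M) {
  check_scalar(M, "M", lower = 0, open_lower = TRUE)
  neighbors <- as_point_matrix(neighbors, length(query))
  check_distinct_points(neighbors, "neighbors")
  pts <- rbind(query, neighbors)
  kstar <- gaussian_kernel_matrix(pts, sigma = sigma)
  sigstar <- diag(c(0, rep(0.25, nrow(neighbors))))
  ainv <- solve(sigstar + M^2 * kstar)
  mse <- unname(1 / ainv[1L, 1L])
  wfull <- unname(-ainv[1L, ] * mse)
  list(weights = unname(wfull[-1L]), mse_bound = mse, w0 = unname(wfull[1L]))
}

#' One-sided confidence interval pair for a probability estimate
#'
#' Each one-sided level (1 - beta) interval is `(F - rho * s, Inf)` or
#' `(-Inf, F + rho * s)` with `s = sqrt(1 + z_beta^2)` and `z_beta` the
#' exact standard normal (1 - beta) quantile; since the target is a
#' probability the infinite endpoints are replaced by 0 and 1. The exact
#' quantile (z = 1.281552, s = 1.625543 at beta = 0.10) is used rather than
#' a rounded multiplier.
#'
#' @param f (unclipped) probability estimate F(w).
#' @param rho upper bound on root mean squared error (>= 0).
#' @param beta one-sided miss level in (0, 0.5).
#' @return list with `low`, `high` clipped to [0, 1].
#' @export
confidence_interval <- function(f, rho, beta = 0.10) {
  check_scalar(rho, "rho", lower = 0)
  check_scalar(beta, "beta", 0, 0.5, open_lower = TRUE, open_upper = TRUE)
  half <- rho * sqrt(1 + stats::qnorm(1 - beta)^2)
  list(low = max(0, f - half), high = min(1, f + half))
}

#' Confident-predictability decision
#'
#' TRUE when the clipped confidence interval lies entirely inside [0, p]
#' or entirely inside [1 - p, 1]; such patients carry the stated one-sided
#' confidence that their true class-1 probability is in that end interval.
#' Others are deferred (reject option).
#'
#' @param ci_low,ci_high clipped interval endpoints, 0 <= low <= high <= 1.
#' @param p_threshold predictability threshold p in (0, 0.5].
#' @return logical.
#' @export
is_confidently_predictable <- function(ci_low, ci_high, p_threshold = 0.35) {
  check_scalar(p_threshold, "p_threshold", 0, 0.5, open_lower = TRUE)
  if (any(ci_low < 0 | ci_high > 1 | ci_low > ci_high)) {
    stop("interval endpoints must satisfy 0 <= low <= high <= 1")
  }
  ci_high <= p_threshold | ci_low >= 1 - p_threshold
}

#' Local minimax prediction for one query
#'
#' Sorts the training points by distance to the query (ties by original
#' index), fits the improved Tikhonov estimator on every candidate
#' neighborhood i = 1..N with the ball-specific smoothness bound M_i, and
#' keeps the neighborhood i* minimizing the finite-sample MSE bound
#' (ties -> smallest i). The estimate is affine in the labels,
#' `F(w) = w* + sum_j w_j Y_j` with contextual offset
#' `w* = alpha (1 - sum_j w_j)`; the reported estimate applies the
#' adjustment e and is clipped to [0, 1]; the confidence interval is formed
#' from the unclipped adjusted estimate and then clipped. The class call
#' uses the unadjusted estimate at threshold 0.5.
#'
#' @param query numeric feature vector.
#' @param train_features N x k matrix of distinct training feature vectors.
#' @param train_labels length-N vector of 0/1 labels.
#' @param config a [minimax_config()].
#' @return a `minimax_prediction`: `f_raw`, `f_adjusted`, `f_reported`,
#'   `rmse_bound`, `ci_low`, `ci_high`, `class_call`, `cp_flag`, and `fit`
#'   (neighborhood size `i`, `radius`, `sigma`, `M`, `gamma`, `weights`,
#'   `w_star`, `mse_bound`, `neighbor_index` into the original training
#'   order, and the full `mse_curve` over i).
#' @export
minimax_estimate <- function(query, train_features, train_labels,
                             config = minimax_config()) {
  stopifnot(inherits(config, "minimax_config"))
  train_features <- as_point_matrix(train_features, length(query))
  n <- nrow(train_features)
  if (length(train_labels) != n) stop("labels do not match training rows")
  y <- as.integer(train_labels)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) stop("labels must all be 0 or 1")
  check_distinct_points(train_features)

  d <- sqrt(rowSums(sweep(train_features, 2L, query)^2))
  sigma <- bandwidth_from_query(query, train_features, config$sigma_fraction)
  ord <- order(d, seq_len(n), method = "radix")
  xs <- train_features[ord, , drop = FALSE]
  ds <- d[ord]
  ys <- y[ord]

  kmat <- gaussian_kernel_matrix(xs, sigma = sigma)
  kvec <- drop(gaussian_kernel_matrix(xs, matrix(query, nrow = 1L), sigma))
  mse_curve <- numeric(n)
  mvals <- vapply(ds, m_bound, numeric(1), sigma = sigma, alpha = config$alpha)
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    gamma <- (0.5 / mvals[i])^2
    w <- drop(solve(kmat[1:i, 1:i, drop = FALSE] + diag(gamma, i), kvec[1:i]))
    mse_curve[i] <- max(mvals[i]^2 * (1 - sum(kvec[1:i] * w)), 0)
    fits[[i]] <- list(weights = w, gamma = gamma)
  }
  i_star <- which.min(mse_curve)  # first minimum = smallest neighborhood
  w <- fits[[i_star]]$weights
  w_star <- config$alpha * (1 - sum(w))
  yy <- ys[seq_len(i_star)]
  e <- config$adjustment_e
  f_raw <- w_star + sum(w * yy)
  f_adjusted <- w_star + sum(w * (e + (1 - 2 * e) * yy))
  rho <- sqrt(mse_curve[i_star])
  ci <- confidence_interval(f_adjusted, rho, config$beta)

  structure(
    list(
      f_raw = f_raw,
      f_adjusted = f_adjusted,
      f_reported = min(max(f_adjusted, 0), 1),
      rmse_bound = rho,
      ci_low = ci$low,
      ci_high = ci$high,
      class_call = as.integer(f_raw >= 0.5),
      cp_flag = is_confidently_predictable(ci$low, ci$high, config$p_threshold),
      fit = list(
        i = i_star, radius = ds[i_star], sigma = sigma, M = mvals[i_star],
        gamma = fits[[i_star]]$gamma, weights = w, w_star = w_star,
        mse_bound = mse_curve[i_star], neighbor_index = ord[seq_len(i_star)],
        order = ord, mse_curve = mse_curve
      )
    ),
    class = "minimax_prediction"
  )
}

#' @export
print.minimax_prediction <- function(x, ...) {
  cat(sprintf(
    paste0("minimax_prediction: F = %.4f (raw %.4f), rho = %.4f, ",
           "CI [%.3f, %.3f]\n  class = %d, confidently predictable = %s, ",
           "i* = %d of radius %.4g, sigma = %.4g\n"),
    x$f_reported, x$f_raw, x$rmse_bound, x$ci_low, x$ci_high,
    x$class_call, x$cp_flag, x$fit$i, x$fit$radius, x$fit$sigma
  ))
  invisible(x)
}

#' Per-patient bandwidth sweep
#'
#' Re-runs [minimax_estimate()] for one query over a grid of bandwidth
#' fractions (default 0.2 to 1.4 by 0.1). The attribute
#' `suggested_lower_limit` carries the recommended smallest fraction: the
#' distance to the ceiling(N/5)-th closest training point divided by the
#' distance to the furthest.
#'
#' @inheritParams minimax_estimate
#' @param fractions positive grid of sigma fractions.
#' @return data.frame with one row per fraction: `fraction`, `f_reported`,
#'   `ci_low`, `ci_high`, `i_star`, `sigma`, `cp_flag`.
#' @export
sigma_sweep <- function(query, train_features, train_labels,
                        config = minimax_config(),
                        fractions = seq(0.2, 1.4, by = 0.1)) {
  if (!length(fractions)) stop("empty fraction grid")
  if (any(fractions <= 0)) stop("fractions must be positive")
  train_features <- as_point_matrix(train_features, length(query))
  rows <- lapply(fractions, function(fr) {
    cfg <- config
    cfg$sigma_fraction <- fr
    p <- minimax_estimate(query, train_features, train_labels, cfg)
    data.frame(fraction = fr, f_reported = p$f_reported,
               ci_low = p$ci_low, ci_high = p$ci_high,
               i_star = p$fit$i, sigma = p$fit$sigma, cp_flag = p$cp_flag)
  })
  out <- do.call(rbind, rows)
  d <- sort(sqrt(rowSums(sweep(train_features, 2L, query)^2)))
  j <- ceiling(nrow(train_features) / 5)
  attr(out, "suggested_lower_limit") <- d[j] / d[length(d)]
  out
}
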