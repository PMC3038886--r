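test_that("gaussian kernel has unit diagonal, known values, and PSD Gram", {
  expect_equal(gaussian_kernel(c(1, 2), c(1, 2), sigma = 3), 1)
  # distance sigma * sqrt(2) -> exp(-1)
  expect_equal(gaussian_kernel(0, sqrt(2) * 1.7, sigma = 1.7), exp(-1))
  expect_error(gaussian_kernel(0, 1, sigma = 0), "sigma")

  set.seed(71)
  pts <- matrix(rnorm(10), 5, 2)
  gram <- outer(1:5, 1:5, Vectorize(function(i, j) {
    gaussian_kernel(pts[i, ], pts[j, ], sigma = 0.8)
  }))
  expect_equal(gram, t(gram))
  expect_true(all(eigen(gram, symmetric = TRUE)$values > 0))
  # matches the vectorized matrix builder used internally
  expect_equal(gram, localminimax:::gaussian_kernel_matrix(pts, sigma = 0.8))
})

test_that("bandwidth is the stated fraction of the furthest distance", {
  train <- rbind(c(2, 0), c(0, 1))
  expect_equal(bandwidth_from_query(c(0, 0), train, 0.5), 1)
  expect_equal(bandwidth_from_query(c(0, 0), matrix(c(10, 0), 1), 0.7), 7)
  expect_equal(bandwidth_from_query(c(1, 1), rbind(c(1, 4)), 0.5), 1.5)
  expect_error(bandwidth_from_query(c(0, 0), rbind(c(0, 0), c(0, 0)), 0.5),
               "coincide")
})

test_that("the smoothness bound matches its closed form and a grid search", {
  expect_equal(m_bound(0, 2, 0.5), sqrt(0.5))
  s <- 1.3
  expect_equal(m_bound(s * sqrt(2), s, 0.5), sqrt(0.5) * exp(0.5))
  # monotone in radius
  r <- seq(0, 3, by = 0.1)
  expect_true(all(diff(vapply(r, m_bound, numeric(1), sigma = 1)) > 0))
  # alpha = 0.5 minimizes the prefactor
  expect_true(all(m_bound(1, 1, 0.5) < vapply(c(0.2, 0.35, 0.65, 0.8),
                                              function(a) m_bound(1, 1, a),
                                              numeric(1))))

  # grid search over a 2-d ball for c = max_x min_y K(y, x): the closed
  # form exp(-r^2 / (2 sigma^2)) is assumed by m_bound, verify it here.
  radius <- 1.4; sigma <- 1.1
  th <- seq(0, 2 * pi, length.out = 60)
  rr <- seq(0, radius, length.out = 25)
  grid <- cbind(c(outer(rr, cos(th))), c(outer(rr, sin(th))))
  kmat <- localminimax:::gaussian_kernel_matrix(grid, sigma = sigma)
  c_grid <- max(apply(kmat, 2, min))
  expect_equal(c_grid, exp(-radius^2 / (2 * sigma^2)), tolerance = 1e-3)
  expect_equal(m_bound(radius, sigma, 0.5),
               sqrt(0.5) * c_grid^(-0.5), tolerance = 1e-3)
})

test_that("single-neighbor Tikhonov fit matches the worked closed form", {
  # i = 1, neighbor at distance 1, sigma = 1, alpha = 0.5
  M <- m_bound(1, 1, 0.5)
  expect_equal(M^2, 0.5 * exp(0.5))
  fit <- tikhonov_fit(0, matrix(1), sigma = 1, M = M)
  gamma <- 0.25 / (0.5 * exp(0.5))
  w1 <- exp(-0.5) / (1 + gamma)
  expect_equal(fit$gamma, gamma)
  expect_equal(fit$weights, w1)
  expect_equal(fit$mse_bound, 0.5 * exp(0.5) * (1 - exp(-0.5) * w1))
  expect_equal(fit$mse_bound, 0.5916641, tolerance = 1e-6)

  # direct-inverse oracle agrees and its leading weight is exactly -1
  d <- tikhonov_fit_direct(0, matrix(1), sigma = 1, M = M)
  expect_equal(d$weights, fit$weights, tolerance = 1e-12)
  expect_equal(d$mse_bound, fit$mse_bound, tolerance = 1e-12)
  expect_equal(d$w0, -1, tolerance = 1e-12)
})

test_that("ridge and direct-inverse paths agree on random instances", {
  for (seed in 1:30) {
    inst <- random_fit_instance(seed)
    a <- tikhonov_fit(inst$query, inst$neighbors, inst$sigma, inst$M)
    b <- tikhonov_fit_direct(inst$query, inst$neighbors, inst$sigma, inst$M)
    expect_equal(a$weights, b$weights, tolerance = 1e-10)
    expect_equal(a$mse_bound, b$mse_bound, tolerance = 1e-10)
    expect_equal(b$w0, -1, tolerance = 1e-10)
    # Schur-complement positivity: 0 < MSE bound <= M^2
    expect_gt(a$mse_bound, 0)
    expect_lte(a$mse_bound, inst$M^2)
  }
})

test_that("coincident neighbors are rejected, not averaged", {
  pts <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_error(tikhonov_fit(c(0, 0), pts, 1, 1), "deduplicate")
  expect_error(minimax_estimate(c(0, 0), pts, c(0L, 1L, 1L)), "deduplicate")
})

test_that("the estimator composes its sub-operations and honors e", {
  tr <- random_training(81, n = 12, k = 3)
  cfg <- minimax_config(sigma_fraction = 0.6)
  p <- minimax_estimate(tr$query, tr$features, tr$labels, cfg)

  # recompose: sigma, neighborhood ordering, fit at i*, F, CI
  sigma <- bandwidth_from_query(tr$query, tr$features, 0.6)
  expect_equal(p$fit$sigma, sigma)
  d <- sqrt(rowSums(sweep(tr$features, 2, tr$query)^2))
  ord <- order(d)
  i <- p$fit$i
  M <- m_bound(sort(d)[i], sigma, cfg$alpha)
  fit <- tikhonov_fit(tr$query, tr$features[ord[1:i], , drop = FALSE], sigma, M)
  expect_equal(p$fit$M, M)
  expect_equal(p$fit$weights, fit$weights, tolerance = 1e-12)
  expect_equal(p$fit$mse_bound, fit$mse_bound, tolerance = 1e-12)
  w_star <- cfg$alpha * (1 - sum(fit$weights))
  expect_equal(p$fit$w_star, w_star)
  expect_equal(p$f_raw, w_star + sum(fit$weights * tr$labels[ord[1:i]]))
  ci <- confidence_interval(p$f_adjusted, sqrt(fit$mse_bound), cfg$beta)
  expect_equal(p$ci_low, ci$low)
  expect_equal(p$ci_high, ci$high)

  # i* minimizes the recorded MSE curve, ties to the smallest i
  expect_identical(p$fit$i, which.min(p$fit$mse_curve))

  # e = 0 leaves the estimate untouched
  expect_identical(p$f_adjusted, p$f_raw)

  # e = 0.05 shifts F but not class call, rho, or CI width
  cfg05 <- minimax_config(sigma_fraction = 0.6, adjustment_e = 0.05)
  p05 <- minimax_estimate(tr$query, tr$features, tr$labels, cfg05)
  expect_identical(p05$f_raw, p$f_raw)
  expect_identical(p05$class_call, p$class_call)
  expect_identical(p05$rmse_bound, p$rmse_bound)
  expect_equal(p05$f_adjusted,
               p$fit$w_star + sum(p$fit$weights *
                 (0.05 + 0.9 * tr$labels[ord[1:i]])))

  # e = 0.5 collapses the label term to w* + 0.5 * sum(w), label-free
  cfg50 <- minimax_config(sigma_fraction = 0.6, adjustment_e = 0.5)
  p50 <- minimax_estimate(tr$query, tr$features, tr$labels, cfg50)
  expect_equal(p50$f_adjusted, p$fit$w_star + 0.5 * sum(p$fit$weights))
  flipped <- minimax_estimate(tr$query, tr$features, 1L - tr$labels, cfg50)
  expect_equal(flipped$f_adjusted, p50$f_adjusted)
})

test_that("uncertainty is label-free and order-free", {
  for (seed in 1:20) {
    tr <- random_training(seed + 200)
    p <- minimax_estimate(tr$query, tr$features, tr$labels)
    # permuted labels: identical rho, i*, CI width; different F in general
    perm <- sample(length(tr$labels))
    q <- minimax_estimate(tr$query, tr$features, tr$labels[perm])
    expect_identical(q$rmse_bound, p$rmse_bound)
    expect_identical(q$fit$i, p$fit$i)
    # identical rho implies identical unclipped width 2 * rho * sqrt(1 + z^2)
    expect_identical(q$fit$mse_curve, p$fit$mse_curve)
    # permuted training rows: the whole prediction is unchanged
    r <- minimax_estimate(tr$query, tr$features[perm, , drop = FALSE],
                          tr$labels[perm])
    expect_prediction_equal(r, p)
  }
})

test_that("all-identical labels push the estimate toward the label", {
  tr <- random_training(91, n = 10, k = 2)
  ones <- minimax_estimate(tr$query, tr$features, rep(1L, 10))
  # F = alpha + (1 - alpha) sum(w) for alpha = 0.5
  expect_equal(ones$f_raw, 0.5 + 0.5 * sum(ones$fit$weights))
  expect_gte(sum(ones$fit$weights), 0)
  expect_identical(ones$class_call, 1L)
  zeros <- minimax_estimate(tr$query, tr$features, rep(0L, 10))
  expect_equal(zeros$f_raw, 0.5 * (1 - sum(zeros$fit$weights)))
  expect_identical(zeros$class_call, 0L)
  # same geometry, same uncertainty
  expect_identical(zeros$rmse_bound, ones$rmse_bound)
})

test_that("confidence intervals use exact normal quantiles and clip", {
  # multiplier sqrt(1 + z^2) at beta = 0.10
  mult <- sqrt(1 + qnorm(0.9)^2)
  expect_equal(mult, 1.6255382, tolerance = 1e-6)

  ci <- confidence_interval(0.579, 0.072, 0.10)
  expect_equal(round(ci$low, 3), 0.462)
  # ci$high is the separate one-sided upper bound, not the 1.0 printed in
  # the lower-interval presentation [0.462, 1.0]
  expect_equal(round(ci$high, 3), 0.696)

  ci <- confidence_interval(0.837, 0.159, 0.10)
  expect_equal(round(ci$low, 3), 0.579)

  # zero-width limit
  expect_equal(confidence_interval(0.3, 0, 0.10), list(low = 0.3, high = 0.3))
  expect_error(confidence_interval(0.3, -0.1, 0.10), "rho")

  # an unclipped negative estimate still yields a valid clipped interval
  ci <- confidence_interval(-0.11, 0.209, 0.10)
  expect_equal(ci$low, 0)
  expect_equal(round(ci$high, 3), 0.23)
})

test_that("confident predictability matches the four patient narratives", {
  expect_true(is_confidently_predictable(0.831, 1.0, 0.35))   # patient 12
  expect_true(is_confidently_predictable(0, 0.226, 0.35))     # patient 209
  expect_false(is_confidently_predictable(0.462, 1.0, 0.35))  # patient 244
  expect_false(is_confidently_predictable(0.579, 1.0, 0.35))  # patient 253

  # CP at p implies CP at any larger threshold
  set.seed(7)
  for (i in 1:50) {
    lo <- runif(1); hi <- runif(1, lo, 1)
    p1 <- runif(1, 0.01, 0.5); p2 <- runif(1, p1, 0.5)
    if (is_confidently_predictable(lo, hi, p1)) {
      expect_true(is_confidently_predictable(lo, hi, p2))
    }
  }
  expect_error(is_confidently_predictable(0.5, 0.4, 0.35), "low <= high")
})

test_that("the per-patient bandwidth sweep covers the grid", {
  tr <- random_training(101, n = 10, k = 3)
  sw <- sigma_sweep(tr$query, tr$features, tr$labels)
  expect_identical(nrow(sw), 13L)
  expect_equal(sw$fraction, seq(0.2, 1.4, by = 0.1))
  # each row's clipped CI brackets its reported estimate
  expect_true(all(sw$ci_low <= sw$f_reported + 1e-12 &
                    sw$f_reported <= sw$ci_high + 1e-12))
  # N = 10 -> suggested lower limit uses the 2nd closest distance
  d <- sort(sqrt(rowSums(sweep(tr$features, 2, tr$query)^2)))
  expect_equal(attr(sw, "suggested_lower_limit"), d[2] / d[10])
  expect_error(sigma_sweep(tr$query, tr$features, tr$labels,
                           fractions = numeric(0)), "empty")
})
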