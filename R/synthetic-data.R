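#' Generate a synthetic expression cohort with planted top-scoring pairs
#'
#' Emulates a two-class microarray-style intensity matrix: most genes are
#' uninformative baseline noise, while each planted pair carries a
#' class-linked intensity ordering. For a planted pair (a, b) the
#' generator draws a per-sample center and a strictly positive half-gap,
#' then orients a below b with probability `separation` in class 0 and
#' `1 - separation` in class 1, so the pair's ordering frequencies are
#' exactly `separation` vs `1 - separation` in expectation and its
#' orientation matches the selector's p0 >= p1 convention.
#'
#' @param n_per_class samples per class (class 0 = normal, 1 = cancer).
#' @param n_genes total gene count (>= 2 * n_informative_pairs).
#' @param n_informative_pairs number of planted pairs.
#' @param separation probability in (0.5, 1] that the informative ordering
#'   holds in its favored class.
#' @param noise_sd intensity noise scale (arbitrary units).
#' @param baseline mean background intensity.
#' @param baseline_sd spread of per-gene mean levels around `baseline`
#'   (genes differ in overall expression; the two genes of a planted pair
#'   share one level so the class signal lives in the within-pair flip,
#'   not in level differences).
#' @param margin minimum intensity gap inside a planted pair. The gap is
#'   kept strictly positive (so the planted ordering is exact given the
#'   flip) but small by default relative to `noise_sd`, as informative
#'   pairs in real data invert reliably without large expression
#'   differences; a gap that dwarfs the center noise would leak class
#'   signal into pairs formed across two planted pairs.
#' @param seed integer seed; equal seeds give identical cohorts.
#' @return a `synthetic_cohort`: `dataset` (labeled [expression_dataset()]),
#'   `planted_pairs` (data.frame gene_a, gene_b, oriented so p0 >= p1),
#'   and `spec` (the generator arguments).
#' @export
generate_cohort <- function(n_per_class = 25L, n_genes = 50L,
                            n_informative_pairs = 3L, separation = 0.95,
                            noise_sd = 1, baseline = 8, baseline_sd = 2,
                            margin = 0.5, seed = NULL) {
  check_scalar(n_per_class, "n_per_class", lower = 2)
  check_scalar(n_genes, "n_genes", lower = 2)
  check_scalar(separation, "separation", 0.5, 1, open_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0, open_lower = TRUE)
  check_scalar(margin, "margin", lower = 0, open_lower = TRUE)
  n_informative_pairs <- as.integer(n_informative_pairs)
  if (n_genes < 2L * n_informative_pairs) {
    stop("n_genes must be at least twice n_informative_pairs")
  }
  n <- 2L * as.integer(n_per_class)
  with_seed(seed, {
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    sample_ids <- c(sprintf("N%03d", seq_len(n_per_class)),
                    sprintf("T%03d", seq_len(n_per_class)))
    labels <- rep(c(0L, 1L), each = n_per_class)
    gene_level <- baseline + stats::rnorm(n_genes, sd = baseline_sd)
    values <- matrix(gene_level + stats::rnorm(n_genes * n, sd = noise_sd),
                     nrow = n_genes, dimnames = list(gene_ids, sample_ids))
    planted <- data.frame(
      gene_a = gene_ids[seq_len(n_informative_pairs) * 2L - 1L],
      gene_b = gene_ids[seq_len(n_informative_pairs) * 2L],
      stringsAsFactors = FALSE
    )
    for (t in seq_len(n_informative_pairs)) {
      # the pair's two genes share one expression level; the class signal
      # is carried purely by which of the two sits above the other
      pair_level <- baseline + stats::rnorm(1, sd = baseline_sd)
      center <- pair_level + stats::rnorm(n, sd = noise_sd)
      half_gap <- margin / 2 + abs(stats::rnorm(n, sd = margin / 2)) / 2
      p_below <- ifelse(labels == 0L, separation, 1 - separation)
      a_below <- stats::rbinom(n, 1L, p_below) == 1L
      lo <- center - half_gap
      hi <- center + half_gap
      values[planted$gene_a[t], ] <- ifelse(a_below, lo, hi)
      values[planted$gene_b[t], ] <- ifelse(a_below, hi, lo)
    }
    structure(
      list(
        dataset = expression_dataset(values, labels = labels),
        planted_pairs = planted,
        spec = list(n_per_class = n_per_class, n_genes = n_genes,
                    n_informative_pairs = n_informative_pairs,
                    separation = separation, noise_sd = noise_sd,
                    baseline = baseline, baseline_sd = baseline_sd,
                    margin = margin, seed = seed)
      ),
      class = "synthetic_cohort"
    )
  })
}

#' Generate a synthetic truth inside the estimator's model class
#'
#' Builds a probability function
#' `f(x) = alpha + (1 - alpha) f1(x) - alpha f2(x)` with each `f_l` a
#' positive Gaussian-kernel multiple centered AT the query point, so f
#' belongs to the model class of every candidate neighborhood ball around
#' the query. Training geometry is fixed first and the kernel bandwidth is
#' derived with the same fraction rule the estimator uses, so the function
#' class of the truth and of the estimator coincide. With coefficients
#' `a, b` in (0, 1), `0 < f_l < 1` holds everywhere and
#' `f` stays within (alpha - alpha*b, alpha + (1 - alpha)*a), a subset of
#' (0, 1); the kernel norm of `f - alpha` is `|(1 - alpha) a - alpha b|`,
#' always below the [m_bound()] of any ball.
#'
#' @param n_train number of training points.
#' @param k_dims feature-space dimension.
#' @param alpha prior constant in (0, 1).
#' @param sigma_fraction bandwidth fraction the estimator will use.
#' @param spread standard deviation of the Gaussian point cloud.
#' @param seed integer seed.
#' @return a `pk_alpha_scenario`: `train_features` (N x k), `query`,
#'   `alpha`, `sigma_fraction`, `sigma`, `f1_coefficient`,
#'   `f2_coefficient`, `f_train` (true probabilities at the training
#'   points), `true_probability_at_query`, `rkhs_norm`, `seed`.
#' @export
generate_pk_alpha <- function(n_train = 30L, k_dims = 5L, alpha = 0.5,
                              sigma_fraction = 0.5, spread = 1,
                              seed = NULL) {
  check_scalar(n_train, "n_train", lower = 1)
  check_scalar(k_dims, "k_dims", lower = 1)
  check_scalar(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_scalar(sigma_fraction, "sigma_fraction", lower = 0, open_lower = TRUE)
  with_seed(seed, {
    query <- stats::rnorm(k_dims, sd = spread)
    train <- matrix(stats::rnorm(n_train * k_dims, sd = spread),
                    nrow = n_train)
    sigma <- bandwidth_from_query(query, train, sigma_fraction)
    a <- stats::runif(1, 0.05, 0.95)
    b <- stats::runif(1, 0.05, 0.95)
    scen <- structure(
      list(train_features = train, query = query, alpha = alpha,
           sigma_fraction = sigma_fraction, sigma = sigma,
           f1_coefficient = a, f2_coefficient = b,
           f_train = NULL, true_probability_at_query = NULL,
           rkhs_norm = abs((1 - alpha) * a - alpha * b),
           seed = seed),
      class = "pk_alpha_scenario"
    )
    scen$f_train <- pk_alpha_value(scen, train)
    scen$true_probability_at_query <- pk_alpha_value(scen, query)
    scen
  })
}

#' Evaluate a scenario's true probability function
#'
#' @param scenario a `pk_alpha_scenario`.
#' @param x a point (vector) or matrix of points (rows).
#' @return true probability value(s) of f at x.
#' @export
pk_alpha_value <- function(scenario, x) {
  stopifnot(inherits(scenario, "pk_alpha_scenario"))
  x <- as_point_matrix(x, length(scenario$query))
  kv <- drop(gaussian_kernel_matrix(
    x, matrix(scenario$query, nrow = 1L), scenario$sigma))
  scenario$alpha +
    (1 - scenario$alpha) * scenario$f1_coefficient * kv -
    scenario$alpha * scenario$f2_coefficient * kv
}

#' Draw Bernoulli label replicates from a scenario
#'
#' Labels at each training point are independent Bernoulli draws with the
#' point's true probability (noise variance f(1-f) <= 0.25, within the
#' estimator's assumed noise bound).
#'
#' @param scenario a `pk_alpha_scenario`.
#' @param n_replicates number of replicate label vectors.
#' @param seed integer seed.
#' @return integer matrix, `n_replicates` x N.
#' @export
simulate_labels <- function(scenario, n_replicates, seed = NULL) {
  stopifnot(inherits(scenario, "pk_alpha_scenario"))
  check_scalar(n_replicates, "n_replicates", lower = 1)
  n <- nrow(scenario$train_features)
  with_seed(seed, {
    matrix(stats::rbinom(n_replicates * n, 1L,
                         rep(scenario$f_train, each = n_replicates)),
           nrow = n_replicates)
  })
}
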