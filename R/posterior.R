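# Joint posterior over source vectors, computed in log space across L sites.

#' Site log-likelihoods for every source vector (vectorized over sites)
#'
#' Internal engine of [joint_posterior()]: computes the L x 3 genotype
#' log-likelihood slab per sample once, then scores every source vector by
#' source-group factorization.
#'
#' @return L x n_vectors matrix of per-site log-likelihoods.
#' @noRd
site_log_likelihood_matrix <- function(data, vectors) {
  L <- length(data$pos)
  k <- length(data$sample_ids)
  total_depth <- data$n_A + data$n_B
  pB <- p_B_given_genotype(data$error_rate)
  ll <- array(0, dim = c(L, k, 3L))
  for (g in 1:3) {
    ll[, , g] <- stats::dbinom(data$n_B, total_depth, pB[g], log = TRUE)
  }
  lp <- hwe_genotype_log_prior(data$freq_B)
  if (L == 1L) lp <- matrix(lp, nrow = 1L)
  out <- matrix(0, L, length(vectors))
  for (j in seq_along(vectors)) {
    S <- vectors[[j]]
    total <- numeric(L)
    for (lab in unique(S)) {
      group <- lp
      for (d in which(S == lab)) group <- group + ll[, d, ]
      total <- total + log_row_sums_exp(group)
    }
    out[, j] <- total
  }
  out
}

#' Posterior distribution over source vectors
#'
#' Computes, for every partition of the k putative replicates into
#' identical-genotype groups, the joint log-likelihood across all L sites
#' (sites are treated as independent) and the posterior
#' `P(S | X) = P(X | S) P(S) / sum_S' P(X | S') P(S')`,
#' normalized in log space with a max-shift log-sum-exp. With the default
#' uniform prior, posterior ratios equal likelihood ratios.
#'
#' A source vector is "called" only if the posterior maximum reaches
#' `threshold`; a tie at the maximum (within 1e-12) yields no call, since
#' tied partitions are indistinguishable given the data.
#'
#' @param data A [replicate_dataset()].
#' @param prior Optional prior over source vectors, in the order of
#'   [enumerate_source_vectors()]; must be non-negative and sum to 1 within
#'   1e-9. Default: uniform.
#' @param threshold Posterior probability required to call a source vector,
#'   in (0, 1]. Default 0.99.
#' @return An object of class `posterior_result` with elements `vectors`
#'   (list of source vectors), `labels` (their `"1,2,1"` renderings),
#'   `log_likelihood`, `posterior`, `called` (an integer vector, or `NULL`
#'   for no call), `threshold`, `k`, `n_sites`, and `sample_ids`.
#' @examples
#' freqs <- rep(0.5, 4)
#' d <- replicate_dataset(c("a", "b"), rep("1", 4), 1:4 * 1000, freqs,
#'                        n_A = matrix(2L, 4, 2), n_B = matrix(0L, 4, 2))
#' joint_posterior(d)
#' @export
joint_posterior <- function(data, prior = NULL, threshold = 0.99) {
  stopifnot(inherits(data, "replicate_dataset"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("`threshold` must lie in (0, 1]", call. = FALSE)
  }
  k <- length(data$sample_ids)
  vectors <- enumerate_source_vectors(k)
  nS <- length(vectors)
  if (is.null(prior)) {
    log_prior <- rep(-log(nS), nS)
  } else {
    if (length(prior) != nS) {
      stop("`prior` must have one entry per source vector (", nS,
           " for k = ", k, ")", call. = FALSE)
    }
    if (any(prior < 0) || abs(sum(prior) - 1) > 1e-9) {
      stop("`prior` must be a proper probability distribution (sum 1 within 1e-9)",
           call. = FALSE)
    }
    log_prior <- log(prior)
  }
  log_lik <- colSums(site_log_likelihood_matrix(data, vectors))
  log_post_unnorm <- log_lik + log_prior
  log_post <- log_post_unnorm - log_sum_exp(log_post_unnorm)
  posterior <- exp(log_post)
  top <- which.max(posterior)
  tied <- sum(posterior >= posterior[top] - 1e-12) > 1L
  called <- if (!tied && posterior[top] >= threshold) vectors[[top]] else NULL
  structure(
    list(vectors = vectors,
         labels = vapply(vectors, format_source_vector, character(1)),
         log_likelihood = log_lik,
         log_posterior = log_post,
         posterior = posterior,
         called = called,
         threshold = threshold,
         prior = if (is.null(prior)) rep(1 / nS, nS) else prior,
         uniform_prior = is.null(prior),
         k = k,
         n_sites = length(data$pos),
         sample_ids = data$sample_ids),
    class = "posterior_result")
}

#' @export
print.posterior_result <- function(x, ...) {
  cat("posterior over source vectors (k = ", x$k, ", L = ", x$n_sites,
      " sites)\n", sep = "")
  ord <- order(x$posterior, decreasing = TRUE)
  show <- utils::head(ord, 8L)
  for (i in show) {
    cat(sprintf("  (%s)  posterior = %.6f\n", x$labels[i], x$posterior[i]))
  }
  if (length(ord) > length(show)) {
    cat("  ... ", length(ord) - length(show), " more\n", sep = "")
  }
  if (is.null(x$called)) {
    cat("no call at threshold ", x$threshold, "\n", sep = "")
  } else {
    cat("called: (", format_source_vector(x$called), ")\n", sep = "")
  }
  invisible(x)
}

#' Turn a posterior result into a tidy data frame
#'
#' @param x A `posterior_result`.
#' @param ... Unused.
#' @return Data frame with columns `source_vector`, `log_likelihood`,
#'   `posterior`, sorted by decreasing posterior.
#' @export
as.data.frame.posterior_result <- function(x, ...) {
  df <- data.frame(source_vector = x$labels,
                   log_likelihood = x$log_likelihood,
                   posterior = x$posterior)
  df[order(df$posterior, decreasing = TRUE), , drop = FALSE]
}

match_vector <- function(result, S) {
  idx <- match(format_source_vector(validate_source_vector(S, result$k)),
               result$labels)
  if (is.na(idx)) {
    stop("source vector (", format_source_vector(S),
         ") not found in the posterior result", call. = FALSE)
  }
  idx
}

#' Posterior odds of one source vector over another
#'
#' Ratio of posterior probabilities `P(S1|X) / P(S2|X)`, computed from the
#' log posterior so it stays finite even when both probabilities underflow
#' to zero on the linear scale. Under the default uniform prior this equals
#' the likelihood ratio, because the prior and the normalizing constant
#' cancel.
#'
#' @param result A `posterior_result`.
#' @param S1,S2 Source vectors present in the result.
#' @return A single numeric odds ratio.
#' @export
posterior_odds <- function(result, S1, S2) {
  stopifnot(inherits(result, "posterior_result"))
  i <- match_vector(result, S1)
  j <- match_vector(result, S2)
  exp(result$log_posterior[i] - result$log_posterior[j])
}

#' Non-replicate rate
#'
#' One minus the posterior probability of the all-ones source vector, i.e.
#' the posterior probability that at least one putative replicate does not
#' share the common genotype source ("probability of no errors" subtracted
#' from one). For k = 2 this is `1 - P(S = (1,1) | X)`.
#'
#' @param result A `posterior_result`.
#' @return A probability in `[0, 1]`.
#' @export
non_replicate_rate <- function(result) {
  stopifnot(inherits(result, "posterior_result"))
  1 - result$posterior[match_vector(result, rep(1L, result$k))]
}
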