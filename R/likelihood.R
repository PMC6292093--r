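# Genotype likelihoods from allelic depths and the Hardy-Weinberg prior.
#
# Observation model at one site for one sample: reads are conditionally
# independent Bernoulli draws of allele B given the genotype, with
#   P(read = B | g) = e (AA), 0.5 (AB), 1 - e (BB),
# where e is the symmetric per-read sequencing error rate. The allelic
# depth pair (n_A, n_B) is therefore binomial in n_B given the total.

GENOTYPES <- c("AA", "AB", "BB") # genotype codes 0, 1, 2 = copies of allele B

assert_error_rate <- function(e) {
  if (!is.numeric(e) || length(e) != 1L || is.na(e) || e <= 0 || e >= 0.5) {
    stop("`error_rate` must lie strictly between 0 and 0.5 ",
         "(e = 0 makes contradictory reads impossible and the model degenerate)",
         call. = FALSE)
  }
  e
}

assert_freq <- function(freq_B, what = "freq_B") {
  if (!is.numeric(freq_B) || anyNA(freq_B) || any(freq_B <= 0) || any(freq_B >= 1)) {
    stop("`", what, "` must lie strictly inside (0, 1); monomorphic sites ",
         "(frequency 0 or 1) carry no information and must be excluded upstream",
         call. = FALSE)
  }
  freq_B
}

assert_counts <- function(n, what) {
  if (!is.numeric(n) || anyNA(n) || any(n < 0) || any(n != floor(n))) {
    stop("`", what, "` must contain non-negative integer read counts", call. = FALSE)
  }
  n
}

#' Per-read probability of observing allele B for each genotype
#' @noRd
p_B_given_genotype <- function(error_rate) {
  c(error_rate, 0.5, 1 - error_rate)
}

#' Log-likelihood of a genotype given allelic depths
#'
#' Binomial read-count model: given genotype `g` (0, 1, 2 copies of allele
#' B) each read carries allele B with probability `e`, 0.5, or `1 - e`, so
#' `P(n_A, n_B | g) = C(n_A + n_B, n_B) (1 - p_B)^n_A p_B^n_B`. The binomial
#' coefficient is included (it cancels in the partition posterior but keeps
#' single-site values interpretable as probabilities). Zero total depth
#' yields log-likelihood 0 for every genotype: no reads, no information.
#'
#' @param n_A,n_B Non-negative read counts for alleles A and B; vectors are
#'   recycled to a common length.
#' @param g Genotype code: a single value in `{0, 1, 2}` for AA, AB, BB.
#' @param error_rate Per-read sequencing error rate, strictly in (0, 0.5).
#' @return Numeric vector of log-likelihoods.
#' @examples
#' genotype_log_likelihood(1, 1, g = 1, error_rate = 0.01) # log(0.5)
#' @export
genotype_log_likelihood <- function(n_A, n_B, g, error_rate = 0.01) {
  assert_counts(n_A, "n_A")
  assert_counts(n_B, "n_B")
  assert_error_rate(error_rate)
  if (length(g) != 1L || !g %in% 0:2) {
    stop("`g` must be a single genotype code in {0, 1, 2} (AA, AB, BB)",
         call. = FALSE)
  }
  p <- p_B_given_genotype(error_rate)[g + 1L]
  stats::dbinom(n_B, n_A + n_B, p, log = TRUE)
}

#' Hardy-Weinberg genotype log-prior
#'
#' Genotype probabilities `((1 - f)^2, 2 f (1 - f), f^2)` for (AA, AB, BB)
#' at a site with population B-allele frequency `f`, on the log scale.
#'
#' @param freq_B B-allele frequency, strictly in (0, 1). May be a vector.
#' @return For a single frequency, a named length-3 vector (AA, AB, BB);
#'   for a vector of frequencies, a matrix with one row per site and
#'   columns AA, AB, BB.
#' @examples
#' exp(hwe_genotype_log_prior(0.1)) # 0.81 0.18 0.01
#' @export
hwe_genotype_log_prior <- function(freq_B) {
  assert_freq(freq_B)
  out <- cbind(AA = 2 * log1p(-freq_B),
               AB = log(2) + log(freq_B) + log1p(-freq_B),
               BB = 2 * log(freq_B))
  if (length(freq_B) == 1L) out[1L, ] else out
}

#' Log-prior of a genotype vector given a source vector
#'
#' Under source vector `S`, samples sharing a source label must share a
#' genotype: any genotype vector violating this has probability zero
#' (returned as `-Inf`). Consistent vectors are scored as the product over
#' distinct sources of the Hardy-Weinberg prior of the group's shared
#' genotype, the shared genotype being treated as a single observation.
#'
#' @param G Integer vector of genotype codes (0/1/2), one per sample.
#' @param S Source vector of the same length (restricted-growth form).
#' @param freq_B Population B-allele frequency at the site, in (0, 1).
#' @return A single log-probability, `-Inf` for inconsistent vectors.
#' @examples
#' genotype_vector_log_prior(c(0, 1, 0), c(1, 1, 2), 0.3) # -Inf: group differs
#' @export
genotype_vector_log_prior <- function(G, S, freq_B) {
  S <- validate_source_vector(S)
  if (length(G) != length(S)) {
    stop("`G` has length ", length(G), " but `S` has length ", length(S),
         call. = FALSE)
  }
  if (anyNA(G) || !all(G %in% 0:2)) {
    stop("`G` must contain genotype codes in {0, 1, 2}", call. = FALSE)
  }
  lp <- hwe_genotype_log_prior(freq_B)
  total <- 0
  for (lab in unique(S)) {
    g_members <- unique(G[S == lab])
    if (length(g_members) > 1L) return(-Inf)
    total <- total + lp[g_members + 1L]
  }
  unname(total)
}

#' Site log-likelihood of a source vector
#'
#' Marginal probability of the k samples' allelic depths at one site given
#' that source vector `S` describes their relations, with the genotype
#' vector summed out:
#' `P(X | S) = sum_G [prod_d P(X_d | G_d)] P(G | S)`.
#' Because the prior factorizes over the distinct sources and forces shared
#' genotypes within a source, the sum over 3^k genotype vectors collapses
#' to, per source group, a sum over 3 genotypes of (HWE prior x product of
#' the group's member likelihoods).
#'
#' @param n_A,n_B Integer vectors of length k: read counts per sample.
#' @param freq_B Population B-allele frequency at the site, in (0, 1).
#' @param S Source vector of length k.
#' @param error_rate Per-read sequencing error rate in (0, 0.5).
#' @return A single log-probability.
#' @export
site_log_likelihood <- function(n_A, n_B, freq_B, S, error_rate = 0.01) {
  S <- validate_source_vector(S)
  k <- length(S)
  assert_counts(n_A, "n_A")
  assert_counts(n_B, "n_B")
  if (length(n_A) != k || length(n_B) != k) {
    stop("`n_A` and `n_B` must each have one count per sample (k = ", k, ")",
         call. = FALSE)
  }
  assert_freq(freq_B)
  assert_error_rate(error_rate)
  # k x 3 genotype log-likelihoods, then factorize by source group
  ll <- vapply(0:2, function(g) {
    genotype_log_likelihood(n_A, n_B, g, error_rate)
  }, numeric(k))
  ll <- matrix(ll, nrow = k)
  lp <- hwe_genotype_log_prior(freq_B)
  total <- 0
  for (lab in unique(S)) {
    members <- which(S == lab)
    total <- total + log_sum_exp(lp + colSums(ll[members, , drop = FALSE]))
  }
  total
}

# log(sum(exp(x))) with max-shift; handles all -Inf
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp for an L x 3 matrix (hot path of joint_posterior)
log_row_sums_exp <- function(m) {
  mx <- pmax(m[, 1L], m[, 2L], m[, 3L])
  out <- mx + log(exp(m[, 1L] - mx) + exp(m[, 2L] - mx) + exp(m[, 3L] - mx))
  out[!is.finite(mx)] <- mx[!is.finite(mx)]
  out
}
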