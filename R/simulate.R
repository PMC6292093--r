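# Synthetic replicate datasets with known ground truth.
#
# Generative model (deliberately identical to the observation model the
# posterior assumes): per-site B-allele frequencies drawn in a chosen MAF
# window; one diploid genotype per distinct source drawn from HWE at that
# frequency; per-sample read depth Poisson(lambda); each read carries
# allele B with probability e, 0.5 or 1 - e given the source genotype.
# Optional contamination replaces the genotype feeding one sample's reads
# at a chosen fraction of sites.

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Simulation configuration
#'
#' @param true_S True source vector; its length sets the sample count k.
#' @param L Number of sites (default 1000).
#' @param maf_window Length-2 numeric: the half-open MAF window
#'   `(min, max]` from which site frequencies are drawn; default
#'   `c(0.4, 0.5)`.
#' @param lambda Mean read depth(s): a scalar broadcast to all k samples,
#'   or one value per sample for unequal-depth designs. Default 3.
#' @param error_rate Per-read error rate in (0, 0.5); default 0.01.
#' @param contamination Optional `list(sample = <index>, p = <fraction>)`:
#'   at `round(p * L)` sites (half-up rounding), reads of that sample come
#'   from an independently drawn HWE genotype instead of its source.
#' @param seed Integer seed; the whole simulated dataset is a pure function
#'   of (config, seed). `NULL` uses the current RNG stream.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(true_S, L = 1000, maf_window = c(0.4, 0.5),
                       lambda = 3, error_rate = 0.01,
                       contamination = NULL, seed = NULL) {
  true_S <- validate_source_vector(true_S)
  k <- length(true_S)
  L <- assert_count(L, "L")
  if (length(maf_window) != 2L || maf_window[1] < 0 ||
      maf_window[1] >= maf_window[2] || maf_window[2] > 0.5) {
    stop("`maf_window` must be c(min, max) with 0 <= min < max <= 0.5",
         call. = FALSE)
  }
  if (length(lambda) == 1L) lambda <- rep(lambda, k)
  if (length(lambda) != k || any(lambda <= 0)) {
    stop("`lambda` must be positive, length 1 or k = ", k, call. = FALSE)
  }
  assert_error_rate(error_rate)
  if (!is.null(contamination)) {
    if (!is.list(contamination) || is.null(contamination$sample) ||
        is.null(contamination$p) ||
        contamination$sample < 1 || contamination$sample > k ||
        contamination$p < 0 || contamination$p > 1) {
      stop("`contamination` must be list(sample = index in 1..k, p in [0, 1])",
           call. = FALSE)
    }
  }
  structure(list(true_S = true_S, k = k, L = L, maf_window = maf_window,
                 lambda = lambda, error_rate = error_rate,
                 contamination = contamination,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' Draw per-site B-allele frequencies in a MAF window
#'
#' MAF is drawn uniformly from the half-open window `(min, max]`, then with
#' probability 0.5 the frequency is flipped to `1 - MAF`, so allele B is
#' equally likely to be the minor or the major allele. No site can come out
#' monomorphic.
#'
#' @param L Number of sites.
#' @param maf_window Length-2 numeric `(min, max]` with `0 <= min < max <= 0.5`.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Numeric vector of L frequencies in (0, 1).
#' @export
simulate_site_frequencies <- function(L, maf_window, seed = NULL) {
  L <- assert_count(L, "L")
  if (length(maf_window) != 2L || maf_window[1] < 0 ||
      maf_window[1] >= maf_window[2] || maf_window[2] > 0.5) {
    stop("`maf_window` must be c(min, max) with 0 <= min < max <= 0.5",
         call. = FALSE)
  }
  with_seed_maybe(seed, {
    # b - u*(b-a) with u in [0,1) lands in (a, b]: the lower edge is open
    maf <- maf_window[2] - stats::runif(L) * diff(maf_window)
    flip <- stats::runif(L) < 0.5
    ifelse(flip, 1 - maf, maf)
  })
}

#' Draw source genotypes under HWE
#'
#' One diploid genotype (0, 1 or 2 copies of allele B) per distinct source
#' label per site, i.i.d. across sites from HWE at each site's frequency.
#' Samples sharing a source label share its genotype at every site by
#' construction.
#'
#' @param true_S True source vector.
#' @param freq_B Per-site B-allele frequencies (length L, in (0, 1)).
#' @param seed Optional seed.
#' @return An object of class `sim_truth`: `true_S`, `freq_B`,
#'   `source_genotypes` (L x n_sources integer matrix), `contamination`
#'   (`NULL` until [inject_contamination()]), `seed`.
#' @export
simulate_source_genotypes <- function(true_S, freq_B, seed = NULL) {
  true_S <- validate_source_vector(true_S)
  assert_freq(freq_B)
  L <- length(freq_B)
  n_src <- max(true_S)
  genotypes <- with_seed_maybe(seed, {
    # sum of two independent allele draws = HWE genotype
    matrix(stats::rbinom(L * n_src, 1L, freq_B) +
             stats::rbinom(L * n_src, 1L, freq_B),
           nrow = L, ncol = n_src)
  })
  structure(list(true_S = true_S, freq_B = freq_B,
                 source_genotypes = genotypes,
                 contamination = NULL,
                 seed = seed),
            class = "sim_truth")
}

#' Contaminate one sample at a fraction of sites
#'
#' Picks `round(p * L)` sites uniformly without replacement (half-up
#' rounding, so `p = 0.5, L = 1000` contaminates exactly 500 sites). At
#' those sites the chosen sample's reads derive from an independently drawn
#' HWE genotype (a second genotype source) instead of its true source. The
#' mask and contaminant genotypes are recorded in the returned truth.
#'
#' @param truth A `sim_truth`.
#' @param sample_index Sample to contaminate, in `1..k`.
#' @param p Fraction of sites contaminated, in `[0, 1]`.
#' @param seed Optional seed.
#' @return The updated `sim_truth`.
#' @export
inject_contamination <- function(truth, sample_index, p, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  k <- length(truth$true_S)
  if (length(sample_index) != 1L || sample_index < 1 || sample_index > k) {
    stop("`sample_index` must be in 1..", k, call. = FALSE)
  }
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  L <- length(truth$freq_B)
  n_cont <- floor(p * L + 0.5) # half-up, not banker's
  with_seed_maybe(seed, {
    sites <- sort(sample.int(L, n_cont))
    mask <- logical(L)
    mask[sites] <- TRUE
    genotypes <- integer(L)
    genotypes[sites] <- stats::rbinom(n_cont, 1L, truth$freq_B[sites]) +
      stats::rbinom(n_cont, 1L, truth$freq_B[sites])
    truth$contamination <- list(sample = as.integer(sample_index),
                                p = p, mask = mask, genotypes = genotypes)
  })
  truth
}

#' Simulate allelic depths from a simulation truth
#'
#' Per sample d and site v: depth `Y ~ Poisson(lambda_d)`; `n_B ~
#' Binomial(Y, p_B(g))` with `p_B` equal to `e`, 0.5, or `1 - e` for the
#' genotype feeding that sample at that site (its source genotype, or the
#' contaminant genotype at contaminated sites); `n_A = Y - n_B`. Zero
#' depths are retained — the posterior treats them as likelihood 1.
#'
#' @param truth A `sim_truth`.
#' @param config A [sim_config()] supplying `lambda` and `error_rate`
#'   (its `true_S` must match the truth's).
#' @param sample_ids Optional sample names; default `sample_1..sample_k`.
#' @param seed Optional seed.
#' @return A [replicate_dataset()]. Simulated sites are placed on one
#'   chromosome at 20 kb spacing so downstream distance filters hold
#'   trivially.
#' @export
simulate_allele_depths <- function(truth, config, sample_ids = NULL,
                                   seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  if (!identical(truth$true_S, config$true_S)) {
    stop("`truth` and `config` disagree on the true source vector", call. = FALSE)
  }
  k <- config$k
  L <- length(truth$freq_B)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(k))
  pB <- p_B_given_genotype(config$error_rate)
  n_A <- matrix(0L, L, k)
  n_B <- matrix(0L, L, k)
  with_seed_maybe(seed, {
    for (d in seq_len(k)) {
      g <- truth$source_genotypes[, truth$true_S[d]]
      cont <- truth$contamination
      if (!is.null(cont) && cont$sample == d) {
        g[cont$mask] <- cont$genotypes[cont$mask]
      }
      depth <- stats::rpois(L, config$lambda[d])
      b <- stats::rbinom(L, depth, pB[g + 1L])
      n_A[, d] <- depth - b
      n_B[, d] <- b
    }
  })
  replicate_dataset(sample_ids = sample_ids,
                    chrom = rep("sim_1", L),
                    pos = seq_len(L) * 20000L,
                    freq_B = truth$freq_B,
                    n_A = n_A, n_B = n_B,
                    error_rate = config$error_rate)
}

#' Simulate a complete replicate dataset with ground truth
#'
#' Convenience wrapper: draws frequencies, source genotypes, optional
#' contamination, and allelic depths from one [sim_config()]. With a
#' non-`NULL` `config$seed` the output is bit-reproducible.
#'
#' @param config A [sim_config()].
#' @param sample_ids Optional sample names.
#' @return `list(dataset = <replicate_dataset>, truth = <sim_truth>)`.
#' @export
simulate_replicates <- function(config, sample_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_maybe(config$seed, {
    freqs <- simulate_site_frequencies(config$L, config$maf_window)
    truth <- simulate_source_genotypes(config$true_S, freqs)
    if (!is.null(config$contamination)) {
      truth <- inject_contamination(truth, config$contamination$sample,
                                    config$contamination$p)
    }
    truth$seed <- config$seed
    dataset <- simulate_allele_depths(truth, config, sample_ids = sample_ids)
    list(dataset = dataset, truth = truth)
  })
}
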