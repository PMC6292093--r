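# Independent oracles used to cross-check the implementation.

# Brute-force set-partition enumerator, independent of the restricted-growth
# encoding: builds partitions as lists of blocks by inserting one element at
# a time into every existing block or a new one.
oracle_partitions <- function(k) {
  parts <- list(list())
  for (el in seq_len(k)) {
    parts <- unlist(lapply(parts, function(p) {
      grown <- lapply(seq_along(p), function(i) {
        p[[i]] <- c(p[[i]], el)
        p
      })
      c(grown, list(c(p, list(el))))
    }), recursive = FALSE)
  }
  parts
}

# Convert a block partition to the canonical label string "1,2,1,..." by
# labeling blocks in order of their smallest element.
oracle_partition_labels <- function(p, k) {
  ord <- order(vapply(p, min, numeric(1)))
  labels <- integer(k)
  for (i in seq_along(ord)) labels[p[[ord[i]]]] <- i
  paste(labels, collapse = ",")
}

# Naive site likelihood: the printed sum over all 3^k genotype vectors,
# with the consistency rule and HWE prior written out directly.
oracle_site_log_likelihood <- function(n_A, n_B, freq_B, S, e) {
  k <- length(S)
  G_all <- as.matrix(expand.grid(rep(list(0:2), k)))
  pB <- c(e, 0.5, 1 - e)
  hwe <- c((1 - freq_B)^2, 2 * freq_B * (1 - freq_B), freq_B^2)
  total <- 0
  for (i in seq_len(nrow(G_all))) {
    g <- G_all[i, ]
    consistent <- all(vapply(unique(S), function(lab) {
      length(unique(g[S == lab])) == 1L
    }, logical(1)))
    if (!consistent) next
    prior <- prod(vapply(unique(S), function(lab) {
      hwe[g[which(S == lab)[1L]] + 1L]
    }, numeric(1)))
    lik <- prod(stats::dbinom(n_B, n_A + n_B, pB[g + 1L]))
    total <- total + prior * lik
  }
  log(total)
}

# Random small-count dataset for property tests (runs in the caller's RNG
# stream; wrap in withr::with_seed at the call site).
random_dataset <- function(k, L, max_count = 4L, error_rate = 0.01) {
  freq <- stats::runif(L, 0.05, 0.95)
  n_A <- matrix(sample(0:max_count, L * k, replace = TRUE), L, k)
  n_B <- matrix(sample(0:max_count, L * k, replace = TRUE), L, k)
  replicate_dataset(sample_ids = paste0("s", seq_len(k)),
                    chrom = rep("chr1", L), pos = seq_len(L) * 25000L,
                    freq_B = freq, n_A = n_A, n_B = n_B,
                    error_rate = error_rate)
}
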