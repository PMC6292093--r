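---
title: "Verifying sequencing replicates from allelic depths: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying sequencing replicates from allelic depths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replicheck)
```

# The inference problem

Suppose k sequence runs are recorded as replicates of one individual. The
question "are they really?" has more than yes/no answers when k > 2: with
three runs, samples 1 and 3 may match while 2 is foreign. `replicheck`
treats the full set of answers — the partitions of the k samples into
identical-genotype groups — as the hypothesis space and computes a posterior
over all of them jointly. Partitions are encoded as restricted-growth
**source vectors**: element d is the source index of sample d, the first
element is 1, and each element exceeds the running maximum by at most one.
This encoding gives each partition exactly one representative, and the
hypothesis count is the Bell number of k (5 for k = 3, 4140 for k = 8).
Because that count grows super-exponentially, `enumerate_source_vectors()`
refuses k > 8, and the command-line interface warns at k = 8; for larger
sets, verify subsets of at most 7 and then re-verify the merged survivors.

# Model and assumptions

Three assumptions: the species is diploid, every analyzed site is
biallelic, and sites are independent. Independence is approximated in
practice by the minimum inter-site distance filter (default 20 kb);
linkage-disequilibrium pruning beyond that is left to upstream tools.

**Observation model.** At site v with alleles A (REF) and B (ALT), the
allelic depth of sample d is a pair of read counts. Conditional on the
genotype g (0, 1, 2 copies of B) and the per-read error rate e, the B
count is binomial with success probability e, 0.5, or 1 − e. The binomial
coefficient is included in the likelihood: it cancels between hypotheses
but keeps per-site values interpretable as probabilities (a deliberate
choice — dropping it would change no posterior).

**Genotype prior.** Given a source vector S, samples sharing a source must
share a genotype; the shared genotype of each source follows Hardy-Weinberg
proportions at the site's population B-allele frequency, and distinct
sources are independent. Genotype vectors violating the sharing rule have
prior exactly zero. These priors sum to one over all 3^k genotype vectors
for any S, which the test suite checks.

**Posterior.** Summing genotypes out of the joint gives the site
likelihood P(X|S); the product across sites and a uniform prior over source
vectors give the posterior. Ratios of posteriors therefore equal ratios of
likelihoods; `posterior_odds()` exposes this. A non-uniform prior is
accepted for sensitivity analyses but is not the default behavior.

**Key computational identity.** The printed marginalization is a sum over
3^k genotype vectors, but the prior factorizes by source group, so the sum
collapses to a per-group sum over only three genotypes:
cost Bell(k)·k·3 per site instead of Bell(k)·3^k. The naive sum is kept in
the test suite as an independent oracle, and the two routes are required to
agree to 1e-10 relative tolerance on random sites for k = 2..4.

# Parameters that matter

* **e, sequencing error rate** (unitless per-read probability, default
  0.01). e = 0 is rejected at validation: it would assign zero likelihood
  to any genotype contradicted by a single read and collapse the posterior
  onto artifacts. The default matches common short-read error magnitudes.
* **L, number of sites** (default 1000). Accuracy saturates quickly in L;
  mean depth matters more. The site-count sweep driver (`run_L_sweep()`)
  reproduces this.
* **MAF window** (half-open `(min, max]`, default `(0.4, 0.5]`).
  Low-frequency sites carry almost no information for separating sources:
  with rare B, every source is probably AA, and the no-error partition is
  favored a priori (for a site with frequency 0.1 and k = 3, the all-AA
  genotype vector has prior 0.81 under the one-source partition but at most
  0.81² under any split). High-MAF windows are therefore strongly
  recommended.
* **minimum inter-site distance** (bp, default 20000): supports the
  independence assumption.
* **threshold** (posterior probability, default 0.99): the single decision
  the user makes. Ties at the maximum yield no call, because tied
  partitions are indistinguishable given the data.

Zero-depth samples at a site contribute likelihood one. The default site
sampler excludes sites lacking a read in every replicate
(`require_read_each = TRUE`), but the math stays total, so datasets built
by other routes — including the simulator's unconditioned Poisson depths —
are handled without special cases.

# What the simulator emulates, and what it does not

`simulate_replicates()` generates the stated world of the simulation
experiments: per-site B-allele frequencies uniform in a chosen MAF window
(flipped to the major allele with probability 0.5), one HWE genotype per
distinct source per site, per-sample depths Poisson(λ), and reads drawn
from the feeding genotype with the same error model the likelihood assumes.
Contamination replaces the genotype feeding one sample's reads at
`round(p·L)` sites (half-up rounding; R's banker's `round()` is avoided)
with an independently drawn genotype.

Two deliberate departures from data-backed simulation. First, genotypes are
HWE draws at the *same* frequencies the inference sees, rather than
resampled reads from real individuals scored against panel-estimated
frequencies. Consequence: the pathology where low-MAF sites become
monomorphic in the evaluation subset — which depresses low-MAF accuracy on
real panels — is not reproduced here, and low-MAF cells perform somewhat
better than they would in the field. A green simulation test therefore
establishes internal consistency of model and inference, not robustness to
frequency misestimation. Second, depths are Poisson, i.e. reads uniform
across sites; real reduced-representation data are more dispersed, which
the experiment drivers do not model.

The generator is deterministic given `(config, seed)`; the experiment
drivers seed once per call and run cells sequentially, so whole tables are
reproducible from one integer.

The contamination-sensitivity driver defaults to the `(0.4, 0.5]` MAF
window — the same default as real-data inference — since the original
experiment description leaves the window unspecified.

# Numerical choices

* All likelihood math is in log space; products over 1000 sites underflow
  double precision in linear space. Posterior normalization uses max-shift
  log-sum-exp; the per-site three-genotype marginalization uses a row-wise
  log-sum-exp guarded against all-`-Inf` rows.
* Monomorphic frequencies (0 or 1) are rejected, not epsilon-floored: an
  invalid site should fail loudly at validation, not be silently bent into
  the model's domain. The site sampler excludes such sites upstream.
* The accuracy-grid drivers simulate one representative source vector per
  partition *shape* (e.g. `(1,1,2)` for the 2+1 shape of k = 3): accuracy
  depends only on the shape, and the posterior test suite verifies the
  underlying permutation equivariance exactly (permuting samples permutes
  posterior mass).
* Greedy seeded acceptance implements the distance constraint in site
  sampling: candidates are visited in a seeded random order and accepted if
  far enough from all previously accepted sites on the chromosome. This is
  reproducible and order-free in expectation; it does not guarantee the
  maximum-cardinality site set, which is irrelevant when candidates are
  plentiful.
* Allele B is bound to the VCF ALT allele, and `freq_B` is the ALT
  frequency. The model is symmetric in the alleles, so the convention is
  harmless if applied consistently; the panel estimator and the frequency
  table reader both follow it.
* Panel allele frequencies are pooled read counts (`sum n_B / sum depth`)
  across panel samples — depth-weighted and call-free, consistent with the
  package's refusal to call genotypes anywhere. Dosage-based estimators are
  out of scope.

# Known limitations

* Diploid, biallelic SNPs only; no polyploid or multiallelic models, no
  per-base quality weighting, no haplotype phasing or imputation.
* Population structure violates the single-frequency HWE prior; analyze
  subpopulations separately with subpopulation frequencies.
* The uniform prior over partitions is a modeling convenience, not an
  empirical claim about error rates; with strong prior knowledge of label
  integrity, supply a prior, but interpret the threshold accordingly.
* k > 7 is computationally inadvisable and k > 8 unsupported.
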