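# replicheck

Bayesian verification of sequencing replicate identity from allelic depths.

## The problem

Individuals are often sequenced more than once — technical re-runs of the
same DNA, biological re-sampling of the same plant or animal, or accidental
duplicates from naming inconsistencies. Before merging those records, you
need to know that no mix-up or contamination occurred. At the shallow mean
depths typical of genotyping-by-sequencing (~1–6x), the standard
pairwise tools (identity-by-state, correlation of imputed dosages,
relationship-matrix heat maps) are unreliable: they require genotype
calling, imputation, or phasing, and pairwise verdicts can be mutually
inconsistent when more than two replicates exist.

`replicheck` instead analyzes the k putative replicates of one individual
*jointly* and works directly on raw allelic read counts. It is aimed at
breeding programs and any group managing replicated sequencing of known
individuals.

## The model

Every way the k samples can be related is a **source vector** `S`: a
partition of the samples into identical-genotype groups, written in
restricted-growth form (`(1,1,1)` = all replicates; `(1,2,1)` = samples 1
and 3 share a source; ...). There are Bell(k) of them — 5 for k = 3,
4140 for k = 8, which is the hard cap.

At each of L biallelic sites v, the allelic depth of sample d is
`X_d = (n_A, n_B)` and the genotype likelihood is binomial,

    P(X_d | g, e) = C(n_A + n_B, n_B) (1 - p_B)^{n_A} p_B^{n_B},
    p_B = e (g = AA), 0.5 (g = AB), 1 - e (g = BB),

with a symmetric per-read error rate `e` (default 0.01). Genotype vectors
get a Hardy-Weinberg prior at the user-supplied population allele
frequency, with samples sharing a source treated as one observation and
distinct sources independent; inconsistent genotype vectors have prior
zero. Summing genotypes out gives `P(X^(v) | S)`; multiplying over sites
(assumed independent, helped by a minimum inter-site distance, default
20 kb) and normalizing under a uniform prior on `S` gives the posterior

    P(S | X) = P(X | S) / sum_S' P(X | S').

A source vector is *called* when its posterior reaches a threshold
(default 0.99); otherwise the full distribution is reported. The
**non-replicate rate** is `1 - P(all-ones S | X)`.

## Worked example

The package ships a small synthetic VCF (three putative replicates
`rep1..rep3` simulated so that rep1 and rep3 share a genotype source, plus
panel samples) and a matching frequency table:

```r
library(replicheck)
vcf <- system.file("extdata", "synthetic_example.vcf", package = "replicheck")
ft  <- system.file("extdata", "synthetic_example_freqs.tsv", package = "replicheck")

catalog <- read_allele_depths(vcf, c("rep1", "rep2", "rep3"))
catalog <- attach_frequencies(catalog, read_frequency_table(ft))
cfg  <- sampling_config(L = 35, maf_min = 0.3, maf_max = 0.5,
                        min_distance = 0, seed = 1)
data <- sample_sites(catalog, cfg, c("rep1", "rep2", "rep3"))
res  <- joint_posterior(data)
res
#> posterior over source vectors (k = 3, L = 35 sites)
#>   (1,2,1)  posterior = 1.000000
#>   (1,2,3)  posterior = 0.000000
#>   (1,1,2)  posterior = 0.000000
#>   (1,1,1)  posterior = 0.000000
#>   (1,2,2)  posterior = 0.000000
#> called: (1,2,1)
head(as.data.frame(res), 3)
#>   source_vector log_likelihood posterior
#> 3         1,2,1         -142.8 1.000e+00
#> 5         1,2,3         -160.7 1.647e-08
#> 2         1,1,2         -174.0 2.787e-14
non_replicate_rate(res)
#> [1] 1
```

The call `(1,2,1)` says sample 2 does **not** share the genotype source of
samples 1 and 3 — exactly the planted truth — and the non-replicate rate of
1 flags the trio as containing an error. With a panel instead of a
frequency table, replace `attach_frequencies()` with
`estimate_allele_frequencies(catalog, panel_ids)` (pooled read counts, no
genotype calls).

Synthetic studies with known truth:

```r
sim <- simulate_replicates(sim_config(c(1, 2, 1), L = 1000,
                                      maf_window = c(0.4, 0.5),
                                      lambda = 3, seed = 42))
joint_posterior(sim$dataset)                   # recovers (1,2,1)
grid <- run_accuracy_grid(k = 3, reps = 25, seed = 1)
summarize_experiment(grid)                     # median accuracy per cell
```

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "replicheck.R", package = "replicheck"))') \
  infer --vcf my.vcf --samples rep1,rep2,rep3 --panel-samples p1,p2,p3 \
  --L 1000 --maf-min 0.4 --maf-max 0.5 --min-distance 20000 --seed 1 \
  --out-prefix out
```

writes `out.report.json` and `out.posterior.tsv`; exit code 0 means a
source vector was called, 2 means no call (distribution still written).
Other subcommands: `simulate` (dataset + truth JSON) and `experiment`
(`accuracy-grid`, `l-sweep`, `sensitivity`, `unequal-depths`).

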