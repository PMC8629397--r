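---
title: "Estimating repeat spectra and genome length from genome skims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating repeat spectra and genome length from genome skims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skimspect)
```

## The problem

A genome skim is shotgun sequencing at a coverage (0.2-4x) far too low for
assembly. The only genome-wide summary such data support is the k-mer count
histogram `o`, where `o_h` is the number of distinct k-mers observed exactly
`h` times in the reads. skimspect inverts this histogram into estimates of

* the **k-mer repeat spectrum** `r`, where `r_j` counts the distinct k-mers
  occurring exactly `j` times in the (unobserved) genome,
* the **genome length** `L = k - 1 + sum_j j r_j`,
* the **sequence coverage** `c` and **per-base error rate** `eps`.

## The generative model

Reads of length `l` start at Poisson-distributed positions with mean depth
`c` per bp, so each genomic position is covered by
`lambda = (1 - (k-1)/l) c` read k-mers on average. With substitution errors
at rate `eps` per base, a sequenced k-mer is error-free with probability
`(1-eps)^k`; erroneous k-mers are assumed novel, each observed once.
Defining the error-free k-mer coverage `lambda_ef = lambda (1-eps)^k`, a
k-mer with genomic copy number `j` is observed `Poisson(j lambda_ef)` times.
In expectation,

    E[O_h] = sum_j P_hj r_j + [h = 1] E,
    P_hj   = exp(-j lambda_ef) (j lambda_ef)^h / h!,
    E      = L lambda (1 - (1-eps)^k),

and the estimation problem is to minimise a weighted p-norm of
`E[O] - o` over `(r, lambda, eps)`. Throughout, the package uses the
weights `w = [0, 1, 1, ...]` and `p = 1`: the singleton bin is excluded
because it is dominated by erroneous k-mers, and is instead used to
estimate `eps`.

## Why the inversion is hard

The mixture matrix `P` is severely ill-conditioned: at `lambda_ef = 1` its
condition number is at least `2^n/n` for `n` copy-number classes
(`condition_number()` verifies this numerically). Unconstrained non-negative
least squares (`estimate_ls()`) therefore recovers `r_1` well but collapses
most higher `r_j` to zero. Regularisation is no remedy, because the true
spectrum is not sparse.

## Constrained estimation

The package stabilises the inversion exactly the way the consecutive
spectral ratios of real genomes suggest: `r_j / r_{j+1}` is tightly
predictable from the spectral index `u_j = r_j / sum_{i>=j} r_i`.

1. **Ratio-constrained LP** (`estimate_lp()`). The L1 objective over bins
   `h >= 2` is minimised subject to `L_j <= r_j/r_{j+1} <= U_j`, where
   `[L_j, U_j]` is the empirical support of the ratio over a training
   corpus of assemblies (`fit_ratio_bounds()`). The absolute values are
   linearised with one auxiliary variable per bin, the ratio constraints
   are multiplied through by `r_{j+1}`, and the LP is solved with the GLPK
   simplex through a small compiled shim. Residual rows are scaled by
   `max(o)` and matrix entries below `1e-14` are dropped; the Poisson tails
   otherwise reach `1e-70` and break the solver's arithmetic. Because no
   single simplex configuration is reliable on these near-degenerate
   systems, the solver cascades scaled/unscaled primal and then dual
   simplex.
2. **Spline correction** (`estimate_slp()`). Gamma-family generalized
   additive models (one per `j = 1..5`, fitted with `mgcv`, smoothness by
   GCV; log link for `j = 1, 2` to absorb the dynamic range, identity for
   `j = 3..5`) predict the ratio `y_j` from `u_j`. The head of the LP
   solution is then rewritten recursively:
   `r_1` kept, `r_j = r_{j-1} / y_{j-1}` for `j = 2..6`, LP values beyond.
   The splines are trained by pairing assembly-true ratios with
   **LP-estimated** indices from simulated skims
   (`spline_training_pairs()`), so they absorb the LP's systematic bias in
   `u` — training them on true indices measurably displaces the annealing
   objective's minimum.
3. **Simulated annealing over coverage** (`anneal()`). `lambda` is the only
   free scale: starting from closed-form initial estimates, each iteration
   proposes `lambda' ~ U[lambda/2, 3 lambda]`, rebuilds `P`, solves the
   inner SLP problem, and accepts with probability
   `min{1, exp((E - E')/(N - t + 1))}` (the `algorithm1` cooling variant;
   an alternative `exp(-(E'-E) t/N)` schedule is available as
   `variant = "overview"` — published descriptions of this class of
   algorithm state both, and they differ numerically, so the package
   exposes the choice). `eps` stays fixed during the loop.
4. **Finalisation** (`finalize_estimate()`). The initial `eps` is made
   under a no-repeat assumption and is biased upward for repetitive
   genomes; a linear regression of its relative error on the estimated
   uniqueness ratio `r_1/L` (learned from calibration skims at known
   `eps`) corrects it, with the relative correction capped at ±20% and
   applied only when the estimated coverage is below 1.5. Then
   `lambda <- lambda (1-eps)^k / (1-eps_corrected)^k`,
   `c = lambda l/(l-k+1)`, and `L = B/c` with `B` the total sequenced
   bases, so `L * c = B` holds exactly.

### Initialization

With `h* = argmax_{h>1} o_h` (smallest `h` on ties),

    lambda_ef = (h*+1) o_{h*+1} / o_{h*}
    lambda    = exp(-lambda_ef) lambda_ef^{h*} / h*! * o_1/o_{h*}
                + lambda_ef (1 - exp(-lambda_ef))
    eps       = 1 - (lambda_ef / lambda)^{1/k}

On an exact error-free Poisson histogram these identities return the truth;
sampling noise can push `lambda` below `lambda_ef`, in which case `eps` is
clamped to zero.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 31 | k-mer length (counting supports `k <= 32`) |
| `n` | 50 | number of copy-number classes carried in `r` |
| `m` | `round(n max(1, lambda_ef))` | histogram bins modelled; fixed for the whole run from the initial estimate (recomputing per proposal would change the objective's support mid-run) |
| `iterations` | 1000 | annealing iterations `N` |
| `drop_tol` | 1e-14 | LP matrix truncation |
| eps-correction cap | 0.20 | maximum relative correction of `eps` |
| coverage gate | 1.5 | apply the correction only below this coverage |

`lambda` proposals are floored at `1e-3` so `P` stays well defined. Observed
histogram bins beyond `m` are excluded from the objective; the excluded mass
is retained as a diagnostic on the annealing state.

## The synthetic corpus

The natural training resource for this method is a large collection of
assembled genomes; the package instead ships models trained on a synthetic
corpus (`make_training_corpus()`), and `train_models()` rebuilds everything
from user assemblies when available. The generator emulates the features
the constraints rely on:

* uniqueness ratios on a regular grid over 0.29-0.995, the span observed
  across real eukaryotic assemblies; covering the near-unique extreme
  matters, because a test genome whose first spectral ratio exceeds every
  trained bound is forced by the constraint chain into a badly distorted
  solution;
* repeat content laid down as many short elements (60-150 bp units) whose
  copy numbers follow a discrete power law on 2..300 — real spectra decay
  smoothly in `j`, and an artificial cliff at some copy number would break
  both the ratio pools and the spline domains;
* the power-law exponent shifts with repeat content (repeat-rich genomes
  have heavier tails) with only slight jitter, because the method's power
  comes from the *tightness* of the cross-genome ratio-index relation: with
  a loose relation the splines are uninformative and coverage becomes
  unidentifiable;
* per-copy divergence of 0.002 substitutions/bp, moving k-mer mass
  gradually below the nominal copy number;
* an occasional short element at 200-500 copies emulating mobile elements
  (their observed counts fall far beyond the modelled bins, as for real
  transposons).

Shipped defaults (`default_trained_models()`) use 40 genomes of 4 Mbp with
a fixed seed; the corpus scale matters because ratio supports and spline
pairs estimated from small genomes carry count noise that displaces the
annealing optimum. Calibration of the error-rate regression uses skims of
the same corpus at 1x, `eps = 0.01`, read length 100.

What the generator does **not** emulate: GC bias and non-uniform read
starts, indel errors and quality-dependent error rates, heterozygosity,
contamination, and the deep phylogenetic structure of real repeat
families. Tests passing on this corpus show that the estimator chain is
correct and self-consistent under its model assumptions, not that shipped
models transfer to any particular taxon — retrain on related assemblies
for real analyses.

## Numerical choices and degenerate inputs

* All Poisson pmf evaluation is in log space (log-gamma), exponentiated
  last; no overflow for dimensions well beyond `m, n = 1000`.
* Ratio pools for `fit_ratio_bounds()` only accept genomes with
  `r_j, r_{j+1} >= 100` (ratios of smaller counts are sampling noise);
  beyond the last well-populated pool the widest observed bound is used,
  leaving the sparsely observed spectrum tail loosely constrained.
* Spline inputs outside the training domain are clamped to its boundary
  (gamma-link extrapolation can explode); predictions are floored at a
  small positive value.
* An LP failure inside the annealing loop counts as a rejected move and is
  recorded in the trace; a failure at initialization aborts with a solver
  error.
* Zero histograms, empty count tables, reads shorter than `k`, and
  histograms without an interior mode all raise typed conditions
  (`skimspect_data_error`, `skimspect_domain_error`) rather than returning
  garbage.
* Trained models serialize to JSON with full double precision; splines are
  stored as dense prediction grids (201 points) evaluated by linear
  interpolation, so a round trip reproduces predictions exactly.

## Validation workloads

The test-suite experiments use deliberately desk-scale problem sizes: the
model-consistency check simulates a 1 Mbp repeat-free genome at 1x; the
estimator-comparison experiment uses 20 synthetic genomes of 4 Mbp at 1x
with no sequencing error and known coverage; parameter recovery uses 12
genomes of 4 Mbp spanning uniqueness 0.3-0.99, skimmed at 1x with
`eps = 0.01`, with the coverage trend checked at 0.5-4x on a subset. The
annealing runs use the default `N = 1000`. At these scales a full recovery
panel completes in minutes on a single core.

## Known limitations

* The initial error-rate estimate degrades with repeat content; the capped
  correction leaves a residual length bias of up to ~10-15% for genomes
  with uniqueness below ~0.45 (the same genomes are the hardest for the
  published method, for the same reason).
* Coverage identification rests on the learned ratio-index relation; for
  genomes far outside the training corpus's repeat structure the annealing
  objective can prefer a shifted coverage.
* Counting is exact and in-memory: practical up to a few hundred million
  k-mer instances; `k` is limited to 32 by the 2-bit packing.
* Skims below ~0.3x leave too little signal in the histogram mode for
  initialization (`insufficient coverage signal`).

## A worked example

```{r example, eval = FALSE}
g <- simulate_genome(4e6, seed = 1)
reads <- simulate_reads(g, coverage = 1, read_length = 100,
                        error_rate = 0.01, seed = 2)
h <- kmer_histogram(reads, k = 31, read_length = 100,
                    total_bases = attr(reads, "total_bases"),
                    n_reads = attr(reads, "n_reads"))
fit <- estimate_genome(h, iterations = 1000, seed = 3)
glance(fit)
autoplot(fit) # annealing trace
```
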