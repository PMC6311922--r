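---
title: "Factored miRNA similarity models: methods and design choices"
author: "fmsm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factored miRNA similarity models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmsm)
```

## The problem and the model

Curated miRNA–disease association databases are sparse binary bipartite
networks: a few percent of all disease–miRNA pairs are recorded, and the
recorded mass is strongly disproportional — a handful of intensively
studied miRNAs and diseases carry a large share of the entries. The task
this package addresses is *per-disease* biomarker prioritization: for
each disease, rank its unknown miRNAs so that true-but-unrecorded
associations surface at the top. This is a top-N recommendation problem
on implicit feedback, and the model is a factored item-similarity model
(FISM-style): instead of fixing an miRNA–miRNA similarity matrix, it
learns one as the product $PQ^\top$ of two latent factor matrices.

The score of a pair $(d, m)$ is

$$\hat r_{dm} = b_d + b_m + |S|^{-\alpha} \sum_{j \in S} p_j q_m^\top,
\qquad S = R_d^+ \setminus \{m\},$$

with $R_d^+$ the miRNAs known for $d$ in the training split. Three
conventions matter here:

* **Self-exclusion.** The pair's own entry never contributes to its own
  score: the sum runs over $R_d^+ \setminus \{m\}$, and the
  neighbourhood count is $|S|$, not $n_d^+ - 1$ blindly. For a positive
  pair the two coincide; for a negative pair of a single-association
  disease the naive count would be $0^{-\alpha}$ and singular. With the
  $|S|^{-\alpha}$ convention the score is *exactly* invariant to
  toggling $U(d,m)$ itself, which the test suite asserts.
* **Empty neighbourhoods.** When $S = \varnothing$ the sum term is 0 and
  the score reduces to the biases. A disease with no training
  associations therefore carries no neighbourhood signal at all — such
  diseases are skipped (and counted) in evaluation rather than scored.
* **$\alpha$** interpolates between averaging ($\alpha = 1$) and summing
  ($\alpha = 0$) the neighbourhood; the default is 0.5, the midpoint of
  the admissible range and the conventional choice for this model
  family. It is exposed in `fmsm_control()`.

Parameters minimize the regularized squared error over the known
associations $R$ plus a per-epoch uniform resample $A$ of $\rho |R|$
unknown pairs,

$$\tfrac12 \sum_{(d,m) \in R \cup A} (r_{dm} - \hat r_{dm})^2
+ \tfrac{\beta}{2}(\|P\|_F^2 + \|Q\|_F^2)
+ \tfrac{\lambda}{2}\textstyle\sum_d b_d^2
+ \tfrac{\gamma}{2}\textstyle\sum_m b_m^2.$$

Treating a small sample of unknowns as zeros (rather than all of them)
keeps each epoch linear in $|R|$ and is the standard implicit-feedback
device; resampling each epoch means every unknown pair is eventually
visited. Optimization is plain SGD with a fixed number of epochs and no
early stopping; a divergence guard aborts with advice to lower the
learning rate if parameters go non-finite.

### SGD update convention

The per-sample updates are the analytic gradients of the loss with
regularization applied, per sample, to the parameters that sample
touches ($q_m$, each $p_j$ with $j \in S$, $b_d$, $b_m$):

$$e = r - \hat r,\quad
b_d \mathrel{+}= \eta(e - \lambda b_d),\quad
b_m \mathrel{+}= \eta(e - \gamma b_m),$$
$$q_m \mathrel{+}= \eta\big(e\,c\,t - \beta q_m\big),\quad
p_j \mathrel{+}= \eta\big(e\,c\,q_m^{\text{old}} - \beta p_j\big),$$

with $c = |S|^{-\alpha}$ and $t = \sum_{j\in S} p_j$. Whether
regularization is charged per sample or per epoch is a genuinely open
convention for this model family; at the default weights the optima are
nearly identical, and the per-sample form keeps every update local. The
full-batch analytic gradient of the objective is implemented separately
in R (`fmsm_gradient()`) and verified against central finite differences
— and the compiled epoch is verified against a pure-R reference update —
so the two derivations cross-check each other.

All updates within an epoch use a sample order shuffled by the run RNG;
given `seed` in `fmsm_control()`, negative sampling, shuffling and hence
the fitted model are exactly reproducible, and the caller's RNG state is
left untouched.

### Initialization

$P = Q = S_m$ when the latent dimension equals the miRNA count (the
default: at these panel sizes accuracy is worth more than speed, and a
full-rank factorization estimates the similarity best). For a lower
dimension $d$, $P = Q = V_d \Lambda_d^{1/2}$ from the truncated
symmetric eigendecomposition of $S_m$ with negative eigenvalues clipped
at zero — the best rank-$d$ symmetric factorization of a PSD similarity.

## The similarity stack

* **Expression similarity** `ES`: Pearson correlation between per-miRNA
  expression vectors across tissues. Correlation lives in $[-1, 1]$ but
  the similarity scale is $[0, 1]$; the default maps negatives to 0
  ("anticorrelated" and "unrelated" both mean *not similar* for
  neighbourhood pooling), with an affine alternative $(r+1)/2$ exposed
  as `es_negative = "affine"` for users who want to preserve ordering.
  Zero-variance profiles (Pearson undefined) are flagged and treated as
  uncovered rather than failing the run.
* **Disease semantic similarity** `SS`: each disease's MeSH tree codes
  are expanded into a DAG by prefix truncation; an ancestor's
  contribution decays by $\Delta$ per generation, taking the maximum
  over child paths (so a node reachable by several paths gets the
  shortest path's weight, and a node that is both an own code and an
  ancestor keeps 1). Similarity is the shared-contribution fraction.
  $\Delta = 0.5$ by default. For multi-code diseases the DAG is the
  union of the code chains and the child set is taken within that union
  — the standard MeSH treatment.
* **GIP kernels** `KD`/`KM`: RBF kernels on the rows/columns of $U$ with
  bandwidth $\gamma = \gamma' / \overline{\|IP\|^2}$, $\gamma' = 1$.
  Because they are functions of $U$, they are recomputed on every
  training split during cross-validation.
* **Integration**: $S_m = (ES + KM)/2$ where expression covers both
  miRNAs and $KM$ elsewhere — averaging with a structurally-zero `ES`
  row would halve valid kernel values, so coverage gates the average.
  $S_d = SS$ where both diseases carry MeSH annotation, $KD$ otherwise.

All five matrices satisfy, and the suite asserts, symmetry within
`1e-9`, entries in $[0,1]$, and unit diagonal on covered entities.

## Evaluation protocol

Scoring is local: a held-out association $(d, m)$ is ranked only against
the candidates of its own disease — $m$ plus every miRNA with no known
association to $d$. The rank uses average ties. Each test sample's
normalized rank $(r-1)/(n-1)$ is pooled across samples; the ROC curve
plots the fraction of test samples above each percentile threshold
against the threshold itself, and the area equals the mean per-sample
percentile $(n-r)/(n-1)$. For a single candidate pool this is exactly
the Wilcoxon–Mann–Whitney statistic of the positive against its
negatives, which the tests verify to $10^{-10}$ against a brute-force
pairwise count. Ranking against *negatives only* (co-held-out positives
of the same disease are excluded from the pool in k-fold) keeps that
equivalence exact.

Leave-one-out retrains the model for every held-out pair with kernels
recomputed on the reduced matrix; expression and semantic similarities
do not depend on $U$ and are computed once and cached across folds.
Repeated k-fold shuffles the associations into $k$ disjoint folds,
pools each repeat's held-out rankings into one AUC, and reports
mean ± sd over repeats. Per-fold fit seeds are derived from the base
seed and the smallest held-out pair index, so `k = |R|` with one repeat
reproduces leave-one-out bit for bit. Fold computations are built
entirely from the training *pair list* — never from the full matrix's
values — so corrupting held-out entries of $U$ cannot change fold
results (asserted bitwise in the tests).

The ablation experiment swaps only the miRNA-similarity input — identity
(no extra similarity), expression only (identity where uncovered), or
expression integrated with the GIP kernel — keeping the disease side
fixed, to show the incremental value of each source.

## The synthetic generator

`simulate_mda()` emulates the joint structure the model exploits, at
configurable scale:

* diseases and miRNAs fall into latent **blocks**; 90% of association
  probability mass lies on matched blocks;
* **popularity**: per-miRNA and per-disease lognormal weights
  (`popularity_sd = 1.1`) multiply the block weights. Curated databases
  are heavily disproportional; 1.1 reproduces a max/mean degree ratio of
  roughly 14, matching the benchmark-scale network this generator
  mirrors (383 diseases × 495 miRNAs × 5430 entries, density 2.86%);
* **expression**: per-block centroids over 172 tissues plus Gaussian
  noise (sd 0.5), so same-block miRNAs correlate strongly (about 0.8)
  and cross-block pairs do not; 80% of miRNAs are covered;
* **MeSH**: same-block diseases share a two-component code prefix; 90%
  of diseases are covered;
* **ground truth**: further pairs drawn from the same weighted process,
  disjoint from the observed set, for recovery checks.

What it does *not* emulate: real miRNA nomenclature, the true MeSH
vocabulary, family/cluster substructure within blocks, study-driven
reporting biases correlated between expression and associations, or the
real benchmark's degree of similarity-network informativeness. Passing
tests on this generator show the pipeline is correct and that each
similarity source adds signal of the planted kind; they do not certify
real-data accuracy.

A note on attainable accuracy at test scale: the recovery fixture (30
diseases × 60 miRNAs, 2 blocks, 5% density) has only 90 associations —
a mean miRNA degree of 1.5. Within a block, candidates are nearly
exchangeable, so local ranking leans on the popularity signal, which at
degree 1.5 is barely estimable; even an oracle ranking candidates by
the true generative weights falls well short of perfect local AUC on
this fixture, and any method restricted to the observable data sits
below that. The model's LOOCV AUC of roughly 0.73–0.76 across seeds
(recomputed by the acceptance script) should be read against that
ceiling, not against benchmark-scale figures, which rest on a mean
degree near 11.

## Numerical choices and degenerate inputs

* Symmetry/diagonal/bounds tolerance for similarity validation: `1e-9`.
* Ranking ties: average rank in evaluation; lexicographic miRNA-name
  tie-break in written ranking files (deterministic output).
* Duplicate association lines collapse to one pair; names are matched
  case-insensitively after trimming (database naming drift).
* A disease whose candidate set is empty is omitted from ranking output
  with a warning; a disease with no training associations is skipped
  and counted in evaluation.
* An all-zero association matrix has no defined kernel bandwidth and
  errors; `rho = 0` trains on positives only; `eta = 0` provably leaves
  the initialization untouched.
* Input formats are plain UTF-8 TSV with `#` comments — no standard
  format exists for these data, and TSV keeps fixtures text-only and
  diffable.

## Problem sizes in the test suite

Unit tests run on panels of roughly 10–30 diseases and 15–60 miRNAs;
the end-to-end recovery, ablation and calibration checks use the
30 × 60 planted fixture described above (about 90 model retrainings per
leave-one-out pass, a few seconds with the compiled SGD epoch); a
benchmark-scale 383 × 495 fixture exercises generation and sparsity
accounting only. These sizes were chosen so the full suite gives
end-to-end coverage in well under a minute on a single core.

## Known limitations

* The model cannot score a disease with no known associated miRNAs
  (cold start); such diseases are reported, not silently dropped.
* Hyperparameters are taken as fixed defaults rather than tuned per
  dataset; no early stopping is provided.
* Negative sampling treats unknown pairs as zeros; truly associated but
  unrecorded pairs are occasionally sampled as negatives, which is
  inherent to the implicit-feedback formulation.
* Only plain SGD is implemented — no adaptive optimizers, no ranking
  losses, no GPU path.
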