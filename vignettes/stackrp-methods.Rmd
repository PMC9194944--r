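---
title: "Methods: energy-profile features and stacked classification of plant R proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: energy-profile features and stacked classification of plant R proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stackrp)
```

This vignette is the package's account of its model and the choices made
where the design was genuinely open. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## The model

A plant R-protein classifier has to work at low sequence similarity, so
the pipeline encodes physicochemistry instead of homology. The encoding
is a fixed 20×20 residue pairwise contact-energy table (symmetric,
dimensionless, fitted by least squares to known structures in prior
work; exposed by `recm_table()`). A sequence of length $L$ becomes the
profile $P \in \mathbb{R}^{L \times 20}$ with $P_{i\cdot}$ the table row
of residue $i$ — the analogue of a PSSM with energies in place of
log-odds. The table ships as a code constant; its symmetry and fidelity
to the printed source are asserted by the test suite over all 400 cells.

Two feature blocks summarise $P$:

**Wavelet block (1040).** Every profile column is a 1-D signal
decomposed by the cascaded two-channel filter bank
$y_{\mathrm{low}}[n] = \sum_k x[k]\, g[2n-k]$,
$y_{\mathrm{high}}[n] = \sum_k x[k]\, h[2n-k]$, re-decomposing the
approximation band at each level. Per level we keep the max, min, mean
and population standard deviation of both bands plus the first five
DCT-II coefficients of the approximation band (the low band carries most
of the signal; the DCT compacts it further): $4+4+5 = 13$ features per
level, 52 per column at the default 4 levels, 1040 per sequence.

**Pseudo-positional block ($20 + 20\lambda$).** Column means
$\bar P_j = \sum_i p_{ij} / L$ and, for each lag $\ell = 1..\lambda$,
$G_j^{\ell} = \sum_{i=1}^{L-\ell} (p_{ij} - p_{i+\ell,j})^2 / (L-\ell)$
— the mean squared difference of entries $\ell$ apart, a non-negative
sequence-order statistic that a bag-of-residues encoding cannot see.

**Selection.** The pooled $1040 + 120$ features are z-scored and ranked
by kernel SVM-RFE: per round, an RBF SVM ($C = 16$, $\gamma = 0.0078$) is
trained on the survivors and each feature $i$ is scored by
$J_i = \tfrac12 \alpha^\top K \alpha - \tfrac12 \alpha^\top K^{(-i)}
\alpha$ with the dual variables held fixed and $K^{(-i)}$ the kernel
recomputed without that feature (for an RBF kernel,
$K^{(-i)} = K \odot e^{\gamma d_i}$, computed in compiled code).
Correlation bias reduction then groups survivors with $|r| \ge R_{th} =
0.9$ by single linkage and assigns each group its maximum score, so
near-duplicate informative features are not eliminated one by one while
their group survives. Half of the survivors are dropped per round until
$4k$ remain, then one per round; the default retains $k = 112$.

**Classifier.** Six base learners (KNN $k=5$; depth-wise boosted trees,
depth 3, learning rate 0.1; RBF SVM; XGBoost defaults; leaf-wise
histogram boosting capped at 31 leaves; random forest, 500 trees)
produce out-of-fold positive-class probabilities under stratified
5-fold assignment; the $n \times 6$ matrix trains an RBF-SVM
meta-classifier with Platt probability outputs. Out-of-fold construction
means no base model ever scores its own training sample, so the
meta-layer learns the members' generalisation behaviour, not their
training fit. Classification thresholds the meta probability at 0.5.

## Choices made where the source was open

* **Level count.** The feature-count arithmetic ($13$ per level,
  $52$ per column, $1040$ total) pins the decomposition at 4 levels;
  the level count remains configurable.
* **Wavelet family.** Unspecified upstream; default `db4` (8-tap
  Daubechies) with whole-sample symmetric extension. The filter bank was
  cross-validated against an independent reference implementation and
  those coefficients are frozen into the unit tests; `haar` and `db2`
  are available, and periodic extension is provided (it preserves energy
  for orthogonal families, which the Parseval test exploits).
* **"First five discrete cosine coefficients."** Read as DCT-II of the
  approximation band (the phrase forces a cosine transform); the
  alternative reading — the band's first five elements — is available
  via `dct_mode = "truncate"`.
* **$\lambda$.** Unstated upstream; default 5, giving the 1160-feature
  pool. Sequences with $L \le \lambda$ are rejected.
* **RFE criterion and CBR rule.** The elimination criterion and the
  exact correction formula are not printed in the source description;
  the standard dual-objective criterion and a group-max correction are
  used, both stated above and configurable ($R_{th}$, `use_cbr`).
* **Elimination threshold.** Unstated; default $4k$ so the rounds near
  the retained subset are one-at-a-time.
* **Standardization.** Not mentioned upstream but necessary for a fixed
  $\gamma = 0.0078$ kernel on energy-scale features; z-score parameters
  are stored in the model and re-applied at prediction time.
* **Meta-features.** Probabilities rather than hard labels: they
  preserve the ranking information the AUC needs.
* **Grids.** `base_layer_spec("paper")` constructs the full published
  search ranges (trees 100–1000 step 25; SVM $C = 2^{-5..15}$ step
  $2^2$, $\gamma = 2^{-15..15}$ exponent step 1; leaf-wise depth 1–25
  and learning rate 0.1–0.8 step 0.01). The default is a small "fast"
  grid, and the default pipeline does not tune at all (`tune = FALSE`):
  the leaf-wise grid alone has ~65,000 points, which is not a desk-scale
  protocol. `tune_base()` implements and tests the search itself.
* **Boosted-tree engines.** All three boosted members run on the xgboost
  engine with member-specific growth policies (depth-wise shallow trees;
  regularised defaults; histogram + leaf-wise `lossguide` growth). They
  are three genuinely different inductive biases, which is what the
  meta-layer needs.
* **Class imbalance.** The 1:2 balance is handled without weights or
  resampling, matching the upstream protocol.

## Numerical conventions

Band statistics use the population standard deviation so a length-1 band
yields 0 rather than `NaN`. DCT outputs use the unnormalised type-II
convention; bands shorter than 5 are zero-padded only inside the DCT
step. The minimum sequence length is filter-length dependent (7 residues
for `db4` symmetric); shorter sequences raise an error naming the
minimum rather than being silently padded. Undefined evaluation ratios
(e.g. precision with no positive predictions) are reported as `NA` and
flagged, never coerced to 0. AUC uses trapezoids over tie-grouped curve
steps, equal to the Mann–Whitney statistic with half credit for ties.
RFE tie-breaks are by column index, making rankings bit-reproducible.

## What the synthetic generator emulates — and what it does not

`generate_sequences()` draws negatives from a uniform residue
composition and positives from a mixture shifted (by signal strength
$s$) toward a composition boosting L, N, K, I — echoing the
leucine/nucleotide-binding bias of NBS-LRR domains — plus a soft motif
whose per-position fidelity is $s$, inserted at a random position. At
$s = 0$ the classes are identically distributed by construction, which
is what makes the chance-level cross-validation check meaningful.

It is *not* a realistic R-protein simulator: no domain architecture, no
length/composition coupling, no phylogenetic redundancy (the real
benchmark is CD-HIT-filtered at 30%), no homology structure between
train and test. Passing tests therefore demonstrate that the pipeline's
machinery is correct and leak-free — that it can learn a compositional +
positional signal and cannot learn a null — not that the published
benchmark accuracies transfer to new proteomes.

## Problem sizes used in the checks

The test suite runs the full nested protocol at $n = 300$ (signal 1)
and $n = 400$ (signal 0) with five outer folds — sizes chosen to match
the scale of the 456-protein benchmark while keeping a complete nested
run comfortable on a single CPU. The acceptance script ranks the full
1160-feature pool for 150 sequences. Smaller unit fixtures (tens of
sequences, planted-feature matrices of 50 columns) isolate individual
stages.

## Known limitations

* The published benchmark is not redistributed, so the headline
  cross-validated metrics of the original study are reproducible only if
  the user supplies those FASTA files (`crossval`/`evaluate`
  subcommands).
* KNN probabilities at $k = 5$ are coarse ($\{0, 0.2, ..., 1\}$); the
  meta-SVM compensates but per-member AUCs for the KNN column are
  step-shaped.
* `rfe_rank()` cost grows with (support vectors)² × features per round;
  at a few thousand samples the ranking stage, not the stacking, is the
  bottleneck.
* The fixed $\gamma = 0.0078$ selection kernel is meaningful because
  features are z-scored first; if standardization is disabled the
  criterion degenerates (all kernel entries ≈ 1).
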