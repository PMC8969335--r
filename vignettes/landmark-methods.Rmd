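---
title: "Splitter ensembles for presence-absence biomarker selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitter ensembles for presence-absence biomarker selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landmark)
```

## The problem

Marker-gene surveys summarize a community as a sample-by-ASV table
(amplicon sequence variants: exact denoised sequences used as biodiversity
units). These tables are sparse, compositional and very wide — thousands of
features against tens of samples — and the question is usually twofold:
can the habitat or condition of a sample be predicted from its community,
and *which* ASVs carry that signal. Axis-aligned decision forests handle
the dimensionality well but their staircase decision boundaries interact
badly with the strong feature correlations of community data. This package
implements an ensemble whose trees cut obliquely: at every node several
multivariate models compete, and the partition with the greatest
information gain wins.

## The classifier

A tree is grown recursively. At each node with $n$ samples and $d$
features:

1. **Random linear oracle (root only, by default).** Two distinct training
   samples $a, b$ are drawn without replacement; the hyperplane through
   $(a+b)/2$ with normal $b-a$ splits the node into two half-spaces that
   are then modelled independently. Points exactly on the hyperplane go to
   the positive side. The oracle injects diversity ahead of any fitted
   model; with `oracle_probability` it can be applied at any depth.
2. **Candidate splitters.** Six linear configurations are fitted: L2- and
   L1-penalized logistic regression, a linear SVM, two stochastic-gradient
   linear models (hinge or modified-Huber loss; L2 or elastic-net
   penalty), and a ridge classifier (only at nodes with more than 6
   samples). A two-branch neural network joins the pool at nodes with more
   than 32 samples. Subset-using families see a random
   `ceiling(max_features * d)` feature subset (drawn once per node and
   shared); the L1-logistic and elastic-net families always see every
   feature, mirroring the convention that sparsity-inducing penalties do
   their own selection. Each candidate is fitted on a bootstrap resample
   of the node (switchable via `use_node_bootstrap`).
3. **Hyperparameter selection.** At nodes with more than 6 samples a
   stratified five-fold cross-validated grid search picks the
   regularization strength: 20 logarithmically spaced values of $C$ in
   $[10^{-4}, 10^4]$ for the logistic families; $\{0.001, 0.01, 0.1, 1,
   10, 100\}$ for the SVC cost and the SGD penalty, with the SGD loss
   (hinge vs modified Huber) tuned in the same search; ridge penalties in
   $[10^{-3}, 10^4]$ by generalized cross-validation. The fold count drops
   to the smallest class size (minimum 2) near the $n = 7$ boundary, and
   at 6 samples or fewer the defaults $C = \alpha = 1$ apply with the SGD
   loss drawn at random. CV ties go to the first grid value.
4. **Split choice.** Every candidate partitions the *full* node; the
   partition's Shannon information gain (bits; Gini optional) is the
   selection criterion. Candidates within `gain_epsilon = 1e-9` of the
   maximum are treated as equivalent and one is chosen uniformly at
   random — this tie-break, together with the feature subsets and
   bootstraps, is what differentiates trees. A node becomes a leaf when it
   is pure, smaller than `min_samples_split = 2`, at `max_depth`, or when
   no candidate achieves positive gain. Splits are $k$-way: a splitter's
   branches are its distinct predicted labels.

The forest (default 64 trees, each on a bagging resample) averages the
per-tree leaf class distributions; labels are the arg-max with ties to the
first class in sorted order. `max_features = 0.4` is the default fraction
of node features offered to subset-using candidates — generalization in
our sweeps, like the ones the sweep harness supports
(`n_estimators` in $\{1 \dots 256\}$, `max_features` in
$\{\sqrt{d}, 0.1 \dots 0.8\}$), plateaus around 40%.

### The neural splitter

The non-linear candidate is a two-branch network sharing one input: a
dense branch of 256, 128, 64, 48 and 24 mish units with alpha dropout
(rate 0.2) after the first three layers, and a random-Fourier-features
branch projecting the input to 24 dimensions (unit Gaussian bandwidth,
fixed per node) followed by 24, 24 and 16 mish units. The concatenated
outputs feed a softmax over the node's classes. Training is categorical
cross-entropy with Adam at learning rate 0.001, batch size 32, a 90/10
train/validation split, and at most 300 epochs with early stopping
(`min_delta` $10^{-4}$, patience 40). The implementation is plain R
numerics with hand-written backpropagation: the splitter needs no
deep-learning runtime, is seed-reproducible, and serializes like every
other splitter. Because it trains a network per qualifying node it is the
most expensive candidate; the benchmark harness therefore disables it by
default (`use_nnet = FALSE` in `model_registry()`), and node gating (> 32
samples) keeps it out of small nodes entirely.

## Decision-space diagnostics

For a fitted forest, `proximity()` counts how often two samples co-occur
in a terminal leaf, divided by the number of trees; the diagonal is 1.
`proximity_to_dissimilarity()` maps proximities through
$d = \sqrt{1 - p}$, and `pcoa()` applies classical scaling
(double-centering of $-\tfrac12 D^2$ via `stats::cmdscale`). Negative
eigenvalues — possible because $\sqrt{1-p}$ need not be Euclidean — are
dropped without Lingoes/Cailliez correction and explained-variance ratios
are reported over the positive spectrum only. `kappa_error_points()`
summarizes ensemble diversity as one point per tree pair: Cohen's kappa
between the trees' hard predictions against the mean of their individual
error rates. The pair-error definition $(e_i + e_j)/2$ is the standard
one for kappa-error diagrams.

## Evaluation metrics

`balanced_accuracy()` implements the confusion-matrix variant used by the
whole harness: each diagonal count is divided by the *larger* of its row
and column sum before averaging over classes,

$$\mathrm{BA} = \frac{1}{n}\sum_i \frac{c_{ii}}
  {\max\left(\sum_j c_{ij}, \sum_j c_{ji}\right)},$$

which penalizes a class for both its misses and its over-predictions; a
constant predictor on balanced two-class data scores 0.25, not 0.5. The
common mean-recall definition is available as
`balanced_accuracy_recall()`; the two agree whenever row and column sums
match. Feature recovery is scored by the Matthews correlation coefficient
over the 2×2 table induced by a selected set, a truth set and the feature
universe, with a zero denominator mapped to 0.

## The synthetic generator

`generate_dataset()` draws a 24-control / 24-treatment presence-absence
table from per-feature baseline probabilities $p_O$. For a chosen set of
perturbed features the treatment block's presence probability is shifted
on the odds scale,

$$\log\frac{q}{1-q} = \log\frac{p_O}{1-p_O} + \log p_N,
  \qquad q = \frac{p_O\,p_N}{1 - p_O + p_O\,p_N},$$

with $p_N$ drawn per feature from
$\{0.1, 0.125, 0.25, 0.5, 2, 4, 8, 10\}$; afterwards 5% of feature
columns are permuted across all 48 samples, adding label-free noise. The
truth mask and applied multipliers are returned for recovery scoring.
Scenarios with 25, 50 and 75 perturbed features span weak to strong
signal.

Baselines can come from a real filtered table
(`estimate_baseline_probs()`, frequencies clipped to
$[1/2n, 1 - 1/2n]$ so the odds stay finite) or from the self-contained
profile `generate_baseline()`: Beta(0.5, 2.83) — skewed sparse, mean
occupancy about 0.15 — truncated below $2/24$ by inverse-CDF sampling,
because a real baseline is estimated from a table already filtered to
features present in at least two of 24 samples and can never contain
sub-floor frequencies. Controls are fresh Bernoulli draws rather than
copies of real rows, keeping the module fully self-contained; column
shuffling permutes entries across both groups jointly (the per-group
variant is a flag). What the generator does *not* emulate: read counts,
compositional closure, sequencing error, and the correlation structure of
real communities — features are independent given their occurrence
probabilities. Passing tests on generated data therefore demonstrate
correct mechanics and achievable recovery under independent Bernoulli
noise, not performance on real amplicon data.

## Biomarker workflow

`rfe_select()` performs recursive feature elimination: refit, score every
feature, drop the weakest `ceiling(step_fraction * remaining)` (default
10%, never crossing below `n_keep = 100`), repeat. Importance drivers per
family: absolute coefficients for linear models; impurity importance for
the axis-aligned forests (via ranger); for splitter ensembles, each
node's information gain weighted by the fraction of training samples
reaching the node and distributed over the node's feature subset
proportionally to absolute splitter coefficients (uniformly for oracle
and neural nodes), summed over the forest and normalized.

`shapley_importance()` provides the model-agnostic alternative: kernel-
weighted Shapley estimation with absent features imputed from a
background set. Up to 13 features every coalition is enumerated and the
attributions are exact (local accuracy holds to numerical precision);
above that, 768 coalitions per explained sample are drawn from the
Shapley kernel distribution. Importance is the mean absolute attribution
across explained samples; eliminated features are assigned exactly 0
before rank comparisons.

`half_split_consistency_experiment()` repeats (seed = iteration number):
split into stratified halves, fit and cross-score full models, run RFE
per half, refit reduced models, then compare halves by Spearman's rho on
the importance ranks and Jaccard distance on the selected sets.
`run_benchmark()` is the general harness: datasets × families × repeats,
balanced accuracy on each 80/20 stratified test split (largest-remainder
allocation of test slots; the split seed is the iteration number) plus
top-$k$ recovery MCC when ground truth is present. Both emit tidy data
frames for downstream statistics in external software; inferential tests
(Friedman/Nemenyi, repeated-measures ANOVA, PerMANOVA) are deliberately
out of scope.

## Numerical and design choices

* **Determinism.** Every stochastic step draws from seed-isolated RNG
  streams; fits, generators and harnesses are bit-reproducible given a
  seed and never touch the caller's global RNG state.
* **Logistic grids** use 20 points because the range $[10^{-4}, 10^4]$ is
  specified but not its resolution; glmnet solves the penalized fits with
  a relaxed convergence threshold ($10^{-5}$) and an iteration cap of
  2000, adequate at node sizes of tens of samples.
* **SGD classifiers** (hinge / modified-Huber / squared-hinge; L2 or
  elastic-net with mixing 0.15) are implemented in-package as shuffled
  mini-batch subgradient descent with an inverse-scaling learning rate
  $\eta_t = 1/(10 + \alpha t)$, 15 epochs inside grid searches and 60
  with early stopping for final fits. No installed R package exposes this
  family directly.
* **Degenerate inputs.** An oracle is "unavailable" when ten anchor draws
  find no distinct rows (the node falls back to model splitters alone); a
  candidate whose backend fails to fit is dropped; a bootstrap that loses
  a class is redrawn up to ten times then replaced by the full node; an
  ensemble bootstrap is redrawn once, after which a pure tree simply
  becomes a single leaf. Branch labels unseen in training route to the
  child with most training samples; an empty branch would inherit the
  parent distribution.
* **Ties.** CV ties take the first grid value; equal-gain candidates are
  drawn uniformly; arg-max label ties take the first class in sorted
  order; on-hyperplane points go to the oracle's positive side.

## Problem sizes used by the test-suite and the acceptance script

The full-scale study design (30 replicate datasets per scenario against a
real filtered baseline of thousands of ASVs, 64-tree ensembles with the
neural splitter active) is hours of single-core compute. The packaged
checks run the same code paths at sizes a laptop handles in minutes, a
choice we document here once: synthetic benchmarks use 300–400-feature
baselines with 3 replicates per scenario and 32–64-tree ensembles with
the neural splitter disabled; the non-linearity contrast uses a two-turn,
evenly spaced two-spiral draw (250 points per class, noise 0.05 — dense
enough that axis-aligned forests can track the arms) and a concentric-
ring draw (60 per class, noise 0.08) over 10 repeats, with the splitter
ensembles at 16 trees / depth 10 (spirals) and 8 trees / depth 6
(rings) — depth-capped small ensembles retain the pattern because even
single oblique trees model these boundaries well, while grow-to-purity
training on clean curved data multiplies the number of cross-validated
nodes; the ensemble-size study uses 200 features, ensemble sizes
{1, 16, 64} and six seeds. Scores under these conditions sit close to, but are not
numerically identical to, the full-scale design; the qualitative
patterns — oblique ensembles beating linear models on curved boundaries,
score and recovery rising with the number of perturbed features,
between-seed variance shrinking with ensemble size — are size-stable.

## Known limitations

* Runtime: a learned model per node makes training orders of magnitude
  slower than an axis-aligned forest; the package is aimed at tables with
  tens to hundreds of samples.
* Binary and multi-class classification only; no regression, pruning, or
  missing-value handling (inputs must be complete).
* The neural splitter's plain-SGD training is faithful to the stated
  architecture but not to any particular deep-learning framework's exact
  arithmetic.
* BIOM support is read-only and follows what `biomformat` can parse; TSV
  is the canonical round-trip format.
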