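---
title: "Methods: sparse-PCA feature selection, similarity fusion and CNN classification for drug sensitivity"
author: "DrugSensFusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse-PCA feature selection, similarity fusion and CNN classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Predicting whether a cancer sample responds to a drug from molecular
profiles is routinely framed as binary classification: IC50 values
(the concentration inhibiting 50% of growth, usually on a natural-log
scale) are thresholded into *sensitive* (label 1) and *non-sensitive*
(label 0) classes, and a classifier is trained per drug. The profiles are
multi-omics — continuous RNA-seq expression (tens of thousands of
transcripts), integer copy-number aberration (CNA) calls, and DNA
methylation fractions in [0, 1] for hundreds of thousands of CpG loci —
while the number of profiled cell lines is a few hundred. Any classifier
applied directly to the concatenated features faces severe overfitting and
gives little biological insight.

DrugSensFusion addresses both problems in three stages:

1. **Per-omics feature selection** by L0-constrained rank-1 sparse PCA,
   iteratively reweighted by random-forest Gini importance against the drug
   labels, so that the retained features span a dominant variance direction
   *and* predict sensitivity.
2. **Sample-similarity networks**: each omics block, restricted to its
   selected features, is converted into an n × n matrix of pairwise sample
   correlations (Pearson for the continuous blocks, Kendall rank
   correlation for integer CNA). This step reduces arbitrary feature
   dimensionality to n per block and makes heterogeneous blocks directly
   commensurable.
3. **Fusion and classification**: the per-omics networks are concatenated
   horizontally into an n × 3n matrix — no averaging or diffusion, so each
   block remains recoverable — and each sample's fused row is classified by
   a small one-dimensional convolutional network.

# Sparse PCA with an L0 budget

For a standardized block $X \in \mathbb{R}^{m \times n}$ (features ×
samples) the rank-1 problem is

$$\max_{u, v} \; u^\top X v \quad \text{s.t.} \quad \|u\|_2 = \|v\|_2 = 1,
\; \|u\|_0 \le s,$$

solved by alternating the $s$-sparse projection $P(Xv, s)$ (keep the $s$
largest-magnitude entries, zero the rest; ties to the lower index) with the
exact update $v \propto X^\top u$. Each half-step maximizes the objective
given the other vector, so the objective sequence is non-decreasing — a
property the test suite asserts on every matrix it touches. With $s = m$
the iteration is plain power iteration and recovers the leading singular
pair, which provides an independent oracle (`svd()`) for the solver.

Numerical choices: iteration stops when $\|u_{new}-u_{old}\|_\infty <
10^{-6}$ (cap 500 iterations); the sign is fixed by making the
largest-magnitude loading positive; an exactly zero $Xv$ aborts with a
"degenerate matrix" error rather than returning an arbitrary direction.
Features are centred and scaled to unit variance before the solve
(correlation-scale PCA); constant features receive unit scale so they pass
through as zeros rather than NaN.

# The importance feedback loop

Sparse PCA is unsupervised: it retains the features spanning the dominant
variance direction, which need not be related to the drug at all. The loop
therefore alternates:

1. rank-1 sparse PCA on the weighted matrix $\mathrm{diag}(w)\,X$;
2. a random forest on the selected features against the labels, scored by
   the **node-Gini importance**: each node that splits on feature $j$
   credits $j$ with the node's Gini index $1 - \sum_k p_{k}^2$ (class
   proportions over the node's bootstrap sample), credits are summed per
   tree, over the forest, and normalized to sum to one. This is a
   node-impurity sum, not the conventional mean *decrease* in impurity;
   the conventional score is available via `importanceMethod = "impurity"`.
3. a weight update. With $t$ the normalized importance over the support of
   size $s'$ and $g = \max(0,\, 2(\mathrm{OOB\ accuracy} - 0.5))$ the
   forest's predictive gain over chance,
   $$w_j \leftarrow w_j \cdot \big((1-\lambda) + \lambda g\big)\,
     (s' t_j)^{1-g},$$
   clipped to $[10^{-3}, 3]$, for selected features only.

The update's design resolved two failure modes we observed with simpler
rules. A rule that multiplies selected weights by a factor proportional to
$m\,t_j$ boosts *every* selected feature (normalized importance over
$s' \ll m$ features makes $m\,t_j \gg 1$ regardless of predictive value),
so the first support — informative or not — is frozen and the loop is a
no-op. A rule that damps below-average features unconditionally keeps
evicting the tail of a support that already classifies perfectly, so the
loop never converges on clean data. The adopted rule scales the update
strength by the support's predictive *shortfall*: a perfect forest
($g = 1$) gives no evidence against any member and leaves the support
untouched; a chance-level forest ($g = 0$) — whose internal importance
ranking is meaningless — damps its support wholesale, shrinking
drug-irrelevant variance directions until class-associated features take
over the leading component; intermediate $g$ discriminates by relative
importance $s' t_j$. The floor keeps eliminated features re-admissible;
the cap stops selected features from running away.

The loop stops when the support, or its stable core (features holding at
least half the uniform importance share $1/(2s')$), repeats on consecutive
outer iterations, up to 20 iterations. On data with no class signal the
support churns and the loop honestly reports non-convergence.

The sparsity budget $s$ (default 50 per omics) is the main tunable: it is
the number of features handed to the similarity stage and exported for
enrichment analysis. The damping $\lambda = 0.5$, forest size 200,
floor/cap and the core threshold are fixed defaults exposed in
`spcaFiLoop()`.

# Similarity networks and fusion

For samples $x, y$ over the $a$ selected features of a continuous block,

$$r_{xy} = \frac{\sum_i (x_i-\bar x)(y_i - \bar y)}
  {\sqrt{\sum_i (x_i-\bar x)^2 \sum_i (y_i-\bar y)^2}},$$

computed with `stats::cor()`; a zero-variance sample is a hard error named
in the message. For the integer CNA block the Kendall coefficient is used
in its untied form (tau-a),

$$\tau = \frac{C - E}{\binom{c}{2}},$$

with $C$/$E$ the concordant/discordant feature pairs; tied pairs count in
neither. Integer copy-number data tie heavily, which shrinks $|\tau|$
towards zero — that is a property of the coefficient, not a bug; the
tie-corrected tau-b is available as an option. Tau-a is computed exactly by
a sign-vector crossproduct (each sample is expanded into the
$\binom{c}{2}$ signs of its pairwise feature differences; the inner product
of two sign vectors is $C - E$), which agrees bit-for-bit with pair
enumeration. The diagonal is set to 1 by convention.

Fusion is horizontal concatenation in a fixed block order (default rnaseq,
cna, methylation). Negative correlations are kept as-is; no rescaling or
diffusion is applied, so slicing columns $((b-1)n, bn]$ returns block $b$
bit-exactly and the classifier input has exactly $3n$ columns.

**Transductive vs. inductive.** The default ("transductive") builds one
similarity network over all samples and then splits rows into train/test —
test samples contribute columns that the training rows see, which mirrors
the single fused matrix the method is defined on but is a mild information
leak. The `inductive` mode restricts feature selection to training samples
and computes every sample's similarity only against training samples
(input width $3 n_{train}$), so test samples influence nothing at fit
time. The no-signal control below is only meaningful in inductive mode.

# The classifier

A compact 1-D CNN consumes each sample's fused row: three same-padded
convolution (+ReLU) stages each followed by max-pooling (widths shrink by
floor division; an input narrower than $p^3$ is rejected with the minimum
stated), batch normalization after the last stage, two ReLU dense layers
and a softmax pair, trained with Adam on the cross-entropy. Defaults —
channels (8, 16, 32), kernel 5, pool 2, dense (64, 32), learning rate
$10^{-3}$, 60 epochs, batch 16 — are sized for the few-hundred-sample
regime this pipeline targets; more capacity overfits a 160-row training
set long before it helps. Initialization (He), shuffling and batch order
are all derived from the config seed, and forests are fit single-threaded,
so a pipeline run is bit-reproducible: rerunning with the same config and
seed yields byte-identical metrics, exports and predictions. The layers
are implemented as im2col packing plus BLAS matrix products (compiled
kernels under `src/`); the backward pass is verified against numerical
differentiation in the test suite. Prediction ties (p0 = p1) resolve to
class 0.

# Evaluation panel

`computeMetrics()` reports sensitivity and specificity (recall of class 1
and 0), per-class precision p1/p0, accuracy, per-class F1 and macro-F1,
with class 1 = sensitive as the positive class. The "precision" column is
the unweighted macro average of p0 and p1 — the interpretation is recorded
in the JSON output metadata. Degenerate 0/0 ratios are reported as 0 with
a warning rather than NaN.

# What the generator emulates — and what it does not

`simulateMultiOmics()` produces three blocks with the real value domains at
desk scale (defaults: n = 200; 2000/1500/3000 features standing in for
~44k transcripts, ~22k CNA loci, ~366k CpGs): Gaussian expression around
per-feature baselines, integer CNA in {−2..2} drawn from a class-dependent
categorical for planted features (the class dependence scales with the
effect size and vanishes at δ = 0), and methylation as a logistic squash
of shifted Gaussians, strictly inside [0, 1]. Planted informative features
receive a standardized between-class shift δ. Three canned fixtures define
the test conditions:

- `separable` (δ = 3, n = 200, blocks 300/200/400, 30/20/30 informative):
  every stage should succeed; held-out accuracy should be high.
- `null` (δ = 0): nothing separates the classes; in inductive mode
  held-out accuracy should hover at chance (a 40-sample test set makes
  single-run accuracy binomially noisy, so control checks average a few
  seeds).
- `variance_trap`: a minimal block of six ~0.95-correlated,
  class-independent features whose leading eigenvalue (~5.75) dominates
  the informative block (~4.5) after standardization. One-pass sparse PCA
  must select the trap; the feedback loop must displace it. Realizing the
  trap as a correlated block rather than a single high-variance feature is
  deliberate: per-feature standardization equalizes single-feature
  variances, and what rank-1 PCA actually chases is a dominant variance
  *direction*.

The generator draws features independently given the class (apart from the
trap block). It does not emulate gene-gene correlation structure, batch
effects, dose-response noise or real identifiers, so green tests
demonstrate the pipeline's mechanics and its behaviour under planted
signal and null conditions — not performance on real pharmacogenomic data.

# Known limitations

- One component per omics; deflation for further components is not fitted
  by default.
- The IC50 threshold (default: per-drug median, ties to class 0, strict
  less-than) is a modelling choice; the scale (natural-log vs raw) is the
  caller's responsibility.
- Transductive mode leaks test-sample identity (not labels) into the
  similarity columns; use inductive mode for honest generalization
  estimates.
- Tau-a on heavily tied integer data compresses the similarity range;
  consider tau-b when CNA profiles are nearly constant.
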