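---
title: "Estimating multiple behavioral traits from functional connectivity with multi-response PLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating multiple behavioral traits from functional connectivity with multi-response PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Resting-state fMRI yields, for every subject, a matrix of region-of-interest
(ROI) time-series.  The synchrony between each pair of ROIs — a resting-state
functional connection (RSFC) — is a stable individual trait, and the vector
of all $N = p(p-1)/2$ edge strengths carries information about who the
subject is: their age, education, cognitive scores, sex.  `plsconn`
implements a framework that estimates **several such labels simultaneously**
from the edge-feature vector with multi-response partial least squares
regression (PLSR), quantifies which edges drive the estimation, and tests
everything by permutation.

Multi-label estimation matters because behavioral variables are themselves
correlated; a single shared low-dimensional projection can exploit that
structure, and fitting one model for many labels is also simply cheaper than
fitting one per label.

## The model

Let $X_{n \times N}$ be the subjects-by-edges feature matrix and
$Y_{n \times M}$ the label matrix.  PLS decomposes the column-centered
matrices as

$$X = T P^\top + E, \qquad Y = U Q^\top + F,$$

extracting $d$ pairs of score vectors (columns of $T$ and $U$) that
successively maximize the covariance between the projections of $X$ and $Y$.
From the decomposition an explicit coefficient matrix follows,

$$\hat Y = X B + \mathbf{1}\,b_0^\top,$$

so prediction for unseen subjects is a single matrix product.  `pls_fit()`
implements the **SIMPLS** algorithm: weight vectors are extracted from the
successively deflated cross-covariance matrix $X_c^\top Y_c$, the data
matrix itself is never deflated, and the $T$ columns come out orthonormal.
At $d$ equal to the rank of centered $X$ the fit coincides with ordinary
least squares, which is one of the strongest correctness checks in the test
suite.  Columns are centered, never scaled: connectivity values share a
natural scale, and the protocol deliberately feeds them to the model raw.

$d$ is the model's only hyper-parameter.  The default is $d = 50$; the
estimation accuracy is insensitive over a broad band (the package ships a
sweep utility, and the validation suite checks per-label $R$ moves by less
than 0.15 across $d = 10, 20, \ldots, 150$ on synthetic data).  When the
cross-covariance becomes numerically rank deficient the extraction stops
early with a warning rather than fabricating directions.

An RBF-kernel variant (`kernel_pls_fit()`, bandwidth $\sigma = 150$ by
default, suited to raw edge features of a few thousand dimensions) follows
the dual formulation on the double-centered Gram matrix; with a linear
kernel it reproduces the linear fit, which is how it is validated.

## Connectivity definitions

`full_correlation()` is plain Pearson correlation, sensitive to direct and
indirect connections alike.  `partial_correlation()` approximates direct
connections: with $\Sigma$ the sample covariance ($1/(T-1)$ estimator on
demeaned series), it inverts the ridge-regularized matrix
$\Sigma + \rho \, \overline{\Sigma_{ii}} I$ and normalizes the negated
off-diagonal precision entries.  Scaling the ridge by the mean diagonal
makes $\rho$ unit-free; the default $\rho = 0.01$ is the standard netmats
setting.  Edge features are the upper triangle in fixed lexicographic
order (1-based), so feature $k$ means the same ROI pair in every file and
every subject; nothing is r-to-z transformed (a toggle is deliberately
absent — raw coefficients are the protocol).

## Cross-validation and metrics

`make_folds()` builds a balanced random $k$-fold partition (default
$k = 10$; with 990 subjects that is the familiar 891-train / 99-test split).
With `family_id` supplied, whole families are assigned greedily — largest
family onto the currently smallest fold — so no family straddles training
and testing; greedy balancing is not provably optimal with very large
families, but is exact in the small cases the tests enumerate.

`run_cv()` fits per fold on training rows only — including the centering
means, so there is no leakage, a property the tests verify by mutating test
labels after the fact — and pools the held-out predictions.  Metrics are
computed on the pooled predictions: Pearson $R$ and RMSE
($\sqrt{\text{mean squared error}}$, no degrees-of-freedom correction) for
continuous labels; for binary labels the estimate is thresholded at 0.5
(estimate $\ge 0.5 \mapsto 1$) for accuracy, and AUC comes from the rank
statistic with ties counted one half.  Pooling rather than averaging
per-fold metrics is a deliberate choice: it yields one well-defined value
per label and the difference is negligible at realistic $n$.

`run_estimation_sets()` reproduces the four-way layout — main labels
jointly, supplementary labels jointly, everything jointly, and each main
label alone — under one shared fold plan, so comparisons isolate the labels
entered into the model.  Binary labels join the $Y$ block as plain 0/1
columns next to continuous ones.

## Permutation inference

Significance is nonparametric throughout.  `run_permutation_test()` shuffles
the label rows jointly (one permutation of subjects applied to all label
columns — preserving the inter-label correlation the multi-label model
exploits; a per-label mode exists behind a flag), re-runs the identical CV
pipeline with the *frozen* fold plan, and computes

$$P = \frac{1 + N_{\text{exceed}}}{1 + N}$$

per label (permuted statistic strictly greater than observed; Pearson $R$
for continuous labels, accuracy for binary ones) and per edge-label pair
(permuted $|\bar B_{ij}|$ strictly greater than observed, where $\bar B$ is
the elementwise mean of the per-fold coefficient matrices).  Ties do not
count as exceedances — the conservative reading.  Edges with $P < \alpha$
(strict, default $\alpha = 0.05$) form the significant-contribution mask.
No multiple-testing correction is applied across the $N \times M$ weight
tests; that mirrors the raw-threshold protocol and is worth remembering
when interpreting edge counts.  The attainable minimum is
$1/(N_{\text{perm}}+1)$, so $P$ is never zero; with the full
$N_{\text{perm}} = 5000$, an estimate stronger than every permutation
reports $P = 0.0002$.

## Contribution analysis

`direct_edge_correlations()` ranks edges by their direct $|r|$ with a label
(ties broken by edge index, deterministically); `significant_among_top()`
asks what fraction of the top-ranked edges also carry significant model
weight — if the model relies on biologically meaningful edges, small
cutoffs are strongly enriched.  `ap_cluster()` partitions ROIs into
functional networks by affinity propagation (responsibility/availability
message passing, damping 0.9, convergence after 50 stable iterations).  AP
fixes the cluster count only indirectly, so the shared preference is tuned
by bisection until the target number of exemplars (10 in the full protocol)
emerges; if the target is unattainable the closest achievable partition is
returned with a warning.  The similarity fed to AP is the Pearson
correlation between ROIs' group-mean connectivity profiles with the
self-pair entries excluded — a natural choice, but an open design point:
the protocol literature does not pin down the AP input, and a different
similarity would move network boundaries.  `summarize_contribution()` then
counts significant edges per ROI, per network, and per network pair;
counting is binary (significant or not), with signed weight magnitudes
available from `B_bar` directly.

## The synthetic-data generator

Real resting-state datasets cannot ship with a package, so `sim_config()` /
`simulate_dataset()` generate data with exactly the statistical structure
the analysis assumes, making every downstream stage testable end-to-end:

* **Network structure.** Each ROI loads on one of $k$ network latent
  signals with loading $\lambda_{s,g}$ that varies across subjects
  (default $0.8 \pm 0.15$) — so indirect, network-mediated correlations
  fluctuate between subjects, as they do in real data.  This is what makes
  the full-vs-partial comparison meaningful: full correlation picks these
  fluctuations up as correlated nuisance features, partial correlation
  largely removes them.
* **Planted effect edges.** Per label, a sparse set of edges receives a
  dedicated latent signal; the subject's standardized strength
  $\eta_{s,e}$ shifts the loading ($c = 0.5 + 0.2\,\eta$) and hence the
  measured connectivity of exactly that edge.
* **Labels.** Continuous labels are
  $\text{effect\_size} \cdot \sum_e \beta_e \eta_{s,e}/\lVert\beta\rVert$
  plus unit-variance Gaussian noise; `effect_size = 0` makes labels
  independent of every edge (the type-I calibration condition), large
  values make them nearly noise-free.  A shared subject factor with weight
  `inter_label_corr` (default 0.3) correlates the labels; one binary label
  is a median-thresholded latent, giving balanced classes.  Families, when
  configured, share an additive intercept (off by default).
* **Determinism.** One master seed; every block of draws (edge placement,
  subject strengths, each subject's time-series, label noise) uses its own
  counter-derived sub-seed, so the dataset is a pure function of the
  configuration and adding a new draw block cannot perturb existing ones.

What the generator does *not* emulate: acquisition physics, motion and
physiological artifacts, spatial structure and ICA decomposition,
non-Gaussian label distributions, and realistic effect sparsity (nobody
knows the true SNR of behavior-connectivity coupling; defaults are chosen
so that effects are detectable at a few hundred subjects, which is what the
calibration and recovery tests need to be informative).  Passing tests
therefore demonstrate the *machinery* is correct and calibrated — not that
any particular real-data accuracy will be achieved.

## Validation problem sizes

The shipped validation suite runs entirely on generated data at sizes
chosen to exercise each property clearly: correctness oracles on tiny
matrix instances; type-I calibration on 200 independent studies of
$n = 150$, $p = 12$, 99 permutations (expected rate of $P < 0.05$ is 0.04
on the attainable p-value grid); effect-edge recovery at $n = 300$,
$p = 15$, 10 planted edges per label; the $d$-sweep stability and
partial-vs-full comparisons at $n = 300$–600, $p = 15$–25 — the latter
sizes emulating the near-thousand-subject regime of the full protocol.
The noise-free end-to-end check uses long series ($T = 3000$) because with
noise-free labels the only remaining error is sampling noise in the
correlation estimates themselves, which shrinks as $1/\sqrt{T}$.

## Numerical choices and edge cases

* SIMPLS deflation uses an orthonormal basis of X-loadings; extraction
  stops when the leading singular value falls below $10^{-12}$ relative to
  the first component's.
* Partial correlation at $\rho = 0$ with $T \le p$ is singular by
  construction; the error message says to raise $\rho$.
* `classify_binary()` maps exactly 0.5 to class 1, matching the
  $\ge 0.5$ convention.
* Ranking ties (equal $|r|$) and AP message ties are broken by the lower
  index, keeping every output deterministic.
* `perm_pvalue()` is exact integer arithmetic; nothing is ever reported as
  $P = 0$.

## Limitations

The package deliberately stops where the protocol stops: no nested CV or
automatic $d$ selection, no stratified folds, no FDR control over edge
tests, no sparse or orthogonalized PLS variants, no anatomical naming of
the recovered networks, and no preprocessing of raw images — input is
always ROI time-series or precomputed edge features.  Estimation quality at
$d$ far beyond 200 is known to deteriorate in practice; the package caps
$d$ at $\min(n-1, N)$ and otherwise leaves the regime unexplored.
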