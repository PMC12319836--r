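---
title: "Multiscale statistical comparison of connectome populations"
author: "connectoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale statistical comparison of connectome populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectoscan)
```

## The inference problem

A multi-subject connectomics study measures one weighted network per
subject, all parcellated onto the same atlas: `n` vertices (brain regions)
and nonnegative edge weights (for structural data, typically streamline
counts). Each subject carries a categorical phenotype label (genotype,
diagnosis, strain). The scientific question is *which components of the
network differ in distribution across the phenotype groups* — and
"component" is deliberately multiscale: an individual edge, a vertex and
its whole connectivity profile, a community of vertices, or the network as
a whole.

`connectoscan` formulates one k-sample hypothesis test per component at
each scale, each built on a random graph model chosen so that the model's
parameters isolate exactly the scale of interest:

* **Edges** — the weighted independent-edge (IE) model: each edge weight is
  an independent draw from an edge-specific distribution. The per-edge null
  is that this distribution is identical across groups.
* **Vertices** — the random dot product graph (RDPG): each vertex has a
  latent position `x_i` in d-dimensional Euclidean space and edges arise
  independently as Bernoulli(`x_i . x_j`). The per-vertex null is that the
  vertex's mean latent position is identical across groups.
* **Communities** — the stochastic block model (SBM) with a known
  assignment of vertices to `K` communities. The per-block null is that
  the block's weight structure is identical across groups.
* **Global** — per-graph latent-position matrices compared wholesale
  through Frobenius dissimilarities.

## Test statistics

### Unbiased k-sample distance correlation

Edge- and community-scale tests use the unbiased (U-centered) distance
correlation between the stacked observations and a one-hot encoding of the
group labels. Distance correlation is zero exactly when the observation
distribution is independent of the label — i.e. when all groups share one
distribution — so the test is consistent against *any* distributional
alternative, not just location shifts. This matters in practice: edge
weights whose group distributions share a mean but differ in spread are
invisible to the t-test and to rank tests, but not to distance correlation
(the package's edge benchmark demonstrates exactly this contrast).

The label distance is 0 within a class and `sqrt(2)` between classes; any
strictly positive between-class constant yields the same permutation test.
The U-centered statistic can be slightly negative in finite samples; the
p-value machinery accepts that. Two null calibrations are provided:

* **Permutation** (default below a total sample size of 20): labels are
  permuted and the add-one estimator `p = (1 + #{perm >= obs}) / (B + 1)`
  is used, so p-values are never smaller than `1/(B+1)` and are valid for
  exchangeable nulls at any sample size.
* **Chi-square approximation** (default at total `n >= 20`, the regime in
  which the approximation is trustworthy): `n * stat + 1` is referred to a
  chi-square distribution with one degree of freedom. This makes
  full-atlas edge scans (tens of thousands of tests) run in seconds.

### Hotelling and MANOVA on joint embeddings

Vertex-scale inference first estimates every graph's latent positions
*jointly* with the omnibus embedding: the `mn x mn` block matrix with
diagonal blocks `A_i` and off-diagonal blocks `(A_i + A_j)/2` is embedded
by its top-d scaled eigenvectors and split back into one `n x d` block per
graph. Because all graphs are embedded in one spectral basis, per-vertex
positions are directly comparable across graphs with no Procrustes
alignment, and the estimates are asymptotically normal. That normality
motivates parametric multivariate tests per vertex: Hotelling's T-squared
for two groups, one-way MANOVA with Pillai's trace for more. The Pillai
approximate F uses `s = min(d, k-1)`, `m = (|d-k+1|-1)/2`,
`r = (N-k-d-1)/2`, `F = ((2r+s+1)/(2m+s+1)) V/(s-V)` on
`(s(2m+s+1), s(2r+s+1))` degrees of freedom; at `k = 2` this is
algebraically identical to the Hotelling test (the test suite asserts
agreement to 1e-10). For a four-group design with `N = 8` per group and
`d = 5` the degrees of freedom are (15, 78).

### Community approaches

Four nested summaries of a block, each tested k-sample:

1. **Average connectivity** — Otsu-binarize, pool nonzero-edge counts per
   group, Pearson chi-squared on the resulting proportions.
2. **Average edge weight** — per-subject block mean, scalar Dcorr.
3. **Multivariate binary** — Otsu-binarize and vectorize the block, Dcorr.
4. **Multivariate weighted** — vectorize the raw block, Dcorr.

The multivariate weighted approach is the default: it is the only one that
retains enough of the block's distributional detail to detect
variance-only differences at realistic sample sizes, while remaining
calibrated under the null (the community benchmark quantifies this).

Otsu's threshold maximizes between-class variance over a fixed 256-bin
histogram; ties break toward the lower bin edge. For community approaches
the threshold is computed **once from the pooled nonzero weights of the
whole sample** so that "connected" means the same thing for every subject;
per-subject thresholding is available by flag but makes the binary
representations incomparable across subjects.

### Multiplicity

Scans correct with Holm's step-down procedure by default: it controls the
family-wise error rate with no independence assumption — appropriate for
network data, where tests at overlapping components are intrinsically
dependent — and dominates plain Bonferroni. Benjamini–Hochberg is offered
for exploratory work but its FDR guarantee leans on independence
assumptions that connectome data violate. When Holm leaves zero
rejections (common at realistic sample sizes against tens of thousands of
edge tests), the scan still emits the complete ranking: ascending raw
p-value, ties broken by descending statistic, then lexicographic component
id, deterministically.

### Conditional independence

To ask whether a vertex's embedding carries label information *beyond* a
per-vertex anatomical covariate (volume, diffusion metrics, ...), the
package tests conditional independence of label and embedding given the
covariate with a local-permutation distance correlation: labels are
permuted only among nearest neighbors in covariate space (random
transpositions along the k-nearest-neighbor graph, neighbor count 10 by
default), which preserves the label-covariate relationship while breaking
any residual label-embedding dependence. The literature offers several
conditional-independence procedures; this one was chosen because it
reuses the package's Dcorr machinery, is valid for categorical labels, and
degrades gracefully to the unconditional test when the covariate is
uninformative.

## Simulation generators

The generators are first-class, tested code: they define the study
conditions under which every benchmark claim in this package is made.

**Edge scale.** Two groups of weighted IE graphs. Every null edge is
truncated-normal with underlying mean 10 and sd 1 (truncation at zero).
Signal edges in group 2 shift the *realized* mean by `delta` and scale the
underlying sd by `1 + phi`. Two calibration choices deserve note. First,
because truncation makes the realized mean a nonlinear function of the
underlying parameters, the group-2 underlying mean is solved numerically
so the realized means differ by exactly `delta`; naively shifting the
underlying mean would leak a mean difference into the variance-only
setting and corrupt the contrast the benchmark is about. Second, the
baseline sits at 10 standard deviations above the truncation point: a
baseline close to zero lets truncation both crush the realized variance
contrast and skew the distributions (so that equal mean no longer implies
equal median, handing the rank test spurious power). With the calibrated
baseline, the variance-only setting cleanly separates
distribution-sensitive from location-only tests.

**Vertex scale.** Two groups of 50-vertex RDPGs. All vertices share the
base latent position (0.45, 0.45); in group 2, the planted signal
vertices' positions are multiplied by a stretch constant (stretch
setting), or first rotated in the plane and then stretched
(rotate-and-stretch setting). The calibrated defaults are 8 graphs per
group (the size of a typical inbred-strain cohort), stretch 1.19, and for
the rotated setting stretch 1.30 with angle `acos(1/1.30)` — the angle at
which rotation and stretch exactly cancel in dot products with unperturbed
vertices, so signal-null edge probabilities are untouched and the
perturbation is visible only in the signal-signal block and in the latent
geometry. This makes the rotated setting a genuinely harder, more
latent-structural problem than the stretch setting, which is the point of
testing both.

**Community scale.** Two groups of weighted SBMs on 3 communities of 10
vertices, block-diagonal (no between-community edges). Block 1 is null;
block 2 inflates the group-2 sd by a factor 1.6 with realized means
matched exactly (same numerical matching as above); block 3 shifts the
realized mean by 0.15 at baseline truncated-normal(1, 0.5). These sizes
put the multivariate-weighted approach's power transition for the
variance-only block at per-group sizes in the mid-20s, with reliable
detection above 30.

**What the generators do not emulate:** weight distributions of real
tractography (zero-inflated, heavy-tailed counts), spatially correlated
edges, hemispheric symmetry, measurement/registration noise shared across
edges, or vertex sets that differ across subjects. Passing benchmarks
therefore demonstrate correctness and relative power of the procedures
under their motivating models — not performance guarantees on any
particular imaging pipeline.

## Competitor vertex representations

The vertex benchmark compares the omnibus-embedding test against three
families of established alternatives, each implemented here as a
documented baseline:

* **MDMR** — each vertex is represented by its vector of adjacent edge
  weights; a Gower-centered distance matrix and the group-label hat matrix
  give a pseudo-F, calibrated by label permutation.
* **NBS** — a per-edge two-sample statistic (|t| or Dcorr) is thresholded;
  connected components of the supra-threshold graph are calibrated against
  the permutation null of the maximum component extent (edge count); each
  vertex inherits its component's p-value, vertices in no component get 1.
  The primary threshold defaults to the 95th percentile of the pooled
  permutation distribution of the edge statistic — a fixed, reproducible
  rule in a procedure whose thresholding is otherwise notoriously ad hoc.
* **Graph-statistic profiles** — each vertex of each subject is summarized
  by (weighted degree, local clustering, betweenness, closeness, triangle
  count), computed on the Otsu-binarized graph except the degree; groups
  are compared per vertex with Hotelling/MANOVA. The five statistics are a
  fixed, conventional choice; the benchmark's message is precisely that
  *no* fixed statistic vector captures latent connectivity structure.

A limitation worth stating plainly: on binary graphs the per-edge |t| and
Dcorr statistics induce essentially the same edge ranking, so inside NBS
the choice between them reduces to how each interacts with the pooled
permutation threshold. In our simulations that interaction consistently
favors the t variant — the Dcorr variant admits more null edges at the
same nominal threshold and merges components — so replacing t with Dcorr
inside NBS does not improve vertex detection here. Both variants remain
far below the embedding-based test regardless.

## Numerical choices

* Embedding signs are canonicalized per dimension (largest-magnitude
  loading made positive) so serialized embeddings are reproducible;
  every comparison across embeddings uses rotation-invariant quantities
  (dissimilarities, test statistics).
* Weighted graphs are embedded as-is; a log transform is left to the user
  since modality conventions differ.
* The default embedding dimension is selected once from the omnibus
  matrix's scree by profile-likelihood elbow (two normal means, pooled
  variance, maximize over the split point), shared by all graphs, with a
  user override; degenerate constant sprectra return d = 1 with a warning.
* Classical MDS double-centers `-D^2/2`, keeps only positive eigenvalues,
  and truncates with a warning if fewer than requested.
* Singular pooled covariance (Hotelling) or `H + E` (MANOVA) matrices fall
  back to the Moore–Penrose pseudo-inverse with a warning.
* Edges with zero weight in every subject are skipped and flagged (they
  carry no information) but still counted in the announced test total;
  ranks place them last.
* One master seed drives everything; per-replicate streams are derived
  deterministically from (seed, setting, replicate) so any replicate can
  be reproduced in isolation.
* All scans accept directed graphs (ordered-pair test counts); the
  community test count convention is `K(K+1)/2` for undirected data —
  within-community blocks are scientifically central (a strain's
  intra-structure wiring can be the strongest signal), so they are
  included.

## Problem sizes used by the tests and benchmarks

The shipped test-suite and acceptance-script problem sizes are the
package's chosen desk-scale study conditions: the vertex benchmark runs
both perturbation settings, signal counts {5, 10, 15, 20, 25}, and 25
replicates per setting (15 in the test suite) with 200 permutations for
the permutation-calibrated baselines; the community benchmark runs 50
replicates at per-group sizes {35, 40, 50} (plus smaller sizes in
pattern checks); the edge benchmark runs 25–50 trials per grid cell.
Calibration checks (type-I error, FWER, super-uniformity) use a few
hundred simulated datasets each and are asserted within binomial
confidence bounds of the nominal level — a stochastic rate can only ever
be verified up to its own sampling noise.

## Known limitations

* Tests require every phenotype class to contain at least two graphs, and
  parametric vertex tests additionally need group sizes comfortably above
  the embedding dimension.
* The chi-square Dcorr calibration is a large-sample device; below a total
  sample of 20 the package switches to permutations automatically.
* The conditional-independence analysis tests one covariate at a time;
  joint conditioning on several covariates is possible through the same
  interface (multi-column `z`) but neighborhoods in high-dimensional
  covariate space become less local.
* Continuous phenotypes must be discretized by the caller.
* Full eigendecompositions are used throughout; atlases beyond a few
  hundred vertices with many subjects will feel the `(mn)^3` cost of the
  omnibus embedding.
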