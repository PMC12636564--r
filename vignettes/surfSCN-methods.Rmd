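---
title: "Structural covariance networks from parcellated surface area: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks from parcellated surface area: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfSCN)
```

# The model

A structural covariance network (SCN) treats cortical regions as vertices
and the partial correlation of a morphometric measure — here absolute
surface area in mm² — across the subjects of a group as signed edge
weights. Partial rather than marginal correlations are used because the
marginal correlation between two regions is confounded by indirect
dependencies through the rest of the cortex; the partial correlation
$\rho_{ij} = -\Omega_{ij} / \sqrt{\Omega_{ii}\Omega_{jj}}$, with
$\Omega = \Sigma^{-1}$ the precision matrix, isolates the unique shared
variance of regions $i$ and $j$.

The central obstacle is rank: with $n$ subjects per group and $H$
hemisphere-averaged parcels, $\Sigma$ is singular whenever $n \le H$
(e.g. 102 subjects and 180 parcels). Rather than regularising the inverse —
which perturbs the dependency structure in ways that are hard to reason
about — the pipeline reduces the atlas: parcels are clustered by Ward's
criterion and cluster areas are summed before inversion. The package
assumes, and checks, that cluster-level areas are approximately normal
(Anderson–Darling) and that the inversion is performed only when
$n > K$ vertices; violating the rank requirement is a hard error, never a
silent fallback.

## Clustering and cluster-count selection

Ward's linkage requires Euclidean geometry, but "clustering the partial
correlation matrix" does not by itself define a metric. The package takes
each parcel's **row profile** of the parcel-level partial-correlation
matrix as its feature vector under Euclidean distance: two parcels are
close when they relate to the rest of the cortex in the same way. This is
the property that makes summing cluster members defensible.

The cluster count $K$ is selected by four scores computed for every
candidate: mean silhouette width and Dunn index (separation/compactness, on
the same row-profile distances), and two consistency scores — the adjusted
Rand index (ARI) between labelings derived independently from left- and
right-hemisphere data, and the mean ARI between subsample labelings and the
full-sample labeling. The four are min–max normalised across the candidate
range and summed; the argmax is chosen, with ties broken toward smaller $K$
for parsimony; the mode over repeated seeded runs is reported. Min–max
normalisation is the simplest way to make silhouette (in $[-1,1]$), Dunn
(in $[0,\infty)$) and ARI commensurate; because it is monotone, the argmax
is unaffected by the scores' different native scales. Subsample labelings
are compared against the full-sample labeling rather than pairwise among
themselves: it measures the same stability signal at a fraction of the
cost. A zero within-cluster diameter makes the Dunn index infinite; it is
clamped to a sentinel of 1e6 and flagged (`dunn_degenerate`) rather than
silently zeroed.

## Harmonization

Scan-site effects are removed with the parametric empirical-Bayes ComBat
location–scale model (via `sva::ComBat`), protecting sex, age and group as
covariates. Single-site data are returned unchanged, and a site with fewer
than two subjects is an error — the site variance is not estimable.

## Global metrics

All metrics operate on the nonnegative weight matrix $A$ with
$A_{ij} = |\rho_{ij}|$, zero diagonal, without thresholding; sign-restricted
subnetworks zero the excluded edges but keep the full vertex set so metric
values stay comparable across modes.

* **Clustering** $C = \mathrm{Tr}(A^3) / \sum_{i\ne j} [A^2]_{ij}$. Note
  this statistic is homogeneous of degree one: scaling all weights by $c$
  scales $C$ by $c$. Since SCN weights are bounded by 1 this is
  well-behaved, but comparisons between networks are comparisons of weight
  structure *and* scale.
* **Path length and efficiency** use edge lengths $1/A_{ij}$ (weights are
  associations, not costs): $L$ is the mean shortest-path distance over
  ordered pairs, and $E_{glob}$ the mean inverse distance with unreachable
  pairs contributing zero. $L$ on a disconnected graph is an error that
  reports component sizes. Because the SCN is dense, shortest paths may
  legitimately hop through an intermediate vertex whenever
  $1/A_{ik} + 1/A_{kj} < 1/A_{ij}$.
* **Betweenness** is computed on the same inverse-weight lengths with all
  equal-length ties counted, normalised by the $(N-1)(N-2)/2$ unordered
  pairs excluding the vertex, so the hub of a star scores exactly 1. The
  alternative (ordered pairs) would merely halve every value; the unordered
  convention was chosen for its unit hub value.
* **Jensen–Shannon complexity.** Each vertex's weights are normalised to a
  probability profile $p_i(j) = w_{ij}/\sum_k w_{ik}$ (uniform $1/n$ for an
  isolated vertex, which arises in sign-restricted subnetworks); pairwise
  Jensen–Shannon divergences in bits are averaged over all $n^2$ ordered
  pairs. The implementation asserts the identity
  $JSD_{global} = (2/n^2)\sum_{i<j} JSD_{ij}$ to 1e-12. A subtlety worth
  recording: because $p_i$ places zero mass at $i$ itself, two vertices
  never have literally identical profiles in a complete graph — on $K_n$
  with equal weights $JSD_{ij} = 1/(n-1)$ exactly and $JSD_{global} = 1/n$,
  not zero. The index therefore measures profile heterogeneity *given* the
  self-exclusion convention, and its natural baseline for an
  $n$-vertex network is $1/n$ rather than 0.

## Spatial analysis

Cluster centroids are arithmetic means of member parcel coordinates,
re-projected to the sphere radius before the great-circle formula
$d_{ij} = r\,\mathrm{atan2}(\|P_i \times P_j\|, P_i \cdot P_j)$ — the
formula presumes on-sphere points, and centroids of ring-shaped or very
spread clusters can fall far inside the sphere; any centroid whose norm
deviates from $r$ by more than 25% is flagged for inspection (the analogue
of checking centroid placement visually).

**Small-world propensity** compares the observed network with a lattice
null (weights sorted descending, assigned to vertex pairs sorted by
geodesic distance ascending — ties broken by index for determinism) and an
ensemble of 10 weight-shuffled random nulls:
$\Delta C = (C_{latt}-C_{obs})/(C_{latt}-C_{rand})$,
$\Delta L = (L_{obs}-L_{rand})/(L_{latt}-L_{rand})$, both clamped to
$[0,1]$ (the clamping convention of the method's source), then
$\phi = 1-\sqrt{(\Delta C^2+\Delta L^2)/2}$ and
$\delta = 4\,\mathrm{atan2}(\Delta L, \Delta C)/\pi - 1$. Degenerate
denominators (identical null metrics) are flagged and the ratio pinned to
its clamp. By construction the lattice null is *more* clustered and has
*longer* paths than the random nulls — $\Delta L$'s denominator relies on
$L_{latt} \ge L_{rand}$.

**Distance–weight curves** are Gaussian GAMs (via mgcv) of edge weight on
geodesic distance with one thin-plate smooth per group (basis dimension
$k = 5$: enough flexibility for a decay-and-flatten shape without chasing
noise) plus a parametric group offset, smoothness chosen by REML (more
stable than GCV at these sample sizes). The full model is compared with a
shared-smooth reduced model by a $\chi^2$ analysis of deviance; with
literally identical groups this comparison is degenerate (the extra smooths
earn ~0 effective df) and the p-value may be `NA`, which callers should
treat as "no evidence of separate smooths". Group differences along
distance use pointwise Z-tests at 100 equidistant grid points spanning the
observed range (inclusive of both endpoints), Benjamini–Hochberg corrected
across the grid. Penalized splines are not shape-constrained: a fitted
curve on decaying data is decreasing in trend but may wiggle within
pointwise noise, and tests assert trend, not strict monotonicity.

## Inference

Permutation tests for global metrics swap group labels **at the level of
the cluster-aggregated surface-area data** — each iteration re-splits the
pooled subjects, re-inverts both covariance matrices and recomputes the
metric, so the null distribution carries the full estimation noise of
network construction. One-sided p-values are the plain proportion of null
differences at least as extreme as observed, following the "proportion of
times" convention; the $(b+1)/(m+1)$ correction is available behind
`add_one` for users who need strictly positive p-values. Effect sizes are
observed difference / null SD, signed like the observed difference.
Failed iterations (e.g. a rank-deficient resample) are recorded and
excluded, never silently imputed.

Group matching is solved exactly: within sex strata, minimizing total
absolute age difference over 1:1 assignments is — for a single continuous
covariate — an assignment problem whose optimum is attained by an
order-preserving matching on sorted ages, found by an $O(nm)$ dynamic
program. This beats greedy nearest-neighbour matching on every instance
(property-tested) without requiring an external solver.

# The synthetic-data generator

The generator exists so that every downstream stage can be exercised, with
known ground truth, in the statistical regime the analysis assumes. It
emulates: approximately normal cluster-level areas; partial correlations
distributed around zero; covariance magnitude decaying with geodesic
distance (strong short-range structure); a group effect that scales
correlation magnitude; and additive/multiplicative site batch effects.

Its construction is hierarchical. Parcels on a Fibonacci-lattice sphere
(deterministic, near-uniform, radius 100 mm like the fsaverage sphere) are
partitioned into `n_latent_clusters` spatially compact groups; each group
shares a unit-variance latent factor carrying `cluster_coherence` = 0.85 of
every member parcel's variance. The latent factors follow a precision
$I - g\,O$ where $O$ has magnitudes $\propto \exp(-0.02\,d)$ in the
centroid geodesic distance $d$ (strong below ~50 mm, negligible beyond
~150 mm), Bernoulli sparsity, and random signs — signs are random so that
partial correlations are centred on zero. Two design choices deserve
explanation:

* **Latent clusters rather than a flat parcel-level precision.** Summing
  parcels with random-sign couplings cancels the very structure the
  cluster-level analysis measures; latent factors shared by contiguous
  parcels survive aggregation exactly, and they reproduce the empirical
  phenomenon that robust clusters are spatially contiguous. The flat model
  remains available as the `n_latent_clusters = n_parcels/2` special case.
* **Positive definiteness by spectral rescaling, with diagonal loading as a
  guard.** $O$ is rescaled so its extreme eigenvalue equals
  `spectral_margin` = 0.6. The affected group multiplies $O$ by
  `group_scale` $g$, so its latent partial correlations scale *exactly* by
  $g$ for $g < 1/0.6 \approx 1.67$. The obvious alternative — add
  $\lambda I$ until positive definite — is triggered asymmetrically by the
  affected group's larger couplings and was measured to shrink the planted
  contrast (a nominal 1.5× became ~1.3×); it is retained only as a
  last-resort guard (minimal $\lambda$ by bisection).

Hemisphere pairs are mirrored copies sharing the parcel latent plus
independent noise (`hemi_noise_sd` = 0.3 of the 50 mm² area SD), which is
what makes hemisphere averaging and left/right ARI checks meaningful. Areas
are shifted to per-parcel means drawn around 500 mm² with SD 50 mm², so
draws are positive in essentially all cases (a negative area would require
a 10-SD event; a floor at 1 mm² guards the tail), then per-site affine
batch effects (SDs: 20 mm² additive, 0.05 log-scale multiplicative) are
applied, with phenotypes attached (age uniform on 18–60, sex Bernoulli 0.5,
site round-robin). One integer seed fixes everything bit-exactly, with
internal sub-seeds keeping the two groups' structural parameters (cluster
partition, coupling signs, site effects, parcel means) identical.

**What the generator does not emulate.** Raw parcel-area distributions of
real cortex (no empirical distributions are published for them), cortical
folding and true parcel geometry, non-Gaussian tails, age/sex effects on
area, and site-by-group confounding. Passing tests therefore demonstrate
that the pipeline recovers the statistical structure it is designed for —
not that real populations have that structure.

# Problem sizes and numerical conventions

Test fixtures run at 160 parcels (80 per hemisphere), 20 latent clusters,
102 subjects per group — the matched-group size of the motivating design —
with a 650-control reference sample for clustering, and permutation counts
of 200–1000; the cluster-count recovery study uses 80 parcels, 10 planted
clusters and 350 subjects. These sizes keep the suite fast while preserving
every rank relationship ($n > K$ for group networks, $n_{ref} > H$ for the
reference) that the full-scale analysis depends on. At these sizes the
group-effect signature (variance ratio < 1, reduced path length, reduced
JSD, short-to-mid-range pointwise differences) is reproduced, while the
edge count (190 vs 1891 at the full 62-cluster atlas) leaves the
variance-ratio F-test underpowered for formal significance at
`group_scale = 1.5` — the same power regime the full-scale design reports
for its medium effects. The planted path-length decrease is decisively
detected by permutation once samples reach 250 per group.

Numerical conventions, in one place: covariance uses the unbiased $n-1$
estimator (partial correlations are invariant to the divisor); precision
symmetry is enforced by averaging $\Omega$ with its transpose before
normalisation and correlations are clipped to $[-1,1]$; shortest-path ties
are resolved by exact accumulation over all equal-length paths;
Anderson–Darling normality uses estimated-parameter critical values
(`nortest::ad.test`); lattice-null ties break by index; the JSD convention
$0\log(0/x)=0$ is applied entrywise; and all stochastic stages take
explicit integer seeds kept below $2^{31}$.

# Limitations

The package consumes already-extracted parcel areas; MRI preprocessing,
surface registration and parcellation are out of scope, as are
voxel/mesh-level simulation, functional-network assignment, and
cortical-thickness analyses. The composite cluster-count score weights its
four ingredients equally — a deliberate, simple choice, but not the only
defensible one. Permutation inference assumes exchangeability of subjects
across groups after harmonization; strong unmodelled site-by-group
confounding would violate it. Small-world propensity is reported without
permutation significance: rebuilding both nulls inside every iteration is
prohibitively expensive, and the package follows the convention of
reporting φ and δ descriptively.
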