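# surfSCN

Structural covariance networks (SCNs) capture how the morphometry of
different cortical regions co-varies across the subjects of a group: vertices
are regions, and each edge weight is the partial correlation of regional
cortical surface area (mm²) across subjects. Because these correlations
reflect coordinated neurodevelopment, comparing the global organisation of
SCNs between an affected group and matched controls is a compact way to ask
whether a condition reshapes cortical organisation. `surfSCN` implements the
full analysis pipeline for researchers working with parcellated surface-area
tables (e.g. the 360-region HCP atlas): atlas reduction, network
construction, global weighted-network metrics, spatially informed
small-world analysis, distance-resolved group comparison, and permutation
inference — plus a seeded synthetic-data generator so every stage is
testable without restricted MRI data.

## The method

Given subject × parcel surface areas for two matched groups of size *n*:

1. **Hemisphere averaging and harmonization.** The 2H parcels are reduced to
   H by averaging L/R pairs; scan-site batch effects are removed by ComBat
   (empirical-Bayes location–scale model) with sex, age and group protected.
2. **Atlas reduction.** Because Σ cannot be inverted when *n* < H, parcels
   are clustered by Ward's criterion on the rows of the parcel
   partial-correlation matrix estimated from a large control reference
   sample. The cluster count K is chosen by a composite of mean silhouette,
   Dunn index, left/right-hemisphere adjusted Rand index (ARI), and
   subsample ARI, min–max normalised and summed, repeated over seeds.
3. **Network construction.** Cluster areas are summed, the cluster
   covariance Σ is inverted, and partial correlations
   ρᵢⱼ = −Ωᵢⱼ/√(ΩᵢᵢΩⱼⱼ) (Ω = Σ⁻¹) define signed edges; |ρᵢⱼ| are the
   weights. Positive-only and negative-only subnetworks are also supported.
4. **Global metrics.** Weighted clustering C = Tr A³ / Σ_{i≠j}[A²]ᵢⱼ;
   characteristic path length L and global efficiency on inverse-weight
   shortest paths; normalised betweenness centrality; and a network
   complexity index: the mean Jensen–Shannon divergence (bits) between the
   normalised edge-weight profiles of all vertex pairs,
   JSD_global = (1/n²) Σᵢⱼ JSDᵢⱼ.
5. **Spatial structure.** Great-circle geodesics between cluster centroids
   (d = r·atan2(‖Pᵢ×Pⱼ‖, Pᵢ·Pⱼ)); small-world propensity
   φ = 1 − √((ΔC² + ΔL²)/2) against a distance-ordered lattice null and
   shuffled random nulls, with δ = 4·atan2(ΔL, ΔC)/π − 1 locating the
   network on the random↔lattice continuum; and Gaussian GAMs of weight on
   geodesic distance (per-group smooths, k = 5, plus a parametric group
   term) with pointwise Z-tests at 100 grid distances, FDR-corrected.
6. **Inference.** 1:1 optimal matching by sex and age; permutation tests
   that swap group labels at the level of the surface-area data and rebuild
   the networks each iteration; effect sizes as observed difference / null
   SD; jackknife standard errors; and the two power analyses (noncentral-t
   solve and permutation simulation).

## Worked example

```r
library(surfSCN)

res <- runPipeline(list(
  synthetic = list(n_subjects_per_group = 102, n_parcels = 160,
                   n_sites = 1, n_latent_clusters = 20,
                   group_scale = 1.5, seed = 1),
  cluster     = list(K = 20, n_reference_subjects = 650),
  permutation = list(n_iter = 1000, seed = 4, direction = "less"),
  swp         = list(n_random = 10, seed = 5),
  gam         = list(k = 5)
))

round(sapply(res$metrics, function(m) c(C = m$C, L = m$L, JSD = m$JSD_global)), 4)
#>     control affected
#> C    0.0956   0.1195
#> L    9.0180   8.0597
#> JSD  0.2320   0.1900
res$dist_report$corr$f          # control/affected variance ratio
#> [1] 0.7902125
sum(res$spatial$pointwise$p_adj < 0.05)
#> [1] 17
res$permutation$L[c("p", "effect_size")]
#> $p
#> [1] 0.123
#> $effect_size
#> [1] -1.115
```

The synthetic affected group was generated with all latent couplings scaled
by 1.5. The output shows the signature this kind of study looks for:
stronger correlations in the affected group (control/affected variance
ratio F = 0.79 < 1), a shorter characteristic path length (8.06 vs 9.02),
higher clustering, lower network complexity (JSD 0.190 vs 0.232 bits), and
17 of the 100 grid distances with FDR-significant weight differences,
concentrated at short-to-moderate range. The label-permutation test of the
path-length difference gives p = 0.123 at effect size −1.12 null-SDs — at n
= 102 per group a planted effect of this size sits right at the edge of
detectability, which is the power regime the matched-group design operates
in. `res$spatial$swp` holds the small-world propensity of each group's
network.

A thin command-line wrapper is installed at
`inst/scripts/scn_pipeline.R` (`Rscript scn_pipeline.R --config run.yaml
--out results/`), taking the same configuration as YAML.

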