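## Shared synthetic fixtures, built in code at test time. Sizes are chosen
## for the test suite: 160 parcels (80 per hemisphere), 20 latent clusters,
## 102 subjects per group — the subject count of the matched study groups.

## cache across tests within a run
.fixture_env <- new.env(parent = emptyenv())

## a two-group study plus the cluster labelling estimated from a separate
## 650-control reference sample, aggregated to cluster level
fixture_study <- function(seed = 1, group_scale = 1, n = 102,
                          n_parcels = 160, k0 = 20, n_sites = 1,
                          ref_n = 650) {
    key <- paste("study", seed, group_scale, n, n_parcels, k0, n_sites,
                 sep = "_")
    if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
    cfg <- synthConfig(n_subjects_per_group = n, n_parcels = n_parcels,
                       n_sites = n_sites, group_scale = group_scale,
                       n_latent_clusters = k0, seed = seed)
    ref_cfg <- synthConfig(n_subjects_per_group = ref_n,
                           n_parcels = n_parcels, n_sites = n_sites,
                           n_latent_clusters = k0, seed = seed)
    ref <- averageHemispheres(
        sampleGroup(ref_cfg, buildPrecision(ref_cfg), "control"))
    sol <- wardCluster(partialCorrMatrix(partialCorr(ref)), k0)
    study <- synthStudy(cfg)
    agg <- aggregateClusters(averageHemispheres(study), sol$labels)
    groups <- splitByGroup(agg)
    layout <- S4Vectors::metadata(study)$layout
    gd <- geodesicMatrix(clusterCentroids(layout$base, sol$labels))
    out <- list(cfg = cfg, study = study, labels = sol$labels,
                groups = groups, layout = layout, gd = gd,
                nets = lapply(groups, partialCorr))
    .fixture_env[[key]] <- out
    out
}

## small deterministic weight matrix fixtures
fixture_random_weights <- function(n, seed = 1, density = 1) {
    set.seed(seed)
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    vals <- runif(sum(ut), 0.05, 1)
    if (density < 1) vals <- vals * rbinom(length(vals), 1, density)
    w[ut] <- vals
    w <- w + t(w)
    diag(w) <- 0
    w
}

## subjects x variables Gaussian draws with a given correlation matrix
fixture_mvn <- function(n, corr, seed = 1) {
    set.seed(seed)
    matrix(rnorm(n * nrow(corr)), n) %*% chol(corr)
}
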