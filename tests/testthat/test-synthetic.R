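test_that("Fibonacci sphere layout is deterministic, on-sphere and near-uniform", {
    lay2 <- makeSphereLayout(2, 1.0)
    expect_equal(sqrt(rowSums(lay2$points^2)), c(1, 1), tolerance = 1e-12)

    lay360 <- makeSphereLayout(360, 100)
    d <- surfSCN:::.sphereDist(lay360$points, 100)
    expect_true(all(d <= pi * 100 + 1e-8))
    expect_identical(lay360$points, makeSphereLayout(360, 100)$points)

    lay100 <- makeSphereLayout(100, 1.0)
    dn <- surfSCN:::.sphereDist(lay100$points, 1.0)
    diag(dn) <- Inf
    nn <- apply(dn, 1, min)
    expect_lt(sd(nn) / mean(nn), 0.5)

    expect_error(makeSphereLayout(1, 1), "n_parcels")
})

test_that("paired layout mirrors hemispheres with shared pair ids", {
    lay <- makePairedLayout(40, 100)
    expect_equal(nrow(lay$points), 40)
    expect_equal(unname(lay$points[1:20, 2:3]),
                 unname(lay$points[21:40, 2:3]))
    expect_equal(unname(lay$points[1:20, 1]),
                 -unname(lay$points[21:40, 1]))
    expect_equal(lay$pair_id, rep(1:20, 2))
})

test_that("flat-mode precision honours the independence and identity limits", {
    ## one latent per parcel: parcel partial correlations equal the coupling
    base <- list(n_parcels = 40L, n_sites = 1L, n_latent_clusters = 20L,
                 seed = 5L)
    far <- do.call(synthConfig, c(base, list(distance_decay_rate = 1e6)))
    om <- buildPrecision(far)
    pc <- surfSCN:::pcorrFromPrecision(om)
    expect_lt(max(abs(pc[upper.tri(pc)])), 1e-10)

    null_cfg <- do.call(synthConfig, c(base, list(group_scale = 1)))
    expect_equal(buildPrecision(null_cfg, group = "control"),
                 buildPrecision(null_cfg, group = "affected"))

    eff <- do.call(synthConfig, c(base, list(group_scale = 1.5)))
    pc_c <- surfSCN:::pcorrFromPrecision(buildPrecision(eff, group = "control"))
    pc_a <- surfSCN:::pcorrFromPrecision(buildPrecision(eff, group = "affected"))
    expect_gt(var(pc_a[upper.tri(pc_a)]), var(pc_c[upper.tri(pc_c)]))
})

test_that("generated precision matrices are symmetric positive definite", {
    for (seed in 1:4) {
        for (gs in c(1, 1.5)) {
            cfg <- synthConfig(n_parcels = 80, n_sites = 1, group_scale = gs,
                               seed = seed)
            om <- buildPrecision(cfg, group = "affected")
            expect_equal(om, t(om), tolerance = 1e-10)
            expect_gt(min(eigen(om, TRUE, only.values = TRUE)$values), 0)
        }
    }
})

test_that("group sampling is seed-exact and respects batch-effect switches", {
    cfg <- synthConfig(n_subjects_per_group = 30, n_parcels = 40,
                       n_sites = 3, site_shift = 0, site_scale = 0,
                       seed = 9)
    om <- buildPrecision(cfg)
    g1 <- sampleGroup(cfg, om, "control")
    g2 <- sampleGroup(cfg, om, "control")
    expect_identical(areaMatrix(g1), areaMatrix(g2))
    expect_identical(as.data.frame(colData(g1)), as.data.frame(colData(g2)))

    ## no batch effect: per-parcel site means agree up to sampling error
    a <- areaMatrix(g1)
    site <- colData(g1)$site
    ms <- vapply(split(seq_len(ncol(a)), site),
                 function(ix) rowMeans(a[, ix, drop = FALSE]),
                 numeric(nrow(a)))
    spread <- apply(ms, 1, function(x) diff(range(x)))
    expect_lt(max(spread) / cfg$area_sd, 2)

    ## with a site effect the spread grows
    cfg_b <- synthConfig(n_subjects_per_group = 30, n_parcels = 40,
                         n_sites = 3, site_shift = 40, site_scale = 0,
                         seed = 9)
    ab <- areaMatrix(sampleGroup(cfg_b, om, "control"))
    msb <- vapply(split(seq_len(ncol(ab)), site),
                  function(ix) rowMeans(ab[, ix, drop = FALSE]),
                  numeric(nrow(ab)))
    expect_gt(mean(apply(msb, 1, function(x) diff(range(x)))),
              mean(spread))
})

test_that("sample covariance converges to the generating covariance", {
    cfg <- synthConfig(n_subjects_per_group = 650, n_parcels = 360,
                       n_sites = 1, site_shift = 0, site_scale = 0,
                       seed = 2)
    om <- buildPrecision(cfg)
    tru <- solve(om)
    relerr <- function(n) {
        c2 <- synthConfig(n_subjects_per_group = n, n_parcels = 360,
                          n_sites = 1, site_shift = 0, site_scale = 0,
                          seed = 2)
        hm <- averageHemispheres(sampleGroup(c2, om, "control"))
        S <- cov(t(areaMatrix(hm))) / c2$area_sd^2
        ## hemisphere averaging leaves half the hemisphere-noise variance
        diag(S) <- diag(S) - c2$hemi_noise_sd^2 / 2
        norm(S - tru, "F") / norm(tru, "F")
    }
    e650 <- relerr(650)
    expect_lt(e650, 0.35)
    expect_lt(e650, relerr(150))
})

test_that("sample partial correlations converge to the generating ones", {
    cfg <- synthConfig(n_parcels = 24, n_sites = 1, n_latent_clusters = 12,
                       seed = 3)
    om <- buildPrecision(cfg)
    tru <- surfSCN:::pcorrFromPrecision(om)
    mae <- vapply(c(200, 1600), function(n) {
        c2 <- synthConfig(n_subjects_per_group = n, n_parcels = 24,
                          n_sites = 1, n_latent_clusters = 12, seed = 3)
        hm <- averageHemispheres(sampleGroup(c2, om, "control"))
        est <- partialCorrMatrix(partialCorr(hm))
        mean(abs(est[upper.tri(est)] - tru[upper.tri(tru)]))
    }, 0)
    expect_lt(mae[2], mae[1])
})

test_that("cluster sums are predominantly normal and weights decay with distance", {
    fx <- fixture_study(seed = 1)
    a <- areaMatrix(fx$groups$control)
    ad_p <- apply(a, 1, function(v) nortest::ad.test(v)$p.value)
    expect_gt(mean(ad_p > 0.05), 0.6)

    ## generating weight-distance curve decreases monotonically across bins
    cfg <- fx$cfg
    om <- buildPrecision(cfg)
    pc <- abs(surfSCN:::pcorrFromPrecision(om))
    lay <- makeSphereLayout(cfg$n_parcels / 2, cfg$radius)
    d <- surfSCN:::.sphereDist(lay$points, cfg$radius)
    ut <- upper.tri(d)
    bins <- cut(d[ut], quantile(d[ut], seq(0, 1, 0.25)),
                include.lowest = TRUE)
    curve <- tapply(pc[ut], bins, mean)
    expect_true(all(diff(curve) < 0))
})

test_that("table round-trips through the TSV/CSV writers", {
    cfg <- synthConfig(n_subjects_per_group = 12, n_parcels = 20,
                       n_sites = 2, seed = 4)
    st <- synthStudy(cfg)
    td <- withr::local_tempdir()
    writeSurfaceAreaTSV(st, file.path(td, "areas.tsv"))
    writePhenotypeCSV(st, file.path(td, "pheno.csv"))
    writeLayoutCSV(S4Vectors::metadata(st)$layout, file.path(td, "layout.csv"))
    back <- readSurfaceAreaTable(file.path(td, "areas.tsv"),
                                 file.path(td, "pheno.csv"),
                                 file.path(td, "layout.csv"))
    expect_equal(areaMatrix(back), areaMatrix(st), tolerance = 1e-12)
    expect_equal(colData(back)$group, colData(st)$group)
    expect_equal(S4Vectors::metadata(back)$layout$points,
                 S4Vectors::metadata(st)$layout$points,
                 ignore_attr = TRUE, tolerance = 1e-12)
})
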