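make_paired_sae <- function(areas_l, areas_r, n_sites = 1, group = "g") {
    h <- nrow(areas_l); n <- ncol(areas_l)
    a <- rbind(areas_l, areas_r)
    rownames(a) <- c(sprintf("L_%03d", 1:h), sprintf("R_%03d", 1:h))
    pheno <- data.frame(subject_id = sprintf("s%03d", 1:n),
                        age = seq(20, 40, length.out = n),
                        sex = rep(c("F", "M"), length.out = n),
                        group = group,
                        site = paste0("site",
                                      rep(seq_len(n_sites), length.out = n)))
    SurfaceAreaExperiment(a, pheno, hemisphere = rep(c("L", "R"), each = h),
                          pair_id = rep(1:h, 2))
}

test_that("hemisphere averaging is the arithmetic mean of pairs", {
    set.seed(1)
    L <- matrix(runif(5 * 8, 100, 200), 5)
    sae_eq <- make_paired_sae(L, L)
    expect_equal(unname(areaMatrix(averageHemispheres(sae_eq))), unname(L))

    R <- L; L[2, ] <- 10; R[2, ] <- 20
    avg <- areaMatrix(averageHemispheres(make_paired_sae(L, R)))
    expect_equal(unname(avg[2, ]), rep(15, 8))
    expect_equal(dim(avg), c(5, 8))

    a_bad <- rbind(L, R)
    rownames(a_bad) <- c(sprintf("L_%03d", 1:5), sprintf("R_%03d", 1:5))
    bad <- SurfaceAreaExperiment(
        a_bad,
        data.frame(subject_id = sprintf("s%03d", 1:8), age = 30, sex = "F",
                   group = "g", site = "s1"),
        hemisphere = rep(c("L", "R"), each = 5),
        pair_id = c(NA, 2:5, 1:5))
    expect_error(averageHemispheres(bad), "pairing")
})

test_that("ComBat harmonization removes site shifts and keeps covariates", {
    cfg <- synthConfig(n_subjects_per_group = 60, n_parcels = 40,
                       n_sites = 1, site_shift = 0, site_scale = 0, seed = 6)
    one_site <- sampleGroup(cfg, buildPrecision(cfg), "control")
    expect_equal(areaMatrix(harmonizeSites(one_site)),
                 areaMatrix(one_site))

    ## two sites differing by a pure additive shift
    a <- areaMatrix(one_site)
    cd <- as.data.frame(colData(one_site))
    cd$site <- rep(c("s1", "s2"), length.out = ncol(a))
    shifted <- a
    shifted[, cd$site == "s2"] <- shifted[, cd$site == "s2"] + 50
    sae <- SurfaceAreaExperiment(shifted, cd,
                                 hemisphere = rowData(one_site)$hemisphere,
                                 pair_id = rowData(one_site)$pair_id)
    harm <- areaMatrix(harmonizeSites(sae))
    m1 <- rowMeans(harm[, cd$site == "s1"])
    m2 <- rowMeans(harm[, cd$site == "s2"])
    ## the 50 mm^2 shift is removed up to the sampling noise of the batch
    ## estimates (site means of n = 30 at SD ~ 50 mm^2)
    expect_lt(mean(abs(m1 - m2)), 10)
    expect_lt(max(abs(m1 - m2)), 25)

    ## an age effect survives harmonization
    aged <- a + outer(rep(1, nrow(a)), 3 * cd$age)
    sae2 <- SurfaceAreaExperiment(aged, cd,
                                  hemisphere = rowData(one_site)$hemisphere,
                                  pair_id = rowData(one_site)$pair_id)
    harm2 <- areaMatrix(harmonizeSites(sae2))
    slope <- coef(lm(harm2[1, ] ~ cd$age))[2]
    slope0 <- coef(lm(aged[1, ] ~ cd$age))[2]
    expect_equal(unname(slope), unname(slope0), tolerance = 0.15)

    cd_bad <- cd; cd_bad$site <- c("lone", rep("s1", ncol(a) - 1))
    sae3 <- SurfaceAreaExperiment(a, cd_bad,
                                  hemisphere = rowData(one_site)$hemisphere,
                                  pair_id = rowData(one_site)$pair_id)
    expect_error(harmonizeSites(sae3), "at least 2")
})

test_that("cluster aggregation sums member parcels", {
    set.seed(2)
    sae <- averageHemispheres(make_paired_sae(matrix(runif(8), 4, 2),
                                              matrix(runif(8), 4, 2)))
    ident <- aggregateClusters(sae, 1:4)
    expect_equal(unname(areaMatrix(ident)), unname(areaMatrix(sae)))

    total <- aggregateClusters(sae, rep(1, 4))
    expect_equal(unname(areaMatrix(total)[1, ]),
                 unname(colSums(areaMatrix(sae))))

    a <- areaMatrix(sae); a[, 1] <- 1:4
    sae2 <- SurfaceAreaExperiment(a, as.data.frame(colData(sae)),
                                  hemisphere = rep("M", 4), pair_id = 1:4)
    agg <- aggregateClusters(sae2, c(1, 1, 2, 2))
    expect_equal(unname(areaMatrix(agg)[, 1]), c(3, 7))

    expect_error(aggregateClusters(sae, c(1, 1, 2, NA)), "cover")
})

test_that("partial correlations match the residual-regression oracle", {
    ## collider: X3 = X1 + X2 + noise makes rho12 negative at near-zero
    ## marginal correlation
    set.seed(3)
    x1 <- rnorm(500); x2 <- rnorm(500)
    X <- cbind(x1, x2, x1 + x2 + rnorm(500, sd = 0.5))
    net <- partialCorr(X)
    pc <- partialCorrMatrix(net)
    expect_lt(abs(cor(x1, x2)), 0.1)
    expect_lt(pc[1, 2], -0.5)
    expect_equal(pc, oracle_pcorr(X), tolerance = 1e-8,
                 ignore_attr = TRUE)

    ## random 5-variable instances, entrywise oracle agreement
    for (seed in 1:3) {
        set.seed(seed)
        sigma <- crossprod(matrix(rnorm(25), 5)) + diag(5)
        X5 <- fixture_mvn(60, cov2cor(sigma), seed = seed)
        expect_equal(partialCorrMatrix(partialCorr(X5)), oracle_pcorr(X5),
                     tolerance = 1e-8, ignore_attr = TRUE)
    }
})

test_that("partial correlations are scale invariant and need n > p", {
    set.seed(4)
    X <- matrix(rnorm(40 * 6), 40)
    pc <- partialCorrMatrix(partialCorr(X))
    Xs <- X; Xs[, 3] <- X[, 3] * 1000
    expect_equal(partialCorrMatrix(partialCorr(Xs)), pc, tolerance = 1e-9)

    expect_error(partialCorr(matrix(rnorm(5 * 6), 5)), "rank deficient")
    Xdup <- cbind(X, X[, 1])
    expect_error(partialCorr(Xdup), "singular|rank")
})

test_that("sign subnetworks partition the absolute weights", {
    pc <- matrix(c(1, 0.5, -0.3,
                   0.5, 1, 0.2,
                   -0.3, 0.2, 1), 3, 3)
    net <- surfSCN:::.newCovNetwork(pc)
    pos <- signSubnetwork(net, "positive_only")
    neg <- signSubnetwork(net, "negative_only")
    expect_equal(edgeWeights(pos) + edgeWeights(neg), edgeWeights(net))
    expect_equal(edgeWeights(pos)[1, 3], 0)
    expect_equal(edgeWeights(neg)[1, 3], 0.3)
    expect_equal(edgeWeights(neg)[1, 2], 0)

    allpos <- surfSCN:::.newCovNetwork(abs(pc))
    expect_true(all(edgeWeights(signSubnetwork(allpos, "negative_only")) == 0))
    expect_error(signSubnetwork(pos, "negative_only"), "absolute")
})

test_that("distribution checks report identity for self-comparison", {
    fx <- fixture_study(seed = 1)
    g <- fx$groups$control
    net <- fx$nets$control
    rep_self <- distributionChecks(net, net, g, g)
    expect_equal(rep_self$corr$welch_t, 0, tolerance = 1e-10)
    expect_equal(rep_self$corr$f, 1, tolerance = 1e-10)
    expect_equal(rep_self$n_correlations, choose(20, 2))
})

test_that("null-group correlations are centred on zero", {
    fx <- fixture_study(seed = 1)
    pc <- partialCorrMatrix(fx$nets$control)
    v <- pc[upper.tri(pc)]
    expect_lt(abs(mean(v)), 2 * sd(v) / sqrt(length(v)))
})
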