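test_that("cluster centroids average member coordinates and flag degeneracy", {
    lay <- makeSphereLayout(10, 1)
    cc <- clusterCentroids(lay, 1:10)
    expect_equal(unname(cc$centroids), unname(lay$points))
    expect_false(any(cc$flagged))

    ## two antipodal points collapse to the origin and get flagged
    anti <- structure(list(points = rbind(c(0, 0, 1), c(0, 0, -1),
                                          c(1, 0, 0)),
                           r = 1), class = "SphereLayout")
    cc2 <- clusterCentroids(anti, c(1, 1, 2))
    expect_equal(unname(cc2$centroids[1, ]), c(0, 0, 0))
    expect_true(cc2$flagged[1])
    expect_false(cc2$flagged[2])

    ## compact cap: centroid direction stays inside the cap
    set.seed(1)
    az <- runif(20, 0, 0.3); el <- runif(20, 0, 2 * pi)
    cap <- cbind(sin(az) * cos(el), sin(az) * sin(el), cos(az))
    cap_lay <- structure(list(points = cap, r = 1), class = "SphereLayout")
    cc3 <- clusterCentroids(cap_lay, rep(1, 20))
    u <- cc3$centroids[1, ] / sqrt(sum(cc3$centroids[1, ]^2))
    expect_gt(sum(u * c(0, 0, 1)), cos(0.3))

    expect_error(clusterCentroids(lay, c(1:9, NA)), "cover")
})

test_that("geodesics follow the atan2 great-circle formula", {
    same <- rbind(c(0, 0, 1), c(0, 0, 1))
    expect_equal(geodesicMatrix(same, r = 1)$d[1, 2], 0)

    ortho <- rbind(c(1, 0, 0), c(0, 1, 0))
    expect_equal(geodesicMatrix(ortho, r = 1)$d[1, 2], pi / 2)

    anti <- rbind(c(0, 0, 100), c(0, 0, -100))
    expect_equal(geodesicMatrix(anti, r = 100)$d[1, 2], 100 * pi)

    ## off-sphere centroids are projected before evaluation
    off <- rbind(c(0.5, 0, 0), c(0, 2, 0))
    expect_equal(geodesicMatrix(off, r = 1)$d[1, 2], pi / 2)
    expect_error(geodesicMatrix(rbind(c(0, 0, 0), c(1, 0, 0)), r = 1),
                 "zero-norm")

    ## symmetry and spherical triangle inequality on random triples
    set.seed(2)
    pts <- matrix(rnorm(30), 10)
    gd <- geodesicMatrix(pts, r = 50)
    expect_equal(gd$d, t(gd$d))
    for (it in 1:20) {
        ijk <- sample.int(10, 3)
        expect_lte(gd$d[ijk[1], ijk[2]],
                   gd$d[ijk[1], ijk[3]] + gd$d[ijk[3], ijk[2]] + 1e-9)
    }
})

test_that("swp angle arithmetic hits the axis cases exactly", {
    expect_equal(swpAngles(1, 0)$delta, -1)
    expect_equal(swpAngles(0, 1)$delta, 1)
    expect_equal(swpAngles(0.4, 0.4)$delta, 0)
    expect_equal(swpAngles(0, 1)$phi, 1 - sqrt(0.5))
    expect_equal(swpAngles(1, 1)$phi, 0)
})

test_that("a lattice-arranged network has phi = 1 - sqrt(1/2)", {
    fx <- fixture_study(seed = 1)
    d <- fx$gd$d
    n <- nrow(d)
    ## place the sorted weights of a real network onto the lattice order
    w0 <- edgeWeights(fx$nets$control)
    ut <- which(upper.tri(d))
    w <- matrix(0, n, n)
    w[ut[order(d[ut])]] <- sort(w0[upper.tri(w0)], decreasing = TRUE)
    w <- w + t(w)
    s <- smallWorldPropensity(w, fx$gd, n_random = 5, seed = 3)
    expect_equal(s$dC, 0, tolerance = 1e-10)
    expect_equal(s$dL, 1)
    expect_equal(s$phi, 1 - sqrt(0.5), tolerance = 1e-10)
    expect_equal(s$delta, 1, tolerance = 1e-10)
})

test_that("swp nulls are ordered and phi is scale invariant", {
    fx <- fixture_study(seed = 1)
    w <- edgeWeights(fx$nets$control)
    s <- smallWorldPropensity(w, fx$gd, n_random = 5, seed = 3)
    ## lattice rearrangement: more clustered and longer paths than random
    expect_gte(s$C_latt, s$C_rand)
    expect_gte(s$L_latt, s$L_rand)
    expect_gte(s$phi, 0); expect_lte(s$phi, 1)
    expect_gte(s$delta, -1); expect_lte(s$delta, 1)
    s2 <- smallWorldPropensity(2.5 * w, fx$gd, n_random = 5, seed = 3)
    expect_equal(s2$phi, s$phi, tolerance = 1e-10)
    expect_equal(s2$delta, s$delta, tolerance = 1e-10)
})

test_that("distance-weight GAM is exchangeable under identical groups", {
    fx <- fixture_study(seed = 1)
    w <- edgeWeights(fx$nets$control)
    fit <- fitDistanceWeight(w, w, fx$gd, k = 5)
    expect_equal(fit$group_coef, 0, tolerance = 1e-10)
    ## identical groups: the group-separated smooths are not supported
    ## (the chi-squared comparison can be degenerate at ~0 df)
    expect_true(is.na(fit$deviance_p) || fit$deviance_p > 0.1)
    pw <- pointwiseCompare(fit)
    expect_equal(sum(pw$p_adj < 0.05), 0)
    expect_equal(nrow(pw), 100)
})

test_that("a constant group offset is recovered within 2 SE", {
    fx <- fixture_study(seed = 1)
    w <- edgeWeights(fx$nets$control)
    set.seed(4)
    wb <- w + 0.02
    diag(wb) <- 0
    fit <- fitDistanceWeight(w, wb, fx$gd, k = 5)
    expect_lt(abs(fit$group_coef - 0.02), 2 * fit$group_se + 1e-12)
})

test_that("smooth fits recover a monotone decreasing distance curve", {
    set.seed(5)
    n <- 40
    pts <- makeSphereLayout(n, 100)$points
    gd <- geodesicMatrix(pts, r = 100)
    d <- gd$d
    g <- function(x) 0.5 * exp(-x / 60)
    mk <- function(seed) {
        set.seed(seed)
        w <- g(d) + matrix(rnorm(n * n, sd = 0.02), n)
        w <- (w + t(w)) / 2
        w <- pmax(w, 0); diag(w) <- 0
        w
    }
    fit <- fitDistanceWeight(mk(1), mk(2), gd, k = 5)
    gr <- fit$grid
    ## decreasing trend across the grid (penalized splines are not shape
    ## constrained, so strict pointwise monotonicity is not asserted)
    expect_lt(cor(gr$dist, gr$pred_a, method = "spearman"), -0.8)
    expect_true(all(diff(gr$pred_a[10:60]) < 0))
    ## negative average slope over the first quartile of distances
    q <- gr$dist <= quantile(d[upper.tri(d)], 0.25)
    expect_lt(mean(diff(gr$pred_a[q])), 0)

    expect_error(fitDistanceWeight(mk(1), mk(2),
                                   matrix(0, n, n), k = 5),
                 "unique distances")
})

test_that("pointwise tests localise an injected mid-range bump", {
    set.seed(6)
    n <- 40
    pts <- makeSphereLayout(n, 100)$points
    gd <- geodesicMatrix(pts, r = 100)
    d <- gd$d
    base <- function(seed) {
        set.seed(seed)
        w <- 0.4 * exp(-d / 80) + matrix(rnorm(n * n, sd = 0.01), n)
        w <- (w + t(w)) / 2; w <- pmax(w, 0); diag(w) <- 0
        w
    }
    wa <- base(1)
    wb <- base(2)
    mid <- d > 120 & d < 200
    wb[mid] <- wb[mid] + 0.08
    fit <- fitDistanceWeight(wa, wb, gd, k = 5)
    pw <- pointwiseCompare(fit)
    sig <- pw$dist[pw$p_adj < 0.05 & abs(pw$diff) > 0.02]
    expect_gt(length(sig), 0)
    expect_true(mean(sig > 100 & sig < 220) > 0.8)
})

test_that("BH adjustment is the identity on unit p-values", {
    expect_equal(fdrBH(rep(1, 100)), rep(1, 100))
})
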