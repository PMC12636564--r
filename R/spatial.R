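#' Cluster centroids on the spherical surface
#'
#' Per-cluster arithmetic mean of member parcel coordinates. Centroids of
#' non-compact clusters can fall well inside the sphere; any centroid whose
#' norm deviates from the sphere radius by more than 25% is flagged for
#' inspection.
#'
#' @param layout a \code{SphereLayout} (points for the parcels being
#'   clustered, in row order matching \code{labels}).
#' @param labels integer cluster assignment per parcel.
#' @return list with \code{centroids} (K x 3), \code{r}, and
#'   \code{flagged} (logical per cluster).
#' @export
clusterCentroids <- function(layout, labels) {
    stopifnot(inherits(layout, "SphereLayout"))
    pts <- layout$points
    labels <- as.integer(labels)
    if (length(labels) != nrow(pts) || anyNA(labels))
        stop("labels must cover every layout point")
    ks <- sort(unique(labels))
    cent <- t(vapply(ks, function(k)
        colMeans(pts[labels == k, , drop = FALSE]), numeric(3)))
    rownames(cent) <- sprintf("cluster_%02d", ks)
    norms <- sqrt(rowSums(cent^2))
    list(centroids = cent, r = layout$r,
         flagged = abs(norms - layout$r) > 0.25 * layout$r)
}

#' Great-circle distance matrix between centroids
#'
#' \eqn{d_{ij} = r \cdot \mathrm{atan2}(\|P_i \times P_j\|, P_i \cdot
#' P_j)}. Centroids are re-projected to radius r before evaluation, since
#' the formula presumes on-sphere points.
#'
#' @param centroids K x 3 matrix (or the list from
#'   \code{\link{clusterCentroids}}).
#' @param r sphere radius (mm); taken from the centroid list when omitted.
#' @return list of class \code{GeodesicMatrix}: \code{d} (symmetric, zero
#'   diagonal, entries <= pi*r), \code{centroids} (projected), \code{r}.
#' @export
geodesicMatrix <- function(centroids, r = NULL) {
    if (is.list(centroids) && !is.null(centroids$centroids)) {
        if (is.null(r)) r <- centroids$r
        centroids <- centroids$centroids
    }
    stopifnot(is.numeric(r), r > 0)
    cent <- as.matrix(centroids)
    norms <- sqrt(rowSums(cent^2))
    if (any(norms < 1e-9 * r))
        stop("zero-norm centroid: geodesic undefined")
    proj <- cent * (r / norms)
    d <- .sphereDist(proj, r)
    dimnames(d) <- list(rownames(cent), rownames(cent))
    structure(list(d = d, centroids = proj, r = r),
              class = "GeodesicMatrix")
}

## assign a weight multiset onto the upper-triangle edge slots in a given
## slot order, returning the full symmetric matrix
.assignWeights <- function(n, slot_order, weights_sorted) {
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w))
    w[ut[slot_order]] <- weights_sorted
    w + t(w)
}

#' Small-world angle and propensity from divergence ratios
#'
#' The deterministic arithmetic shared by \code{\link{smallWorldPropensity}}:
#' given the clamped clustering and path-length divergence ratios,
#' \eqn{\phi = 1 - \sqrt{(\Delta C^2 + \Delta L^2)/2}},
#' \eqn{\alpha = \mathrm{atan2}(\Delta L, \Delta C)} and
#' \eqn{\delta = 4\alpha/\pi - 1}, so (dC, dL) = (1, 0) gives delta -1,
#' equal ratios give 0, and (0, 1) gives +1.
#'
#' @param dC,dL divergence ratios in [0, 1].
#' @return list with \code{phi}, \code{alpha}, \code{delta}.
#' @export
swpAngles <- function(dC, dL) {
    stopifnot(dC >= 0, dC <= 1, dL >= 0, dL <= 1)
    alpha <- atan2(dL, dC)
    list(phi = 1 - sqrt((dC^2 + dL^2) / 2), alpha = alpha,
         delta = 4 * alpha / pi - 1)
}

#' Small-world propensity with spatial null models
#'
#' Compares the observed network against (i) a lattice null in which the
#' largest edge weights are placed at the shortest geodesic distances
#' (weights sorted descending assigned to edge slots sorted by distance
#' ascending, ties broken by index) and (ii) an ensemble of random nulls in
#' which the weights are shuffled over edge slots. With clustering and path
#' length of the observed and null networks,
#' \eqn{\Delta C = (C_{latt} - C_{obs}) / (C_{latt} - C_{rand})} and
#' \eqn{\Delta L = (L_{obs} - L_{rand}) / (L_{latt} - L_{rand})}, each
#' clamped to [0, 1]; \eqn{\phi = 1 - \sqrt{(\Delta C^2 + \Delta L^2)/2}},
#' \eqn{\alpha = \mathrm{atan2}(\Delta L, \Delta C)} and
#' \eqn{\delta = 4\alpha/\pi - 1} (-1: clustering maximally different from
#' the lattice; +1: path length maximally different from random).
#'
#' @param w symmetric nonnegative weight matrix, zero diagonal.
#' @param gd a \code{GeodesicMatrix} (or plain distance matrix) conformable
#'   with \code{w}.
#' @param n_random size of the random-null ensemble (default 10).
#' @param seed integer seed for the shuffles.
#' @return list of class \code{SWPResult}: \code{phi}, \code{delta},
#'   \code{alpha}, \code{dC}, \code{dL}, observed/null metric values, and
#'   \code{degenerate} flags.
#' @export
smallWorldPropensity <- function(w, gd, n_random = 10, seed = 1L) {
    .assertWeights(w)
    d <- if (inherits(gd, "GeodesicMatrix")) gd$d else gd
    stopifnot(all(dim(d) == dim(w)))
    n <- nrow(w)
    ut <- upper.tri(w)
    wt <- w[ut]; dd <- d[ut]
    ## lattice: strongest weights at shortest distances
    w_latt <- .assignWeights(n, order(dd), sort(wt, decreasing = TRUE))
    C_obs <- globalClustering(w); L_obs <- pathLength(w)
    C_latt <- globalClustering(w_latt); L_latt <- pathLength(w_latt)
    rand <- .withSeed(seed, lapply(seq_len(n_random), function(b) {
        w_r <- .assignWeights(n, sample.int(length(wt)), wt)
        c(C = globalClustering(w_r), L = pathLength(w_r))
    }))
    C_rand <- mean(vapply(rand, `[[`, 0, "C"))
    L_rand <- mean(vapply(rand, `[[`, 0, "L"))
    ratio <- function(num, den) {
        if (abs(den) < 1e-12) {
            list(val = if (num > 0) 1 else 0, degen = TRUE)
        } else list(val = min(max(num / den, 0), 1), degen = FALSE)
    }
    rc <- ratio(C_latt - C_obs, C_latt - C_rand)
    rl <- ratio(L_obs - L_rand, L_latt - L_rand)
    dC <- rc$val; dL <- rl$val
    ang <- swpAngles(dC, dL)
    structure(list(phi = ang$phi, delta = ang$delta, alpha = ang$alpha,
                   dC = dC, dL = dL,
                   C_obs = C_obs, C_latt = C_latt, C_rand = C_rand,
                   L_obs = L_obs, L_latt = L_latt, L_rand = L_rand,
                   degenerate = c(C = rc$degen, L = rl$degen)),
              class = "SWPResult")
}

#' Smooth distance-weight group model
#'
#' Gaussian GAM of edge weight on geodesic distance: per-group thin-plate
#' smooths of distance (basis dimension k) plus a parametric group term,
#' fitted to the pooled upper-triangle edge observations of the two groups
#' with REML smoothness selection. The full model is compared with a
#' reduced model sharing one smooth across groups by a chi-squared analysis
#' of deviance, and per-group predictions with standard errors are stored
#' at 100 equidistant grid points spanning the observed distance range.
#'
#' @param w_a,w_b weight matrices of the two groups (group labels
#'   \code{"a"} and \code{"b"}; \code{"a"} is the reference level).
#' @param gd a \code{GeodesicMatrix} or distance matrix shared by both.
#' @param k smooth basis dimension (default 5).
#' @return list of class \code{DistanceWeightModel}: fitted \code{full} and
#'   \code{reduced} mgcv models, coefficient/smooth summaries, the deviance
#'   comparison, and the prediction \code{grid}.
#' @export
fitDistanceWeight <- function(w_a, w_b, gd, k = 5) {
    .assertWeights(w_a); .assertWeights(w_b)
    d <- if (inherits(gd, "GeodesicMatrix")) gd$d else gd
    stopifnot(all(dim(d) == dim(w_a)), all(dim(w_a) == dim(w_b)), k >= 3)
    ut <- upper.tri(d)
    dd <- d[ut]
    if (length(unique(dd)) <= k)
        stop("basis dimension k exceeds the number of unique distances")
    dat <- data.frame(
        weight = c(w_a[ut], w_b[ut]),
        dist = rep(dd, 2),
        group = factor(rep(c("a", "b"), each = sum(ut))))
    full <- mgcv::gam(weight ~ group + s(dist, by = group, k = k),
                      data = dat, method = "REML")
    reduced <- mgcv::gam(weight ~ group + s(dist, k = k),
                         data = dat, method = "REML")
    sm <- summary(full)
    dev_cmp <- anova(reduced, full, test = "Chisq")
    grid_d <- seq(min(dd), max(dd), length.out = 100)
    newd <- data.frame(dist = rep(grid_d, 2),
                       group = factor(rep(c("a", "b"), each = 100)))
    pr <- predict(full, newdata = newd, se.fit = TRUE)
    grid <- data.frame(dist = grid_d,
                       pred_a = pr$fit[1:100], se_a = pr$se.fit[1:100],
                       pred_b = pr$fit[101:200], se_b = pr$se.fit[101:200])
    structure(list(
        full = full, reduced = reduced, k = k,
        group_coef = sm$p.table["groupb", "Estimate"],
        group_se = sm$p.table["groupb", "Std. Error"],
        group_t = sm$p.table["groupb", "t value"],
        group_p = sm$p.table["groupb", "Pr(>|t|)"],
        smooth_table = sm$s.table,
        deviance_diff = dev_cmp$Deviance[2],
        deviance_p = dev_cmp$`Pr(>Chi)`[2],
        grid = grid), class = "DistanceWeightModel")
}

#' Pointwise group comparison along the distance grid
#'
#' At each of the 100 grid distances, \eqn{z = (\hat y_a - \hat y_b) /
#' \sqrt{SE_a^2 + SE_b^2}} with a two-sided normal p-value,
#' Benjamini-Hochberg adjusted over the grid.
#'
#' @param model a \code{DistanceWeightModel}.
#' @return data.frame with \code{dist}, \code{diff}, \code{se}, \code{z},
#'   \code{p}, \code{p_adj}.
#' @export
pointwiseCompare <- function(model) {
    stopifnot(inherits(model, "DistanceWeightModel"))
    g <- model$grid
    se <- sqrt(g$se_a^2 + g$se_b^2)
    z <- (g$pred_a - g$pred_b) / se
    p <- 2 * pnorm(-abs(z))
    data.frame(dist = g$dist, diff = g$pred_a - g$pred_b, se = se, z = z,
               p = p, p_adj = fdrBH(p))
}
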