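#' Average paired hemispheres
#'
#' Reduces a paired L/R table to hemisphere-level parcels by taking the
#' arithmetic mean of each left/right pair.
#'
#' @param sae a \linkS4class{SurfaceAreaExperiment} with hemisphere labels
#'   "L"/"R" and a complete \code{pair_id}.
#' @return a \linkS4class{SurfaceAreaExperiment} with half the parcels,
#'   hemisphere \code{"M"}.
#' @export
averageHemispheres <- function(sae) {
    stopifnot(is(sae, "SurfaceAreaExperiment"))
    rd <- rowData(sae)
    if (any(is.na(rd$pair_id)) || !setequal(unique(rd$hemisphere), c("L", "R")))
        stop("table must have complete L/R pairing metadata")
    left <- which(rd$hemisphere == "L")[order(rd$pair_id[rd$hemisphere == "L"])]
    right <- which(rd$hemisphere == "R")[order(rd$pair_id[rd$hemisphere == "R"])]
    if (length(left) != length(right) ||
        !identical(rd$pair_id[left], rd$pair_id[right]))
        stop("unpaired parcels: each pair_id needs one L and one R parcel")
    a <- areaMatrix(sae)
    m <- (a[left, , drop = FALSE] + a[right, , drop = FALSE]) / 2
    rownames(m) <- sprintf("M_%03d", rd$pair_id[left])
    out <- SurfaceAreaExperiment(m, as.data.frame(colData(sae)),
                                 hemisphere = rep("M", nrow(m)),
                                 pair_id = rd$pair_id[left])
    S4Vectors::metadata(out) <- S4Vectors::metadata(sae)
    out
}

#' ComBat scan-site harmonization
#'
#' Removes per-site additive and multiplicative batch effects from the area
#' assay with the parametric empirical-Bayes ComBat location-scale model,
#' protecting sex, age and group as biological covariates. With a single
#' site the input is returned unchanged.
#'
#' @param sae a \linkS4class{SurfaceAreaExperiment}; \code{colData} provides
#'   the batch (\code{site}) and the protected covariates.
#' @return harmonized \linkS4class{SurfaceAreaExperiment}, same shape.
#' @export
harmonizeSites <- function(sae) {
    stopifnot(is(sae, "SurfaceAreaExperiment"))
    cd <- as.data.frame(colData(sae))
    if (anyNA(cd[c("age", "sex", "group", "site")]))
        stop("covariates must be complete")
    sites <- table(cd$site)
    if (length(sites) == 1) return(sae)
    if (any(sites < 2)) stop("every site needs at least 2 subjects")
    terms <- c("age",
               if (length(unique(cd$sex)) > 1) "sex",
               if (length(unique(cd$group)) > 1) "group")
    mod <- model.matrix(as.formula(paste("~", paste(terms, collapse = "+"))),
                        data = cd)
    log <- utils::capture.output(
        adj <- sva::ComBat(dat = areaMatrix(sae), batch = cd$site,
                           mod = mod, par.prior = TRUE,
                           prior.plots = FALSE))
    out <- sae
    SummarizedExperiment::assay(out, "area") <- adj
    out
}

#' Sum parcels into clusters
#'
#' @param sae a \linkS4class{SurfaceAreaExperiment} (hemisphere-level).
#' @param labels integer cluster assignment, one label in 1..K per parcel.
#' @return \linkS4class{SurfaceAreaExperiment} with one row per cluster,
#'   each the column-wise sum of its member parcels.
#' @export
aggregateClusters <- function(sae, labels) {
    stopifnot(is(sae, "SurfaceAreaExperiment"))
    labels <- as.integer(labels)
    if (length(labels) != nrow(sae) || anyNA(labels))
        stop("labels must cover every parcel")
    a <- areaMatrix(sae)
    agg <- rowsum(a, group = labels)
    rownames(agg) <- sprintf("cluster_%02d", sort(unique(labels)))
    out <- SurfaceAreaExperiment(agg, as.data.frame(colData(sae)),
                                 hemisphere = rep("M", nrow(agg)),
                                 pair_id = NA_integer_)
    S4Vectors::metadata(out) <- S4Vectors::metadata(sae)
    S4Vectors::metadata(out)$cluster_labels <- labels
    out
}

#' Partial-correlation network by covariance inversion
#'
#' Estimates the signed partial-correlation matrix of the variables (rows of
#' the area assay, or columns of a plain subjects-by-variables matrix) by
#' inverting the unbiased sample covariance: with precision
#' \eqn{\Omega = \Sigma^{-1}}, \eqn{\rho_{ij} = -\Omega_{ij} /
#' \sqrt{\Omega_{ii}\Omega_{jj}}}, diagonal set to 1. Requires more subjects
#' than variables; rank-deficient input is a hard error (reduce
#' dimensionality by clustering first).
#'
#' @param x \linkS4class{SurfaceAreaExperiment} or numeric matrix with
#'   subjects in rows and variables in columns.
#' @param group label stored on the resulting network.
#' @return a \linkS4class{CovNetwork} in \code{"absolute"} mode.
#' @export
partialCorr <- function(x, group = "") {
    X <- if (is(x, "SurfaceAreaExperiment")) t(areaMatrix(x)) else as.matrix(x)
    n <- nrow(X); p <- ncol(X)
    if (n <= p)
        stop(sprintf(
            "covariance is rank deficient (%d subjects <= %d variables)",
            n, p))
    sigma <- cov(X)                       # unbiased (n-1) estimator
    omega <- tryCatch(solve(sigma), error = function(e)
        stop("singular covariance matrix: ", conditionMessage(e)))
    pc <- pcorrFromPrecision((omega + t(omega)) / 2)
    pc <- pmin(pmax(pc, -1), 1)
    if (!is.null(colnames(X)))
        dimnames(pc) <- list(colnames(X), colnames(X))
    else
        dimnames(pc) <- NULL
    .newCovNetwork(pc, mode = "absolute", group = group)
}

#' Sign-restricted subnetwork
#'
#' Keeps edge-weight magnitudes only where the signed partial correlation
#' has the admitted sign; excluded edges get weight 0. The vertex set is
#' unchanged so metrics stay comparable across modes.
#'
#' @param net a \linkS4class{CovNetwork} in \code{"absolute"} mode.
#' @param mode \code{"positive_only"} or \code{"negative_only"} (or
#'   \code{"absolute"}, a no-op).
#' @return a \linkS4class{CovNetwork} in the requested mode.
#' @export
signSubnetwork <- function(net, mode = c("positive_only", "negative_only",
                                         "absolute")) {
    stopifnot(is(net, "CovNetwork"))
    mode <- match.arg(mode)
    if (networkMode(net) != "absolute")
        stop("sign subnetworks are taken from an absolute-mode network")
    if (mode == "absolute") return(net)
    pc <- partialCorrMatrix(net)
    w <- abs(pc)
    diag(w) <- 0
    mask <- if (mode == "positive_only") pc > 0 else pc < 0
    diag(mask) <- FALSE
    w[!mask] <- 0
    .newCovNetwork(pc, weights = w, mode = mode, group = net@group)
}

#' Distributional checks on cluster areas and network correlations
#'
#' Reports, per cluster and group, Anderson-Darling normality p-values of
#' the cluster areas and between-group F-tests of the area variances
#' (BH-adjusted within the family), and on the vectorized upper-triangle
#' partial correlations of the two networks: Shapiro-Wilk normality per
#' group, Welch's t-test of means, and the two-sided F-test of variances
#' (ratio = group A variance over group B variance, so F < 1 flags larger
#' correlation magnitudes in group B).
#'
#' @param net_a,net_b \linkS4class{CovNetwork}s of the two groups.
#' @param sae_a,sae_b the cluster-aggregated
#'   \linkS4class{SurfaceAreaExperiment}s the networks were built from.
#' @return list of class \code{scnDistributionReport}.
#' @export
distributionChecks <- function(net_a, net_b, sae_a, sae_b) {
    stopifnot(is(net_a, "CovNetwork"), is(net_b, "CovNetwork"),
              is(sae_a, "SurfaceAreaExperiment"),
              is(sae_b, "SurfaceAreaExperiment"))
    if (!all(dim(net_a) == dim(net_b)) || nrow(sae_a) != nrow(sae_b))
        stop("mismatched dimensions between groups")
    aa <- areaMatrix(sae_a); ab <- areaMatrix(sae_b)
    ad_p <- cbind(a = apply(aa, 1, function(v) nortest::ad.test(v)$p.value),
                  b = apply(ab, 1, function(v) nortest::ad.test(v)$p.value))
    ftests <- lapply(seq_len(nrow(aa)), function(i)
        var.test(aa[i, ], ab[i, ]))
    area_f <- data.frame(
        cluster = rownames(aa),
        f = vapply(ftests, function(t) unname(t$statistic), 0),
        p = vapply(ftests, function(t) t$p.value, 0))
    area_f$p_adj <- p.adjust(area_f$p, method = "BH")
    ra <- .upperTri(partialCorrMatrix(net_a))
    rb <- .upperTri(partialCorrMatrix(net_b))
    ft <- var.test(ra, rb)
    tt <- t.test(ra, rb, var.equal = FALSE)
    out <- list(
        ad_normality_p = ad_p,
        prop_normal = colMeans(ad_p > 0.05),
        area_variance_f = area_f,
        n_correlations = length(ra),
        corr = list(
            shapiro_p = c(a = shapiro.test(ra)$p.value,
                          b = shapiro.test(rb)$p.value),
            mean = c(a = mean(ra), b = mean(rb)),
            sd = c(a = sd(ra), b = sd(rb)),
            welch_t = unname(tt$statistic), welch_p = tt$p.value,
            f = unname(ft$statistic), f_p = ft$p.value))
    class(out) <- "scnDistributionReport"
    out
}
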