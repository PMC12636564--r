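## Feature space for all clustering steps: rows of the parcel
## partial-correlation matrix under Euclidean distance. Ward's criterion
## needs Euclidean geometry, and a parcel's row profile is its covariance
## fingerprint with the rest of the cortex.
.pcorrFeatureDist <- function(pcorr) {
    .assertSymmetric(pcorr, "partial-correlation matrix")
    if (max(abs(diag(pcorr) - 1)) > 1e-6)
        stop("partial-correlation matrix must have unit diagonal")
    dist(pcorr)
}

#' Ward hierarchical clustering of parcels
#'
#' Agglomerative clustering (Ward's criterion, implemented as
#' \code{hclust(method = "ward.D2")} on Euclidean distances between rows of
#' the partial-correlation matrix) cut at K clusters.
#'
#' @param pcorr symmetric parcel partial-correlation matrix, unit diagonal.
#' @param K number of clusters, 2..nrow(pcorr).
#' @param quality if TRUE also compute silhouette and Dunn scores.
#' @return list of class \code{ClusterSolution}: \code{labels} (1..K),
#'   \code{K}, and when requested \code{silhouette} and \code{dunn}.
#' @export
wardCluster <- function(pcorr, K, quality = FALSE) {
    d <- .pcorrFeatureDist(pcorr)
    n <- nrow(pcorr)
    if (K < 1 || K > n) stop("K out of range")
    hc <- hclust(d, method = "ward.D2")
    labels <- unname(cutree(hc, k = K))
    sol <- list(labels = labels, K = as.integer(K))
    if (quality && K >= 2 && K < n) {
        q <- clusterQuality(pcorr, labels)
        sol$silhouette <- q$silhouette
        sol$dunn <- q$dunn
    }
    class(sol) <- "ClusterSolution"
    sol
}

#' Cluster separation and compactness scores
#'
#' Mean silhouette width and the Dunn index (minimum between-cluster
#' distance over maximum within-cluster diameter), both on the same
#' Euclidean row-profile distances used for clustering. A zero maximum
#' intra-cluster diameter makes the Dunn index infinite; it is guarded to a
#' large finite sentinel (1e6) and flagged.
#'
#' @inheritParams wardCluster
#' @param labels cluster assignment from \code{\link{wardCluster}}.
#' @return list with \code{silhouette}, \code{dunn} and \code{dunn_degenerate}.
#' @export
clusterQuality <- function(pcorr, labels) {
    d <- .pcorrFeatureDist(pcorr)
    labels <- as.integer(labels)
    if (length(unique(labels)) < 2)
        stop("quality scores need at least 2 clusters")
    sil <- cluster::silhouette(labels, d)
    dm <- as.matrix(d)
    ks <- sort(unique(labels))
    diam <- max(vapply(ks, function(k) {
        idx <- which(labels == k)
        if (length(idx) < 2) 0 else max(dm[idx, idx])
    }, 0))
    sep <- min(vapply(seq_along(ks)[-1], function(i) {
        min(vapply(seq_len(i - 1), function(j)
            min(dm[labels == ks[i], labels == ks[j], drop = FALSE]), 0))
    }, 0))
    degenerate <- diam == 0
    dunn <- if (degenerate) 1e6 else sep / diam
    list(silhouette = mean(sil[, "sil_width"]), dunn = dunn,
         dunn_degenerate = degenerate)
}

## partial correlations of hemisphere-level parcels from a paired table,
## optionally restricted to one hemisphere or a subject subsample
.parcelPcorr <- function(sae, hemisphere = NULL, subjects = NULL) {
    if (!is.null(subjects)) sae <- sae[, subjects]
    if (!is.null(hemisphere)) {
        sae <- sae[rowData(sae)$hemisphere == hemisphere, ]
    } else if (all(c("L", "R") %in% rowData(sae)$hemisphere)) {
        sae <- averageHemispheres(sae)
    }
    partialCorrMatrix(partialCorr(sae))
}

#' Clustering consistency by adjusted Rand index
#'
#' \code{ari_hemi}: ARI between labelings obtained separately from the
#' left-parcel and right-parcel partial correlations (parcels correspond by
#' pair index). \code{ari_subsample}: mean ARI between labelings from
#' random subject subsamples and the full-sample labeling.
#'
#' @param sae_controls paired-hemisphere control
#'   \linkS4class{SurfaceAreaExperiment}.
#' @param K cluster count.
#' @param n_subsamples number of random subsamples (default 20).
#' @param subsample_size subjects per subsample (default half the sample).
#' @param seed integer seed for the subsampling.
#' @return list with \code{ari_hemi} and \code{ari_subsample}.
#' @export
consistencyARI <- function(sae_controls, K, n_subsamples = 20,
                           subsample_size = floor(ncol(sae_controls) / 2),
                           seed = 1L) {
    stopifnot(is(sae_controls, "SurfaceAreaExperiment"),
              subsample_size < ncol(sae_controls))
    rd <- rowData(sae_controls)
    if (!all(c("L", "R") %in% rd$hemisphere))
        stop("consistency needs a paired-hemisphere table")
    lab_l <- wardCluster(.parcelPcorr(sae_controls, "L"), K)$labels
    lab_r <- wardCluster(.parcelPcorr(sae_controls, "R"), K)$labels
    ari_hemi <- mclust::adjustedRandIndex(lab_l, lab_r)
    full <- wardCluster(.parcelPcorr(sae_controls), K)$labels
    aris <- .withSeed(seed, vapply(seq_len(n_subsamples), function(b) {
        idx <- sample.int(ncol(sae_controls), subsample_size)
        lab_b <- wardCluster(.parcelPcorr(sae_controls, subjects = idx),
                             K)$labels
        mclust::adjustedRandIndex(lab_b, full)
    }, 0))
    list(ari_hemi = ari_hemi, ari_subsample = mean(aris))
}

#' Select the cluster count by composite quality/consistency score
#'
#' For each seed and each candidate K: mean silhouette, Dunn index,
#' left/right-hemisphere ARI and mean subsample ARI are computed, min-max
#' normalised across the K range, and summed; the K maximizing the sum is
#' chosen (ties toward smaller K). The reported \code{modal_K} is the mode
#' of the per-seed choices.
#'
#' @inheritParams consistencyARI
#' @param K_range integer vector of candidate cluster counts.
#' @param n_seeds number of repetitions with different subsampling seeds.
#' @return list of class \code{SelectionReport}: per-seed score tables,
#'   \code{chosen_K} per seed, \code{modal_K}.
#' @export
selectK <- function(sae_controls, K_range, n_seeds = 10, n_subsamples = 20,
                    subsample_size = floor(ncol(sae_controls) / 2),
                    seed = 1L) {
    K_range <- sort(unique(as.integer(K_range)))
    if (!length(K_range)) stop("empty K range")
    h <- sum(rowData(sae_controls)$hemisphere %in% c("L", "M"))
    stopifnot(min(K_range) >= 2, max(K_range) <= h - 1)
    pc_full <- .parcelPcorr(sae_controls)
    base <- lapply(K_range, function(K) {
        sol <- wardCluster(pc_full, K, quality = TRUE)
        list(sil = sol$silhouette, dunn = sol$dunn)
    })
    per_seed <- lapply(seq_len(n_seeds), function(s) {
        cons <- lapply(K_range, function(K)
            consistencyARI(sae_controls, K, n_subsamples, subsample_size,
                           seed = .childSeed(seed, 97L * s + K)))
        tab <- data.frame(
            K = K_range,
            silhouette = vapply(base, `[[`, 0, "sil"),
            dunn = vapply(base, `[[`, 0, "dunn"),
            ari_hemi = vapply(cons, `[[`, 0, "ari_hemi"),
            ari_subsample = vapply(cons, `[[`, 0, "ari_subsample"))
        tab$composite <- .minmax(tab$silhouette) + .minmax(tab$dunn) +
            .minmax(tab$ari_hemi) + .minmax(tab$ari_subsample)
        tab$chosen <- seq_along(K_range) == which.max(tab$composite)
        tab
    })
    chosen <- vapply(per_seed, function(tab) tab$K[tab$chosen], 0L)
    counts <- table(chosen)
    modal <- min(as.integer(names(counts)[counts == max(counts)]))
    out <- list(per_seed = per_seed, chosen_K = chosen, modal_K = modal,
                K_range = K_range)
    class(out) <- "SelectionReport"
    out
}
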