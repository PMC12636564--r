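#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors DataFrame metadata SimpleList
NULL

#' SurfaceAreaExperiment: subjects-by-parcel cortical surface areas
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one assay,
#' \code{"area"}, with parcels (or parcel clusters) as rows and subjects as
#' columns. Row metadata records the hemisphere of each parcel (\code{"L"},
#' \code{"R"}, or \code{"M"} once hemispheres have been averaged) and, for
#' paired layouts, the index linking a parcel to its contralateral homologue.
#' Column metadata carries the phenotypes used throughout the pipeline:
#' \code{subject_id}, \code{age} (years), \code{sex}, \code{group} and
#' \code{site}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @name SurfaceAreaExperiment-class
#' @exportClass SurfaceAreaExperiment
setClass("SurfaceAreaExperiment", contains = "SummarizedExperiment")

setValidity("SurfaceAreaExperiment", function(object) {
    msg <- NULL
    if (!"area" %in% names(assays(object)))
        msg <- c(msg, "assay 'area' is required")
    else {
        a <- assay(object, "area")
        if (!is.numeric(a)) msg <- c(msg, "assay 'area' must be numeric")
        if (any(!is.finite(a))) msg <- c(msg, "assay 'area' has non-finite values")
    }
    rd <- rowData(object)
    if (!"hemisphere" %in% colnames(rd))
        msg <- c(msg, "rowData must contain 'hemisphere'")
    else if (!all(rd$hemisphere %in% c("L", "R", "M")))
        msg <- c(msg, "hemisphere must be 'L', 'R' or 'M'")
    cd <- colData(object)
    need <- c("subject_id", "age", "sex", "group", "site")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData missing: ", paste(miss, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' Construct a SurfaceAreaExperiment
#'
#' @param areas numeric matrix of surface areas in mm^2, parcels in rows and
#'   subjects in columns (a subjects-by-parcels table is accepted and
#'   transposed when row/column names make the orientation unambiguous is NOT
#'   attempted; pass parcels in rows).
#' @param phenotypes data.frame with one row per subject and columns
#'   \code{subject_id}, \code{age}, \code{sex}, \code{group}, \code{site}.
#' @param hemisphere character vector, one of "L","R","M" per parcel.
#' @param pair_id integer vector linking each parcel to its contralateral
#'   partner (same value for the two members of a pair); NA when unpaired.
#' @param layout optional \code{SphereLayout} stored in \code{metadata()}.
#' @return a \linkS4class{SurfaceAreaExperiment}.
#' @export
SurfaceAreaExperiment <- function(areas, phenotypes, hemisphere,
                                  pair_id = NA_integer_, layout = NULL) {
    areas <- as.matrix(areas)
    stopifnot(nrow(phenotypes) == ncol(areas),
              length(hemisphere) == nrow(areas))
    if (is.null(rownames(areas)))
        rownames(areas) <- sprintf("parcel_%03d", seq_len(nrow(areas)))
    if (is.null(colnames(areas)))
        colnames(areas) <- as.character(phenotypes$subject_id)
    rd <- DataFrame(parcel_id = rownames(areas),
                    hemisphere = hemisphere,
                    pair_id = rep_len(pair_id, nrow(areas)))
    cd <- DataFrame(phenotypes)
    md <- if (is.null(layout)) list() else list(layout = layout)
    se <- SummarizedExperiment(assays = SimpleList(area = areas),
                               rowData = rd, colData = cd, metadata = md)
    new("SurfaceAreaExperiment", se)
}

#' CovNetwork: signed partial-correlation network on clusters
#'
#' The structural covariance network: a symmetric matrix of signed partial
#' correlations between cluster surface areas (unit diagonal) together with
#' the nonnegative edge-weight matrix used by all graph metrics. In
#' \code{"absolute"} mode weights are the absolute partial correlations with
#' zero diagonal; \code{"positive_only"} / \code{"negative_only"} keep the
#' magnitude only where the underlying correlation has the admitted sign.
#'
#' @slot pcorr symmetric numeric matrix of partial correlations, diagonal 1.
#' @slot weights symmetric nonnegative matrix, zero diagonal.
#' @slot mode character, one of "absolute", "positive_only", "negative_only".
#' @slot group character label of the group the network describes.
#' @name CovNetwork-class
#' @exportClass CovNetwork
setClass("CovNetwork",
         representation(pcorr = "matrix", weights = "matrix",
                        mode = "character", group = "character"))

setValidity("CovNetwork", function(object) {
    msg <- NULL
    p <- object@pcorr; w <- object@weights
    if (!isTRUE(all.equal(p, t(p), tolerance = 1e-8)))
        msg <- c(msg, "pcorr must be symmetric")
    if (any(abs(p) > 1 + 1e-8))
        msg <- c(msg, "partial correlations must lie in [-1, 1]")
    if (max(abs(diag(p) - 1)) > 1e-8)
        msg <- c(msg, "pcorr diagonal must be 1")
    if (any(w < 0)) msg <- c(msg, "weights must be nonnegative")
    if (max(abs(diag(w))) > 0) msg <- c(msg, "weight diagonal must be 0")
    if (!isTRUE(all.equal(w, t(w), tolerance = 1e-8)))
        msg <- c(msg, "weights must be symmetric")
    if (!object@mode %in% c("absolute", "positive_only", "negative_only"))
        msg <- c(msg, "unknown mode")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn CovNetwork-class number of vertices (clusters).
#' @param x,object a CovNetwork.
#' @export
setMethod("dim", "CovNetwork", function(x) dim(x@pcorr))

setMethod("show", "CovNetwork", function(object) {
    n <- nrow(object@pcorr)
    w <- edgeWeights(object)
    ut <- w[upper.tri(w)]
    cat(sprintf("CovNetwork: %d vertices, mode '%s'%s\n", n, object@mode,
                if (nzchar(object@group)) paste0(", group '", object@group, "'")
                else ""))
    cat(sprintf("  nonzero edges: %d / %d; mean |weight| %.4f\n",
                sum(ut > 0), length(ut), mean(ut)))
})

setMethod("show", "SurfaceAreaExperiment", function(object) {
    cat(sprintf("SurfaceAreaExperiment: %d parcels x %d subjects\n",
                nrow(object), ncol(object)))
    cat(sprintf("  hemispheres: %s; groups: %s; sites: %s\n",
                paste(unique(rowData(object)$hemisphere), collapse = "/"),
                paste(unique(colData(object)$group), collapse = "/"),
                paste(sort(unique(colData(object)$site)), collapse = "/")))
})

#' Accessors
#'
#' \code{partialCorrMatrix} returns the signed partial-correlation matrix,
#' \code{edgeWeights} the nonnegative weight matrix, \code{networkMode} the
#' sign mode, and \code{areaMatrix} the parcels-by-subjects area assay.
#'
#' @param object a \code{CovNetwork} or \code{SurfaceAreaExperiment}.
#' @return matrix or character scalar, as named.
#' @export
partialCorrMatrix <- function(object) {
    stopifnot(is(object, "CovNetwork"))
    object@pcorr
}

#' @rdname partialCorrMatrix
#' @export
edgeWeights <- function(object) {
    stopifnot(is(object, "CovNetwork"))
    object@weights
}

#' @rdname partialCorrMatrix
#' @export
networkMode <- function(object) {
    stopifnot(is(object, "CovNetwork"))
    object@mode
}

#' @rdname partialCorrMatrix
#' @export
areaMatrix <- function(object) {
    stopifnot(is(object, "SurfaceAreaExperiment"))
    assay(object, "area")
}

.newCovNetwork <- function(pcorr, weights = NULL, mode = "absolute",
                           group = "") {
    if (is.null(weights)) {
        weights <- abs(pcorr)
        diag(weights) <- 0
    }
    new("CovNetwork", pcorr = pcorr, weights = weights, mode = mode,
        group = group)
}
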