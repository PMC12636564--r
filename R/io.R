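#' Read and write pipeline tables
#'
#' Plain-text interchange formats: the area table is TSV with a
#' \code{subject_id} column plus one column per parcel (mm^2); phenotypes
#' are CSV with \code{subject_id}, \code{age}, \code{sex}, \code{group},
#' \code{site}; the layout is CSV with \code{parcel_id}, \code{x},
#' \code{y}, \code{z}, \code{r}. Hemisphere and pairing are encoded in
#' parcel ids as \code{L_###} / \code{R_###} (or \code{M_###} once
#' averaged).
#'
#' @param sae a \linkS4class{SurfaceAreaExperiment}.
#' @param path output file path.
#' @return \code{writeSurfaceAreaTSV}, \code{writePhenotypeCSV},
#'   \code{writeLayoutCSV} return the path invisibly;
#'   \code{readSurfaceAreaTable} returns a
#'   \linkS4class{SurfaceAreaExperiment}.
#' @name scn-io
NULL

#' @rdname scn-io
#' @export
writeSurfaceAreaTSV <- function(sae, path) {
    a <- t(areaMatrix(sae))
    df <- data.frame(subject_id = rownames(a), a, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname scn-io
#' @export
writePhenotypeCSV <- function(sae, path) {
    cd <- as.data.frame(colData(sae))
    write.csv(cd[c("subject_id", "age", "sex", "group", "site")], path,
              quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname scn-io
#' @param layout a \code{SphereLayout}.
#' @export
writeLayoutCSV <- function(layout, path) {
    pts <- layout$points
    ids <- rownames(pts)
    if (is.null(ids)) ids <- sprintf("p_%03d", seq_len(nrow(pts)))
    df <- data.frame(parcel_id = ids, x = pts[, 1], y = pts[, 2],
                     z = pts[, 3], r = layout$r)
    write.csv(df, path, quote = FALSE, row.names = FALSE)
    invisible(path)
}

.parseParcelIds <- function(ids) {
    hemi <- sub("_.*$", "", ids)
    if (!all(hemi %in% c("L", "R", "M")))
        stop("parcel ids must look like L_001 / R_001 / M_001")
    pair <- suppressWarnings(as.integer(sub("^[LRM]_", "", ids)))
    list(hemisphere = hemi, pair_id = pair)
}

#' @rdname scn-io
#' @param area_path,pheno_path,layout_path input file paths (layout
#'   optional).
#' @export
readSurfaceAreaTable <- function(area_path, pheno_path,
                                 layout_path = NULL) {
    at <- read.delim(area_path, check.names = FALSE,
                     stringsAsFactors = FALSE)
    pheno <- read.csv(pheno_path, stringsAsFactors = FALSE)
    stopifnot("subject_id" %in% names(at),
              all(c("subject_id", "age", "sex", "group", "site") %in%
                  names(pheno)))
    m <- as.matrix(at[setdiff(names(at), "subject_id")])
    rownames(m) <- at$subject_id
    pheno <- pheno[match(at$subject_id, pheno$subject_id), ]
    if (anyNA(pheno$subject_id)) stop("phenotypes missing for some subjects")
    meta <- .parseParcelIds(colnames(m))
    layout <- NULL
    if (!is.null(layout_path)) {
        ld <- read.csv(layout_path, stringsAsFactors = FALSE)
        pts <- as.matrix(ld[c("x", "y", "z")])
        rownames(pts) <- ld$parcel_id
        pts <- pts[colnames(m), , drop = FALSE]
        layout <- structure(list(points = pts, r = ld$r[1]),
                            class = "SphereLayout")
    }
    SurfaceAreaExperiment(t(m), pheno, hemisphere = meta$hemisphere,
                          pair_id = meta$pair_id, layout = layout)
}

#' Write a network as CSV adjacency plus JSON metadata
#'
#' @param net a \linkS4class{CovNetwork}.
#' @param prefix path prefix; writes \code{<prefix>_pcorr.csv} (signed
#'   adjacency) and \code{<prefix>_meta.json}.
#' @return the two paths, invisibly.
#' @export
writeCovNetwork <- function(net, prefix) {
    stopifnot(is(net, "CovNetwork"))
    p_csv <- paste0(prefix, "_pcorr.csv")
    p_json <- paste0(prefix, "_meta.json")
    write.csv(partialCorrMatrix(net), p_csv, quote = FALSE)
    jsonlite::write_json(
        list(n = nrow(partialCorrMatrix(net)), mode = networkMode(net),
             group = net@group),
        p_json, auto_unbox = TRUE, digits = NA)
    invisible(c(p_csv, p_json))
}

#' @rdname writeCovNetwork
#' @param labels integer cluster labels.
#' @param parcel_ids parcel identifiers, same length.
#' @param path output CSV path.
#' @export
writeClusterLabelsCSV <- function(labels, parcel_ids, path) {
    write.csv(data.frame(parcel_id = parcel_ids, cluster_id = labels),
              path, quote = FALSE, row.names = FALSE)
    invisible(path)
}
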