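## igraph on inverse-weight edge lengths: weights encode association, so
## path cost of an edge is 1/w. Zero-weight entries are non-edges.
.weightGraph <- function(w) {
    .assertWeights(w)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    igraph::E(g)$length <- 1 / igraph::E(g)$weight
    g
}

.shortestPathMatrix <- function(w) {
    g <- .weightGraph(w)
    igraph::distances(g, weights = igraph::E(g)$length)
}

#' Weighted global clustering coefficient
#'
#' Organisation of network weights into triangles:
#' \eqn{C = \mathrm{Tr}(A^3) / \sum_{i \ne j} [A^2]_{ij}} with A the
#' nonnegative weight matrix.
#'
#' @param w symmetric nonnegative weight matrix, zero diagonal.
#' @return scalar C.
#' @export
globalClustering <- function(w) {
    .assertWeights(w)
    a2 <- w %*% w
    denom <- sum(a2) - sum(diag(a2))
    if (denom <= 0) stop("no two-paths in the network: C undefined")
    sum(diag(a2 %*% w)) / denom
}

#' Characteristic path length
#'
#' Mean shortest-path distance over ordered vertex pairs, edge lengths taken
#' as inverse weights. A disconnected graph is an error (component sizes are
#' reported).
#'
#' @inheritParams globalClustering
#' @return scalar L.
#' @export
pathLength <- function(w) {
    d <- .shortestPathMatrix(w)
    off <- d[row(d) != col(d)]
    if (any(!is.finite(off))) {
        comp <- igraph::components(.weightGraph(w))
        stop("graph is disconnected (component sizes: ",
             paste(comp$csize, collapse = ", "), "): L undefined")
    }
    mean(off)
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over ordered vertex pairs;
#' unreachable pairs contribute 0.
#'
#' @inheritParams globalClustering
#' @return scalar E_glob (0 for an empty graph).
#' @export
globalEfficiency <- function(w) {
    d <- .shortestPathMatrix(w)
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0        # unreachable pairs and the diagonal
    diag(inv) <- 0
    n <- nrow(w)
    sum(inv) / (n * (n - 1))
}

#' Normalised weighted betweenness centrality
#'
#' Fraction of shortest paths (on inverse-weight lengths, with equal-length
#' ties all counted) between other vertex pairs that pass through each
#' vertex, normalised by the (N-1)(N-2)/2 unordered pairs excluding it, so
#' the hub of a star scores 1.
#'
#' @inheritParams globalClustering
#' @return numeric vector of per-vertex centralities in [0, 1].
#' @export
betweennessCentrality <- function(w) {
    g <- .weightGraph(w)
    n <- nrow(w)
    if (n < 3) return(rep(0, n))
    b <- igraph::betweenness(g, weights = igraph::E(g)$length,
                             directed = FALSE)
    unname(b) / ((n - 1) * (n - 2) / 2)
}

## base-2 KL divergence with the 0 * log(0/x) = 0 convention
.klBits <- function(p, m) {
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / m[nz]))
}

#' Jensen-Shannon edge-weight complexity
#'
#' Each vertex's edge weights are normalised to a probability vector
#' \eqn{p_i(j) = w_{ij} / \sum_k w_{ik}} (uniform 1/n when the row sum is
#' zero). For every vertex pair the Jensen-Shannon divergence
#' \eqn{JSD_{ij} = \frac12 D_{KL}(p_i \| m_{ij}) + \frac12 D_{KL}(p_j \|
#' m_{ij})} with \eqn{m_{ij} = (p_i + p_j)/2} is computed in bits. The
#' global index is the mean over all n^2 ordered pairs (diagonal terms are
#' zero), equivalently \eqn{(2/n^2) \sum_{i<j} JSD_{ij}}.
#'
#' @inheritParams globalClustering
#' @return list with \code{global} (bits), \code{per_vertex}
#'   (\eqn{JSD_i = n^{-1} \sum_j JSD_{ij}}) and \code{pairwise} (n x n
#'   symmetric matrix, zero diagonal).
#' @export
jsdComplexity <- function(w) {
    .assertWeights(w)
    n <- nrow(w)
    rs <- rowSums(w)
    p <- w / ifelse(rs > 0, rs, 1)
    p[rs == 0, ] <- 1 / n
    jsd <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
            m <- (p[i, ] + p[j, ]) / 2
            jsd[i, j] <- jsd[j, i] <-
                0.5 * .klBits(p[i, ], m) + 0.5 * .klBits(p[j, ], m)
        }
    }
    list(global = sum(jsd) / n^2,
         per_vertex = rowSums(jsd) / n,
         pairwise = jsd)
}

#' All global metrics of a network
#'
#' @param net a \linkS4class{CovNetwork} (or a weight matrix).
#' @return list of class \code{MetricSet}: \code{C}, \code{L},
#'   \code{E_glob}, \code{C_B}, \code{JSD_global}, \code{JSD_i}.
#' @export
networkMetrics <- function(net) {
    w <- if (is(net, "CovNetwork")) edgeWeights(net) else net
    jsd <- jsdComplexity(w)
    out <- list(C = globalClustering(w),
                L = pathLength(w),
                E_glob = globalEfficiency(w),
                C_B = betweennessCentrality(w),
                JSD_global = jsd$global,
                JSD_i = jsd$per_vertex)
    class(out) <- "MetricSet"
    out
}
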