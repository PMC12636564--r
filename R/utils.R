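.assertSymmetric <- function(m, what = "matrix", tol = 1e-8) {
    if (!is.matrix(m) || nrow(m) != ncol(m))
        stop(what, " must be a square matrix")
    if (max(abs(m - t(m))) > tol)
        stop(what, " must be symmetric")
    invisible(m)
}

.assertWeights <- function(w) {
    .assertSymmetric(w, "weight matrix")
    if (any(w < 0)) stop("weights must be nonnegative")
    if (max(abs(diag(w))) > 0) stop("weight diagonal must be zero")
    invisible(w)
}

## partial correlations from a precision matrix: rho_ij = -Omega_ij /
## sqrt(Omega_ii * Omega_jj), unit diagonal
pcorrFromPrecision <- function(omega) {
    .assertSymmetric(omega, "precision matrix")
    d <- 1 / sqrt(diag(omega))
    p <- -(omega * tcrossprod(d))
    diag(p) <- 1
    p
}

.minmax <- function(x) {
    r <- range(x)
    if (r[2] - r[1] < .Machine$double.eps) return(rep(0.5, length(x)))
    (x - r[1]) / (r[2] - r[1])
}

## deterministic child seeds below 2^31 derived from one integer seed
.childSeed <- function(seed, k) {
    (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483647L
}

.upperTri <- function(m) m[upper.tri(m)]

## evaluate expr under a private RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
    expr
}
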