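## Independent brute-force oracles. These deliberately avoid the package's
## own code paths (igraph, matrix inversion shortcuts) so that agreement is
## informative.

## partial correlation of columns i, j given all others: correlation of the
## residuals after regressing each on the remaining columns
oracle_pcorr <- function(X) {
    p <- ncol(X)
    out <- diag(p)
    for (i in seq_len(p - 1)) {
        for (j in (i + 1):p) {
            others <- X[, -c(i, j), drop = FALSE]
            ri <- if (ncol(others)) resid(lm.fit(cbind(1, others), X[, i]))
                  else X[, i] - mean(X[, i])
            rj <- if (ncol(others)) resid(lm.fit(cbind(1, others), X[, j]))
                  else X[, j] - mean(X[, j])
            out[i, j] <- out[j, i] <- cor(ri, rj)
        }
    }
    out
}

## global clustering by the literal triple loop
oracle_clustering <- function(w) {
    n <- nrow(w)
    num <- 0
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
        num <- num + w[i, j] * w[j, k] * w[k, i]
    den <- 0
    a2 <- w %*% w
    for (i in 1:n) for (j in 1:n) if (i != j) den <- den + a2[i, j]
    num / den
}

## all-pairs shortest paths on lengths 1/w by Floyd-Warshall
oracle_dists <- function(w) {
    n <- nrow(w)
    d <- ifelse(w > 0, 1 / w, Inf)
    diag(d) <- 0
    for (k in 1:n) for (i in 1:n) for (j in 1:n)
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
    d
}

oracle_pathlength <- function(w) {
    d <- oracle_dists(w)
    mean(d[row(d) != col(d)])
}

oracle_efficiency <- function(w) {
    d <- oracle_dists(w)
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    n <- nrow(w)
    sum(inv) / (n * (n - 1))
}

## betweenness by exhaustive enumeration of all simple paths between every
## pair, keeping those within tol of the shortest length; normalised by the
## (N-1)(N-2)/2 unordered pairs excluding the vertex
oracle_betweenness <- function(w, tol = 1e-9) {
    n <- nrow(w)
    len <- ifelse(w > 0, 1 / w, Inf)
    paths_between <- function(s, t) {
        found <- list()
        grow <- function(path, cost) {
            last <- path[length(path)]
            if (last == t) {
                found[[length(found) + 1]] <<- list(path = path, cost = cost)
                return(invisible())
            }
            for (v in seq_len(n)) {
                if (v %in% path || !is.finite(len[last, v])) next
                grow(c(path, v), cost + len[last, v])
            }
        }
        grow(s, 0)
        found
    }
    cb <- numeric(n)
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
        ps <- paths_between(s, t)
        if (!length(ps)) next
        costs <- vapply(ps, `[[`, 0, "cost")
        best <- min(costs)
        short <- ps[costs <= best + tol]
        sigma <- length(short)
        for (v in seq_len(n)) {
            if (v == s || v == t) next
            through <- sum(vapply(short, function(pp) v %in% pp$path, NA))
            cb[v] <- cb[v] + through / sigma
        }
    }
    cb / ((n - 1) * (n - 2) / 2)
}

## Jensen-Shannon divergence between two probability vectors, by the
## printed definition, base-2 logs
oracle_jsd_pair <- function(p, q) {
    m <- (p + q) / 2
    kl <- function(a, b) {
        nz <- a > 0
        sum(a[nz] * log2(a[nz] / b[nz]))
    }
    0.5 * kl(p, m) + 0.5 * kl(q, m)
}

## Ward objective (total within-cluster sum of squares over row profiles)
## for an explicit labelling
oracle_ward_ss <- function(feat, labels) {
    sum(vapply(unique(labels), function(k) {
        m <- feat[labels == k, , drop = FALSE]
        sum(sweep(m, 2, colMeans(m))^2)
    }, 0))
}

## every partition of n items into exactly k nonempty groups
oracle_partitions <- function(n, k) {
    out <- list()
    gen <- function(labels, i, used) {
        if (i > n) {
            if (used == k) out[[length(out) + 1]] <<- labels
            return(invisible())
        }
        for (g in seq_len(min(used + 1, k))) {
            labels[i] <- g
            gen(labels, i + 1, max(used, g))
        }
    }
    gen(integer(n), 1, 0)
    out
}
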