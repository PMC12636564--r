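## optimal order-preserving 1:1 assignment of each affected age to a
## distinct pool age minimizing total |difference|; exact for a single
## continuous covariate (sorted DP, O(n*m))
.assignAges <- function(a, b) {
    n <- length(a); m <- length(b)
    if (m < n) stop("insufficient pool")
    oa <- order(a); ob <- order(b)
    as_ <- a[oa]; bs <- b[ob]
    cost <- matrix(Inf, n + 1, m + 1)
    cost[1, ] <- 0
    pick <- matrix(FALSE, n + 1, m + 1)
    for (i in seq_len(n)) {
        for (j in i:m) {
            take <- cost[i, j] + abs(as_[i] - bs[j])
            skip <- cost[i + 1, j]
            if (take <= skip) {
                cost[i + 1, j + 1] <- take
                pick[i + 1, j + 1] <- TRUE
            } else cost[i + 1, j + 1] <- skip
        }
    }
    sel <- integer(n)
    i <- n; j <- m
    while (i > 0) {
        if (pick[i + 1, j + 1]) {
            sel[i] <- j
            i <- i - 1; j <- j - 1
        } else j <- j - 1
    }
    ## map back to original indices
    list(pairs = cbind(affected = oa, control = ob[sel]),
         total = cost[n + 1, m + 1])
}

#' 1:1 optimal group matching by sex and age
#'
#' Selects one control per affected subject from a pool, within sex strata
#' (when \code{by_sex}), minimizing the total absolute age difference (when
#' \code{by_age}; otherwise the first available controls in input order are
#' taken). The age assignment is solved exactly. No control is reused.
#'
#' @param affected,pool data.frames with \code{subject_id}, \code{age},
#'   \code{sex}.
#' @param by_age,by_sex logical flags for the matching variables.
#' @return list of class \code{MatchResult}: \code{pairs} (affected_id,
#'   control_id and their ages/sex), \code{total_age_discrepancy}, and
#'   per-group age/sex summaries.
#' @export
optimalMatch <- function(affected, pool, by_age = TRUE, by_sex = TRUE) {
    stopifnot(all(c("subject_id", "age", "sex") %in% names(affected)),
              all(c("subject_id", "age", "sex") %in% names(pool)))
    strata <- if (by_sex) split(seq_len(nrow(affected)), affected$sex)
              else list(all = seq_len(nrow(affected)))
    pairs <- do.call(rbind, lapply(names(strata), function(s) {
        ai <- strata[[s]]
        pi <- if (by_sex) which(pool$sex == s) else seq_len(nrow(pool))
        if (length(pi) < length(ai))
            stop("insufficient pool in stratum '", s, "' (",
                 length(pi), " < ", length(ai), ")")
        if (by_age) {
            asg <- .assignAges(affected$age[ai], pool$age[pi])
            data.frame(affected_idx = ai[asg$pairs[, "affected"]],
                       control_idx = pi[asg$pairs[, "control"]])
        } else {
            data.frame(affected_idx = ai,
                       control_idx = pi[seq_along(ai)])
        }
    }))
    res <- data.frame(
        affected_id = affected$subject_id[pairs$affected_idx],
        control_id = pool$subject_id[pairs$control_idx],
        affected_age = affected$age[pairs$affected_idx],
        control_age = pool$age[pairs$control_idx],
        sex = affected$sex[pairs$affected_idx])
    if (anyDuplicated(res$control_id)) stop("internal error: control reused")
    structure(list(
        pairs = res,
        total_age_discrepancy = sum(abs(res$affected_age - res$control_age)),
        summary = data.frame(
            group = c("affected", "control"),
            age_mean = c(mean(res$affected_age), mean(res$control_age)),
            age_sd = c(sd(res$affected_age), sd(res$control_age)),
            prop_female = c(mean(res$sex == "F"), mean(res$sex == "F")))),
        class = "MatchResult")
}

## weights of the partial-correlation network of a subjects x vars matrix
.pcorrWeights <- function(X) {
    net <- partialCorr(X)
    edgeWeights(net)
}

.permPval <- function(obs, null, direction, add_one = FALSE) {
    null <- null[is.finite(null)]
    num <- switch(direction,
                  greater = sum(null >= obs),
                  less = sum(null <= obs),
                  two.sided = sum(abs(null) >= abs(obs)))
    if (add_one) (num + 1) / (length(null) + 1) else num / length(null)
}

#' Permutation test of a global network metric
#'
#' Group labels are swapped at the level of the (cluster-aggregated)
#' surface-area data: each iteration pools the subjects, re-splits them
#' randomly into two groups of the original sizes, rebuilds each group's
#' partial-correlation network and recomputes the metric. The one-sided
#' p-value is the plain proportion of null differences at least as extreme
#' as the observed difference in the chosen direction (the add-one
#' correction is available via \code{add_one}); the effect size is the
#' observed difference divided by the SD of the null differences.
#'
#' @param sae_a,sae_b cluster-aggregated
#'   \linkS4class{SurfaceAreaExperiment}s (group difference is computed as
#'   b minus a).
#' @param metric_fn function mapping a weight matrix to a scalar, e.g.
#'   \code{\link{pathLength}}.
#' @param n_iter permutation iterations (the study convention is 10000).
#' @param direction \code{"two.sided"}, \code{"greater"} or \code{"less"}
#'   (direction of the b-minus-a difference).
#' @param seed integer seed.
#' @param add_one use the (b+1)/(m+1) p-value correction.
#' @return list of class \code{PermResult}: \code{observed}, \code{null}
#'   (length \code{n_iter}, NA for failed iterations), \code{p},
#'   \code{effect_size}, \code{direction}, \code{n_invalid}.
#' @export
permTestMetric <- function(sae_a, sae_b, metric_fn, n_iter = 1000,
                           direction = c("two.sided", "greater", "less"),
                           seed = 1L, add_one = FALSE) {
    direction <- match.arg(direction)
    Xa <- t(areaMatrix(sae_a)); Xb <- t(areaMatrix(sae_b))
    stopifnot(ncol(Xa) == ncol(Xb))
    na <- nrow(Xa); nb <- nrow(Xb)
    obs <- metric_fn(.pcorrWeights(Xb)) - metric_fn(.pcorrWeights(Xa))
    X <- rbind(Xa, Xb)
    null <- .withSeed(seed, vapply(seq_len(n_iter), function(b) {
        idx <- sample.int(na + nb)
        tryCatch(
            metric_fn(.pcorrWeights(X[idx[(na + 1):(na + nb)], , drop = FALSE])) -
            metric_fn(.pcorrWeights(X[idx[seq_len(na)], , drop = FALSE])),
            error = function(e) NA_real_)
    }, 0))
    structure(list(observed = obs, null = null,
                   p = .permPval(obs, null, direction, add_one),
                   effect_size = obs / sd(null, na.rm = TRUE),
                   direction = direction,
                   n_invalid = sum(!is.finite(null))),
              class = "PermResult")
}

.skewness <- function(x) {
    m <- mean(x); s <- sqrt(mean((x - m)^2))
    mean((x - m)^3) / s^3
}
.kurtosis <- function(x) {
    m <- mean(x); v <- mean((x - m)^2)
    mean((x - m)^4) / v^2 - 3
}

#' Permutation test on per-vertex value distributions
#'
#' Compares two equal-length vectors of per-vertex values (e.g. betweenness
#' centralities) by a descriptive statistic under label permutation. For
#' \code{mean}, \code{var}, \code{skew} and \code{kurt} the statistic is
#' the b-minus-a difference after pooling and random re-splitting; for
#' \code{corr} it is the Pearson correlation of the paired vectors, with a
#' null built by randomly swapping values within vertex pairs.
#'
#' @param a,b numeric vectors of equal length.
#' @param stat one of \code{"corr"}, \code{"mean"}, \code{"var"},
#'   \code{"skew"}, \code{"kurt"}.
#' @inheritParams permTestMetric
#' @return a \code{PermResult}.
#' @export
permTestDistribution <- function(a, b,
                                 stat = c("mean", "var", "skew", "kurt",
                                          "corr"),
                                 n_iter = 1000,
                                 direction = c("two.sided", "greater",
                                               "less"),
                                 seed = 1L, add_one = FALSE) {
    stat <- match.arg(stat)
    direction <- match.arg(direction)
    stopifnot(length(a) == length(b))
    n <- length(a)
    if (stat == "corr" && (sd(a) == 0 || sd(b) == 0))
        stop("constant vector: correlation undefined")
    f <- switch(stat, mean = mean, var = var, skew = .skewness,
                kurt = .kurtosis, corr = NULL)
    if (stat == "corr") {
        obs <- cor(a, b)
        null <- .withSeed(seed, vapply(seq_len(n_iter), function(it) {
            sw <- runif(n) < 0.5
            a2 <- ifelse(sw, b, a); b2 <- ifelse(sw, a, b)
            cor(a2, b2)
        }, 0))
    } else {
        obs <- f(b) - f(a)
        pool <- c(a, b)
        null <- .withSeed(seed, vapply(seq_len(n_iter), function(it) {
            idx <- sample.int(2 * n)
            f(pool[idx[(n + 1):(2 * n)]]) - f(pool[idx[seq_len(n)]])
        }, 0))
    }
    structure(list(observed = obs, null = null,
                   p = .permPval(obs, null, direction, add_one),
                   effect_size = obs / sd(null),
                   direction = direction, n_invalid = 0L),
              class = "PermResult")
}

#' Jackknife (leave-one-out) standard error
#'
#' \eqn{SE = \sqrt{\frac{n-1}{n} \sum_i (\theta_{(i)} -
#' \bar\theta_{(\cdot)})^2}} over leave-one-subject-out recomputations of
#' the statistic.
#'
#' @param x a \linkS4class{SurfaceAreaExperiment} (subjects = columns) or a
#'   subjects-by-variables matrix.
#' @param metric_fn function from the subsetted object to a scalar.
#' @return the jackknife standard error.
#' @export
jackknifeSE <- function(x, metric_fn) {
    n <- if (is(x, "SurfaceAreaExperiment")) ncol(x) else nrow(x)
    if (n < 3) stop("jackknife needs at least 3 subjects")
    theta <- vapply(seq_len(n), function(i) {
        xi <- if (is(x, "SurfaceAreaExperiment")) x[, -i]
              else x[-i, , drop = FALSE]
        metric_fn(xi)
    }, 0)
    sqrt((n - 1) / n * sum((theta - mean(theta))^2))
}

#' Minimum detectable effect for a two-sample t-test
#'
#' Solves the two-sided two-sample t-test power equation (noncentral t) for
#' the standardized mean difference d.
#'
#' @param n_per_group observations per group.
#' @param power target power.
#' @param alpha two-sided significance level.
#' @return Cohen's d.
#' @export
powerTtestSolveD <- function(n_per_group, power = 0.8, alpha = 0.05) {
    stopifnot(n_per_group >= 2, power > 0, power < 1, alpha > 0, alpha < 1)
    if (power <= alpha) return(0)
    power.t.test(n = n_per_group, power = power, sig.level = alpha,
                 type = "two.sample", alternative = "two.sided")$delta
}

#' Simulated power of a two-sample permutation test of means
#'
#' Outer loop: draw two unit-variance normal samples whose means differ by
#' d. Inner loop: two-sided permutation p-value for the mean difference
#' (plain proportion of null |differences| at least the observed). Power is
#' the fraction of outer replicates with p <= alpha.
#'
#' @param n_per_group observations per group.
#' @param d true standardized mean difference.
#' @param alpha significance level.
#' @param n_outer outer Monte-Carlo replicates.
#' @param n_inner label permutations per replicate.
#' @param seed integer seed.
#' @return estimated power (scalar in [0, 1]).
#' @export
powerPermSim <- function(n_per_group, d, alpha = 0.05, n_outer = 2000,
                         n_inner = 500, seed = 1L) {
    stopifnot(n_per_group >= 2, alpha > 0, alpha < 1)
    n <- n_per_group
    .withSeed(seed, {
        hits <- vapply(seq_len(n_outer), function(rep) {
            x <- rnorm(n); y <- rnorm(n, mean = d)
            v <- c(x, y)
            tot <- sum(v)
            obs <- abs(mean(y) - mean(x))
            s <- vapply(seq_len(n_inner), function(it)
                sum(v[sample.int(2 * n, n)]), 0)
            nulls <- abs((tot - 2 * s) / n)
            mean(nulls >= obs) <= alpha
        }, NA)
        mean(hits)
    })
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
fdrBH <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}
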