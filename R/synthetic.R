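#' Synthetic study configuration
#'
#' Defines the generating model for synthetic subject-by-parcel surface-area
#' tables. The generator emulates the statistical structure the downstream
#' analysis assumes: approximately normal (cluster-summed) areas, partial
#' correlations distributed around zero, covariance magnitude decaying with
#' geodesic distance on the spherical cortical model (strong short-range
#' structure), a group effect that scales off-diagonal precision entries, and
#' additive/multiplicative scan-site batch effects.
#'
#' @param n_subjects_per_group subjects per group (default 102, the matched
#'   group size used throughout).
#' @param n_parcels total parcel count, paired L/R (default 360; 180 per
#'   hemisphere).
#' @param n_sites number of scan sites (default 3).
#' @param precision_sparsity fraction of off-diagonal precision entries kept
#'   nonzero (default 0.15).
#' @param distance_decay_rate positive rate (1/mm) of the exp(-rate * d)
#'   falloff of off-diagonal precision magnitude with geodesic distance
#'   (default 0.02: strong below ~50 mm, negligible beyond ~150 mm).
#' @param group_scale multiplier >= 0 applied to off-diagonal precision
#'   entries in the affected group (default 1 = null).
#' @param site_shift,site_scale SDs of per-site additive (mm^2) and
#'   multiplicative (log-scale) batch effects (defaults 20 and 0.05).
#' @param age_range,sex_ratio phenotype distributions: uniform age range in
#'   years and Bernoulli probability of female.
#' @param area_mean,area_sd mean parcel area (mm^2) and SD of the shared
#'   latent component; defaults 500 and 50 keep draws positive in >= 99.9%
#'   of cases (z < -10 required for a negative area).
#' @param hemi_noise_sd SD of independent per-hemisphere noise, as a fraction
#'   of \code{area_sd} (default 0.3).
#' @param base_strength raw magnitude of the strongest (zero-distance)
#'   off-diagonal latent precision entries before spectral rescaling
#'   (default 0.6).
#' @param spectral_margin cap on the extreme eigenvalue of the latent
#'   off-diagonal block (default 0.6): the off-diagonals are rescaled so the
#'   latent precision stays positive definite for any
#'   \code{group_scale < 1/spectral_margin}; diagonal loading remains as a
#'   guard beyond that.
#' @param n_latent_clusters number of latent covariance clusters K0: parcels
#'   are partitioned into K0 spatially compact groups, each sharing one
#'   latent factor; the latent factors carry the distance-decaying
#'   dependency structure. \code{NULL} (default) picks the study-like ratio
#'   \code{round(0.345 * n_parcels/2)} (62 clusters at 360 parcels); setting
#'   it to \code{n_parcels/2} gives the flat one-parcel-per-latent model.
#' @param cluster_coherence fraction of each parcel's variance carried by
#'   its cluster latent (default 0.85); the rest is independent parcel
#'   noise.
#' @param radius sphere radius in mm (default 100, the fsaverage sphere).
#' @param seed integer seed fixing every random draw.
#' @return a validated list of class \code{SynthConfig}.
#' @export
synthConfig <- function(n_subjects_per_group = 102L, n_parcels = 360L,
                        n_sites = 3L, precision_sparsity = 1.0,
                        distance_decay_rate = 0.02, group_scale = 1,
                        site_shift = 20, site_scale = 0.05,
                        age_range = c(18, 60), sex_ratio = 0.5,
                        area_mean = 500, area_sd = 50, hemi_noise_sd = 0.3,
                        base_strength = 0.6, spectral_margin = 0.6,
                        n_latent_clusters = NULL, cluster_coherence = 0.85,
                        radius = 100, seed = 1L) {
    stopifnot(n_subjects_per_group >= 2, n_parcels >= 4,
              n_parcels %% 2 == 0, n_sites >= 1,
              precision_sparsity > 0, precision_sparsity <= 1,
              distance_decay_rate > 0, group_scale >= 0,
              site_shift >= 0, site_scale >= 0,
              length(age_range) == 2, age_range[1] < age_range[2],
              sex_ratio >= 0, sex_ratio <= 1,
              area_mean > 0, area_sd > 0, hemi_noise_sd >= 0,
              base_strength > 0, spectral_margin > 0, spectral_margin < 1,
              cluster_coherence > 0, cluster_coherence < 1, radius > 0)
    h <- n_parcels / 2
    if (is.null(n_latent_clusters))
        n_latent_clusters <- max(2L, as.integer(round(0.345 * h)))
    stopifnot(n_latent_clusters >= 2, n_latent_clusters <= h)
    cfg <- list(n_subjects_per_group = as.integer(n_subjects_per_group),
                n_parcels = as.integer(n_parcels),
                n_sites = as.integer(n_sites),
                precision_sparsity = precision_sparsity,
                distance_decay_rate = distance_decay_rate,
                group_scale = group_scale, site_shift = site_shift,
                site_scale = site_scale, age_range = age_range,
                sex_ratio = sex_ratio, area_mean = area_mean,
                area_sd = area_sd, hemi_noise_sd = hemi_noise_sd,
                base_strength = base_strength,
                spectral_margin = spectral_margin,
                n_latent_clusters = as.integer(n_latent_clusters),
                cluster_coherence = cluster_coherence,
                radius = radius, seed = as.integer(seed))
    class(cfg) <- "SynthConfig"
    cfg
}

#' Quasi-uniform points on a sphere (Fibonacci lattice)
#'
#' Deterministic near-uniform layout used for parcel centroids. Point i
#' (0-based) sits at z = 1 - 2(i + 0.5)/n with longitude i times the golden
#' angle.
#'
#' @param n_parcels number of points (>= 2).
#' @param r sphere radius.
#' @return list of class \code{SphereLayout} with \code{points} (n x 3
#'   matrix) and \code{r}.
#' @export
makeSphereLayout <- function(n_parcels, r) {
    stopifnot(n_parcels >= 2, r > 0)
    i <- seq_len(n_parcels) - 1
    z <- 1 - 2 * (i + 0.5) / n_parcels
    phi <- i * pi * (3 - sqrt(5))
    rho <- sqrt(pmax(0, 1 - z^2))
    pts <- r * cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
    structure(list(points = pts, r = r), class = "SphereLayout")
}

#' Paired-hemisphere layout
#'
#' Builds a layout for \code{n_parcels} parcels in which parcel i and parcel
#' i + n_parcels/2 are mirror images across the x = 0 plane, modelling
#' left/right homologue pairs on a single sphere.
#'
#' @inheritParams makeSphereLayout
#' @return \code{SphereLayout} with an extra \code{pair_id} vector.
#' @export
makePairedLayout <- function(n_parcels, r) {
    stopifnot(n_parcels >= 4, n_parcels %% 2 == 0)
    h <- n_parcels / 2L
    base <- makeSphereLayout(h, r)
    right <- base$points
    right[, 1] <- -right[, 1]
    pts <- rbind(base$points, right)
    rownames(pts) <- c(sprintf("L_%03d", seq_len(h)),
                       sprintf("R_%03d", seq_len(h)))
    structure(list(points = pts, r = r, pair_id = rep(seq_len(h), 2),
                   base = base),
              class = "SphereLayout")
}

## great-circle distances between rows of a point matrix on a sphere
.sphereDist <- function(pts, r) {
    n <- nrow(pts)
    u <- pts / r
    ## numerically safe: atan2(|PixPj|, Pi.Pj)
    dotm <- tcrossprod(u)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
            cr <- c(u[i, 2] * u[j, 3] - u[i, 3] * u[j, 2],
                    u[i, 3] * u[j, 1] - u[i, 1] * u[j, 3],
                    u[i, 1] * u[j, 2] - u[i, 2] * u[j, 1])
            d[i, j] <- d[j, i] <- r * atan2(sqrt(sum(cr^2)), dotm[i, j])
        }
    }
    d
}

## add lambda*I until the smallest eigenvalue clears a floor; bisection on
## lambda keeps the loading minimal so the off-diagonal pattern dominates
.diagLoad <- function(m, floor_frac = 0.05) {
    target <- floor_frac * mean(diag(m))
    ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    if (ev >= target) return(m)
    lo <- 0; hi <- target - ev
    for (it in 1:60) {
        mid <- (lo + hi) / 2
        evm <- min(eigen(m + mid * diag(nrow(m)), symmetric = TRUE,
                         only.values = TRUE)$values)
        if (evm >= target) hi <- mid else lo <- mid
        if (hi - lo < 1e-10) break
    }
    m + hi * diag(nrow(m))
}

## latent-level machinery shared by buildPrecision: spatially compact
## partition of the h parcels into K0 latent clusters (identity when
## K0 == h), projected cluster centroids, and the rescaled off-diagonal
## coupling block of the latent precision
.latentStructure <- function(cfg, layout) {
    h <- cfg$n_parcels / 2L
    pts <- layout$points
    k0 <- cfg$n_latent_clusters
    if (k0 == h) {
        plab <- seq_len(h)
        cent <- pts
    } else {
        plab <- .withSeed(.childSeed(cfg$seed, 13L),
            kmeans(pts, centers = k0, nstart = 5, iter.max = 50)$cluster)
        cent <- t(vapply(seq_len(k0), function(k)
            colMeans(pts[plab == k, , drop = FALSE]), numeric(3)))
        cent <- cent * (layout$r / sqrt(rowSums(cent^2)))
    }
    d <- .sphereDist(cent, layout$r)
    mag <- cfg$base_strength * exp(-cfg$distance_decay_rate * d)
    off <- .withSeed(.childSeed(cfg$seed, 11L), {
        np <- k0 * (k0 - 1) / 2
        keep <- matrix(0, k0, k0)
        keep[upper.tri(keep)] <- rbinom(np, 1, cfg$precision_sparsity)
        sgn <- matrix(0, k0, k0)
        sgn[upper.tri(sgn)] <- sample(c(-1, 1), np, replace = TRUE)
        o <- mag * keep * sgn
        o + t(o)
    })
    nrm <- max(abs(eigen(off, symmetric = TRUE, only.values = TRUE)$values))
    if (nrm > cfg$spectral_margin)
        off <- off * (cfg$spectral_margin / nrm)
    list(labels = plab, centroids = cent, coupling = off)
}

#' Generating precision matrix over hemisphere-level parcels
#'
#' Constructs the symmetric positive-definite precision matrix of the
#' n_parcels/2 hemisphere-level parcels under a hierarchical latent model:
#' parcels are partitioned into \code{n_latent_clusters} spatially compact
#' groups; each group shares a unit-variance latent factor carrying
#' \code{cluster_coherence} of the parcel variance, and the latent factors
#' follow a precision \eqn{I - g \cdot O} whose coupling block O has
#' magnitudes decaying with centroid geodesic distance as
#' exp(-distance_decay_rate * d), random signs, Bernoulli sparsity, and an
#' extreme eigenvalue rescaled to \code{spectral_margin}. The affected
#' group multiplies the coupling by \code{g = group_scale} (control g = 1),
#' so latent partial correlations scale exactly by \code{group_scale}
#' whenever \code{group_scale * spectral_margin < 1}; diagonal loading
#' (minimal lambda by bisection) remains as a positive-definiteness guard
#' beyond that. With \code{n_latent_clusters = n_parcels/2} the model
#' reduces to one parcel per latent factor and the parcel partial
#' correlations equal the coupling entries directly.
#'
#' @param cfg a \code{SynthConfig}.
#' @param layout base-hemisphere \code{SphereLayout} (n_parcels/2 points);
#'   defaults to the Fibonacci layout implied by \code{cfg}.
#' @param group \code{"control"} or \code{"affected"}.
#' @return symmetric positive-definite precision matrix with attribute
#'   \code{planted_labels} (the latent cluster partition).
#' @export
buildPrecision <- function(cfg, layout = NULL,
                           group = c("control", "affected")) {
    stopifnot(inherits(cfg, "SynthConfig"))
    group <- match.arg(group)
    h <- cfg$n_parcels / 2L
    if (is.null(layout)) layout <- makeSphereLayout(h, cfg$radius)
    stopifnot(nrow(layout$points) == h)
    lat <- .latentStructure(cfg, layout)
    g <- if (group == "affected") cfg$group_scale else 1
    k0 <- cfg$n_latent_clusters
    om_lat <- diag(k0) - g * lat$coupling
    om_lat <- .diagLoad(om_lat)
    sig_lat <- cov2cor(solve(om_lat))
    coh <- cfg$cluster_coherence
    sig_p <- coh * sig_lat[lat$labels, lat$labels] + (1 - coh) * diag(h)
    omega <- solve(sig_p)
    omega <- (omega + t(omega)) / 2
    attr(omega, "planted_labels") <- lat$labels
    omega
}

#' Sample one group of subjects
#'
#' Draws \code{n_subjects_per_group} subjects from a multivariate normal on
#' the hemisphere-level latent parcels (covariance = scaled inverse
#' precision), mirrors each latent value into left and right parcels with
#' independent hemisphere noise, shifts to positive mean areas, applies
#' per-site additive/multiplicative batch effects, clips at a 1 mm^2 floor,
#' and attaches phenotypes (age uniform, sex Bernoulli, site round-robin).
#'
#' @param cfg a \code{SynthConfig}.
#' @param precision positive-definite hemisphere-level precision matrix from
#'   \code{\link{buildPrecision}}.
#' @param group group label stored in the phenotypes.
#' @param seed integer seed for this group's draws (default derived from
#'   \code{cfg$seed}).
#' @return a \linkS4class{SurfaceAreaExperiment} with 2H parcels.
#' @export
sampleGroup <- function(cfg, precision, group = "control",
                        seed = .childSeed(cfg$seed, 29L)) {
    stopifnot(inherits(cfg, "SynthConfig"))
    .assertSymmetric(precision, "precision matrix")
    h <- nrow(precision)
    n <- cfg$n_subjects_per_group
    sigma <- solve(precision)
    ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) stop("precision matrix is not positive definite")
    corr <- cov2cor(sigma)
    ## per-parcel mean areas and per-site batch parameters are fixed by
    ## cfg$seed so both groups share them
    mu <- .withSeed(.childSeed(cfg$seed, 3L),
                    runif(h, 0.8 * cfg$area_mean, 1.2 * cfg$area_mean))
    batch <- .withSeed(.childSeed(cfg$seed, 5L),
                       list(shift = rnorm(cfg$n_sites, sd = 1),
                            lscale = rnorm(cfg$n_sites, sd = 1)))
    ch <- chol(corr)
    hn <- cfg$hemi_noise_sd * cfg$area_sd
    site <- rep(seq_len(cfg$n_sites), length.out = n)
    drawn <- .withSeed(seed, {
        z <- matrix(rnorm(n * h), n, h)
        latent <- z %*% ch      # n x h, unit variance, target correlation
        mkhemi <- function() {
            e <- matrix(rnorm(n * h, sd = hn), n, h)
            sweep(cfg$area_sd * latent + e, 2, mu, "+")
        }
        list(areas = cbind(mkhemi(), mkhemi()),   # subjects x 2h
             age = runif(n, cfg$age_range[1], cfg$age_range[2]),
             sex = ifelse(runif(n) < cfg$sex_ratio, "F", "M"))
    })
    shift <- cfg$site_shift * batch$shift
    scale <- exp(cfg$site_scale * batch$lscale)
    areas <- drawn$areas * scale[site] + shift[site]
    areas <- pmax(areas, 1)
    pheno <- data.frame(
        subject_id = sprintf("%s_%04d", group, seq_len(n)),
        age = drawn$age, sex = drawn$sex, group = group,
        site = paste0("site", site),
        stringsAsFactors = FALSE)
    amat <- t(areas)
    rownames(amat) <- c(sprintf("L_%03d", seq_len(h)),
                        sprintf("R_%03d", seq_len(h)))
    colnames(amat) <- pheno$subject_id
    SurfaceAreaExperiment(amat, pheno,
                          hemisphere = rep(c("L", "R"), each = h),
                          pair_id = rep(seq_len(h), 2))
}

#' Generate a full two-group synthetic study
#'
#' Builds the paired layout, the control and affected precision matrices,
#' and samples both groups with seeds derived from \code{cfg$seed}. The true
#' generating objects are kept in \code{metadata()} for diagnostics.
#'
#' @param cfg a \code{SynthConfig}.
#' @return \linkS4class{SurfaceAreaExperiment} with both groups' subjects.
#' @export
synthStudy <- function(cfg) {
    stopifnot(inherits(cfg, "SynthConfig"))
    lay <- makePairedLayout(cfg$n_parcels, cfg$radius)
    prec_c <- buildPrecision(cfg, lay$base, "control")
    prec_a <- buildPrecision(cfg, lay$base, "affected")
    ctl <- sampleGroup(cfg, prec_c, "control", .childSeed(cfg$seed, 29L))
    aff <- sampleGroup(cfg, prec_a, "affected", .childSeed(cfg$seed, 31L))
    amat <- cbind(areaMatrix(ctl), areaMatrix(aff))
    pheno <- rbind(as.data.frame(colData(ctl)), as.data.frame(colData(aff)))
    out <- SurfaceAreaExperiment(amat, pheno,
                                 hemisphere = rowData(ctl)$hemisphere,
                                 pair_id = rowData(ctl)$pair_id,
                                 layout = lay)
    S4Vectors::metadata(out)$precision <- list(control = prec_c,
                                               affected = prec_a)
    S4Vectors::metadata(out)$config <- cfg
    out
}

#' Split a SurfaceAreaExperiment by group label
#' @param sae a \linkS4class{SurfaceAreaExperiment}.
#' @return named list of per-group objects.
#' @export
splitByGroup <- function(sae) {
    g <- colData(sae)$group
    lapply(split(seq_len(ncol(sae)), g), function(idx) sae[, idx])
}
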