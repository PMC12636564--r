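#' Read a pipeline run configuration
#'
#' Configurations are YAML with nested sections: either a \code{synthetic}
#' block (arguments for \code{\link{synthConfig}}) or an \code{input} block
#' (\code{areas}, \code{phenotypes}, optional \code{layout} file paths); a
#' \code{cluster} block (\code{K}, or \code{select} with \code{range} and
#' \code{n_seeds}, plus optional \code{n_reference_subjects} for the
#' synthetic clustering reference sample); \code{permutation}
#' (\code{n_iter}, \code{seed}); \code{swp} (\code{n_random}, \code{seed});
#' \code{gam} (\code{k}). Every stochastic stage carries an explicit seed.
#'
#' @param path YAML file path.
#' @return list of class \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    asRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a plain list with the same structure.
#' @export
asRunConfig <- function(cfg) {
    if (is.null(cfg$synthetic) && is.null(cfg$input))
        stop("config error: need a 'synthetic' or 'input' section")
    if (is.null(cfg$cluster) ||
        (is.null(cfg$cluster$K) && is.null(cfg$cluster$select)))
        stop("config error: 'cluster' needs K or a select block")
    cfg$permutation <- modifyList(list(n_iter = 1000, seed = 1L,
                                       direction = "two.sided"),
                                  cfg$permutation %||% list())
    cfg$swp <- modifyList(list(n_random = 10, seed = 1L), cfg$swp %||% list())
    cfg$gam <- modifyList(list(k = 5), cfg$gam %||% list())
    cfg$cluster$n_reference_subjects <-
        cfg$cluster$n_reference_subjects %||% 650L
    class(cfg) <- "RunConfig"
    cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("pipeline stage '%s' failed: %s", name,
                     conditionMessage(e)), call. = FALSE))
}

#' Run the full SCN pipeline
#'
#' Stages, in order: load or generate the study data; average hemispheres;
#' harmonize sites; estimate (or select) the parcel clustering on the
#' control reference sample; aggregate clusters; build per-group
#' partial-correlation networks; global metrics and JSD complexity;
#' geodesics and small-world propensity; distance-weight GAM with pointwise
#' comparison; permutation inference on global metrics. All outputs are
#' written under \code{out_dir} together with a manifest recording the
#' configuration and seeds; a rerun with the same config reproduces every
#' numeric output.
#'
#' @param config a \code{RunConfig} (see \code{\link{readRunConfig}}).
#' @param out_dir output directory (created if missing); NULL skips all
#'   file output.
#' @return invisibly, a list with every intermediate and final result.
#' @export
runPipeline <- function(config, out_dir = NULL) {
    if (!inherits(config, "RunConfig")) config <- asRunConfig(config)
    if (!is.null(out_dir) && !dir.exists(out_dir))
        dir.create(out_dir, recursive = TRUE)
    outfile <- function(...) file.path(out_dir, paste0(...))

    ## --- load or generate -------------------------------------------------
    res <- list(config = config)
    dat <- .stage("load", {
        if (!is.null(config$synthetic)) {
            scfg <- do.call(synthConfig, config$synthetic)
            study <- synthStudy(scfg)
            refn <- config$cluster$n_reference_subjects
            ref_cfg <- do.call(synthConfig,
                               modifyList(config$synthetic,
                                          list(n_subjects_per_group = refn)))
            ref <- sampleGroup(ref_cfg,
                               buildPrecision(ref_cfg,
                                              makePairedLayout(
                                                  ref_cfg$n_parcels,
                                                  ref_cfg$radius)$base,
                                              "control"),
                               group = "control",
                               seed = .childSeed(ref_cfg$seed, 101L))
            list(study = study, reference = ref,
                 layout = S4Vectors::metadata(study)$layout)
        } else {
            study <- readSurfaceAreaTable(config$input$areas,
                                          config$input$phenotypes,
                                          config$input$layout)
            ref <- if (!is.null(config$input$reference_areas))
                readSurfaceAreaTable(config$input$reference_areas,
                                     config$input$reference_phenotypes,
                                     config$input$layout)
            else splitByGroup(study)$control
            list(study = study, reference = ref,
                 layout = S4Vectors::metadata(study)$layout)
        }
    })

    ## --- harmonize + average hemispheres ---------------------------------
    prep <- .stage("harmonize", {
        study <- averageHemispheres(harmonizeSites(dat$study))
        ref <- averageHemispheres(harmonizeSites(dat$reference))
        list(study = study, ref = ref)
    })

    ## --- clustering -------------------------------------------------------
    clus <- .stage("cluster", {
        if (!is.null(config$cluster$select)) {
            sel <- selectK(dat$reference,
                           K_range = do.call(seq, as.list(
                               config$cluster$select$range)),
                           n_seeds = config$cluster$select$n_seeds %||% 10,
                           seed = config$cluster$select$seed %||% 1L)
            K <- sel$modal_K
        } else {
            sel <- NULL
            K <- config$cluster$K
        }
        pc_ref <- partialCorrMatrix(partialCorr(prep$ref))
        sol <- wardCluster(pc_ref, K, quality = TRUE)
        list(selection = sel, K = K, solution = sol)
    })
    res$clustering <- clus

    ## --- aggregate + per-group networks ----------------------------------
    nets <- .stage("build-scn", {
        agg <- aggregateClusters(prep$study, clus$solution$labels)
        groups <- splitByGroup(agg)
        if (length(groups) != 2)
            stop("pipeline expects exactly two groups, got ",
                 length(groups))
        ## controls are the reference group: F ratios, permutation
        ## differences and GAM group terms are all affected-vs-control
        gnames <- names(groups)
        if ("control" %in% gnames)
            gnames <- c("control", setdiff(gnames, "control"))
        net <- lapply(gnames, function(g) partialCorr(groups[[g]], group = g))
        names(net) <- gnames
        list(agg = agg, groups = groups, net = net, gnames = gnames)
    })
    ga <- nets$gnames[1]; gb <- nets$gnames[2]
    res$networks <- nets$net

    ## --- metrics ----------------------------------------------------------
    res$metrics <- .stage("metrics", lapply(nets$net, networkMetrics))
    res$dist_report <- .stage("metrics", distributionChecks(
        nets$net[[ga]], nets$net[[gb]], nets$groups[[ga]],
        nets$groups[[gb]]))

    ## --- spatial ----------------------------------------------------------
    sp <- .stage("spatial", {
        h <- sum(rowData(dat$study)$hemisphere == "L")
        base_layout <- if (!is.null(dat$layout$base)) dat$layout$base
                       else dat$layout
        cent <- clusterCentroids(base_layout, clus$solution$labels)
        gd <- geodesicMatrix(cent)
        swp <- lapply(nets$net, function(nt)
            smallWorldPropensity(edgeWeights(nt), gd,
                                 n_random = config$swp$n_random,
                                 seed = config$swp$seed))
        gam <- fitDistanceWeight(edgeWeights(nets$net[[ga]]),
                                 edgeWeights(nets$net[[gb]]), gd,
                                 k = config$gam$k)
        list(centroids = cent, geodesics = gd, swp = swp, gam = gam,
             pointwise = pointwiseCompare(gam))
    })
    res$spatial <- sp

    ## --- permutation inference -------------------------------------------
    res$permutation <- .stage("permute", {
        fns <- list(C = globalClustering, L = pathLength,
                    E_glob = globalEfficiency, JSD_global = function(w)
                        jsdComplexity(w)$global)
        lapply(seq_along(fns), function(i)
            permTestMetric(nets$groups[[ga]], nets$groups[[gb]], fns[[i]],
                           n_iter = config$permutation$n_iter,
                           direction = config$permutation$direction,
                           seed = .childSeed(config$permutation$seed,
                                             i))) |>
            setNames(names(fns))
    })
    res$jackknife_se <- .stage("permute", lapply(nets$groups, function(g)
        jackknifeSE(g, function(s) pathLength(.pcorrWeights(t(areaMatrix(s)))))))

    ## --- write outputs ----------------------------------------------------
    if (!is.null(out_dir)) .stage("write", {
        writeSurfaceAreaTSV(dat$study, outfile("areas.tsv"))
        writePhenotypeCSV(dat$study, outfile("phenotypes.csv"))
        if (!is.null(dat$layout))
            writeLayoutCSV(dat$layout, outfile("layout.csv"))
        writeClusterLabelsCSV(clus$solution$labels,
                              rownames(prep$ref), outfile("clusters.csv"))
        for (g in nets$gnames)
            writeCovNetwork(nets$net[[g]], outfile("network_", g))
        num <- function(x) lapply(x, function(v)
            if (is.numeric(v)) unname(v) else v)
        jsonlite::write_json(
            lapply(res$metrics, num), outfile("metrics.json"),
            auto_unbox = TRUE, digits = NA)
        jsonlite::write_json(
            lapply(sp$swp, function(s) num(unclass(s))),
            outfile("swp.json"), auto_unbox = TRUE, digits = NA)
        write.csv(sp$pointwise, outfile("pointwise.csv"),
                  quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
            lapply(res$permutation, function(p)
                list(observed = p$observed, p = p$p,
                     effect_size = p$effect_size, direction = p$direction,
                     n_invalid = p$n_invalid)),
            outfile("permutation.json"), auto_unbox = TRUE, digits = NA)
        manifest <- list(package_version =
                             as.character(utils::packageVersion("surfSCN")),
                         config = unclass(config))
        jsonlite::write_json(manifest, outfile("manifest.json"),
                             auto_unbox = TRUE, digits = NA)
    })
    invisible(res)
}
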