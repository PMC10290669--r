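## End-to-end invariance report: bulk pair statistics with their resampling
## nulls, PCA/tree/clustering similarity, network degree analytics, and the
## single-cell DE stage, from one configuration with a single global seed
## expanded into fixed per-stage substreams (so adding a stage never
## perturbs earlier stages' draws).

stageSeed <- function(seed, offset) as.integer((seed + offset) %% .Machine$integer.max)

defaultRunConfig <- function() list(
    seed = 1L,
    outDir = NULL,
    statistics = c("r", "rho", "mi", "eta2"),
    group = "NvsT",
    nReps = 100L,
    logTransform = FALSE,
    filter = list(apply = FALSE, q = 0.05, minSampleFrac = 0.5),
    bulk = list(simulate = TRUE),
    network = list(simulate = TRUE),
    singleCell = list(simulate = TRUE))

#' Run the full gene-set invariance report
#'
#' Orchestrates every stage from a single configuration: bulk pair
#' statistics (Pearson, Spearman, MI, noise) for the whole matrix and the
#' focal set with size-matched resampling nulls; PCA embedding with the
#' normal-tumor distance and its null; neighbor-joining tree and
#' hierarchical clustering with separation scores; interaction-network
#' degree report, power-law fit and degree null; and the single-cell
#' QC/normalization/per-cluster-DE stage with the focal fraction.
#'
#' @param config a list (or path to a YAML file) with entries \code{seed},
#'   \code{outDir} (optional; when set, JSON/TSV/Newick outputs are
#'   written), \code{statistics}, \code{group}, \code{nReps},
#'   \code{logTransform}, \code{filter} (\code{apply}, \code{q},
#'   \code{minSampleFrac}), and per-stage input blocks \code{bulk},
#'   \code{network}, \code{singleCell}. Each input block either names paths
#'   (\code{matrix}/\code{conditions}/\code{geneset} for bulk;
#'   \code{edges}/\code{geneset} for network; \code{dir}/\code{geneset} for
#'   single cell) or sets \code{simulate = TRUE} with optional generator
#'   parameters (passed to [bulkSimConfig()], [networkSimConfig()],
#'   [singleCellSimConfig()]). All referenced paths are checked before any
#'   computation.
#' @return list of stage results: \code{pairStats}, \code{nulls},
#'   \code{embedding}, \code{conditionDistance}, \code{tree},
#'   \code{separation}, \code{network}, \code{singleCell}, \code{seed}.
#' @export
runInvarianceReport <- function(config = list()) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- utils::modifyList(defaultRunConfig(), config)
    seed <- as.integer(cfg$seed)

    ## fail before any computation if a referenced path is missing
    paths <- unlist(lapply(list(cfg$bulk, cfg$network, cfg$singleCell),
                           function(b) b[names(b) %in%
                               c("matrix", "conditions", "geneset",
                                 "edges", "dir")]))
    for (p in paths)
        if (!file.exists(p)) stop("input path does not exist: ", p)

    ## ---- bulk stage ----
    if (isTRUE(cfg$bulk$simulate)) {
        simArgs <- cfg$bulk[setdiff(names(cfg$bulk), "simulate")]
        simArgs$seed <- stageSeed(seed, 11L)
        sim <- simulateBulk(do.call(bulkSimConfig, simArgs))
        em <- sim$matrix; focal <- sim$focal
    } else {
        em <- readExpression(cfg$bulk$matrix, cfg$bulk$conditions)
        focal <- readGeneSets(cfg$bulk$geneset)[[1L]]
    }
    if (isTRUE(cfg$filter$apply))
        em <- filterLowExpression(em, cfg$filter$q,
                                  cfg$filter$minSampleFrac)

    pairStats <- rbind(
        pairStatReport(em, NULL, cfg$statistics, cfg$logTransform),
        pairStatReport(em, focal, cfg$statistics, cfg$logTransform))

    nulls <- lapply(setNames(cfg$statistics, cfg$statistics), function(s)
        buildNull(em, focal, s, cfg$group, nReps = cfg$nReps,
                  seed = stageSeed(seed, 44L),
                  logTransform = cfg$logTransform))

    ## ---- similarity stage ----
    emb <- pcaEmbed(em)
    condDist <- conditionDistance(emb)
    distNull <- resamplingNull(
        rownames(em), focal,
        function(ids) conditionDistance(pcaEmbed(em, ids)),
        "conditionDistance", nReps = cfg$nReps,
        seed = stageSeed(seed, 55L))
    d <- sampleDistanceMatrix(em)
    tree <- njTree(d)
    hc <- hierarchicalCluster(d)
    separation <- list(tree = separationScore(tree, condition(em)),
                       dendrogram = separationScore(hc, condition(em)))

    ## ---- network stage ----
    if (isTRUE(cfg$network$simulate)) {
        netArgs <- cfg$network[setdiff(names(cfg$network), "simulate")]
        netArgs$seed <- stageSeed(seed, 22L)
        nsim <- simulateNetwork(do.call(networkSimConfig, netArgs))
        net <- nsim$network; netFocal <- nsim$focal
    } else {
        net <- readEdgeList(cfg$network$edges)
        netFocal <- if (!is.null(cfg$network$geneset))
            readGeneSets(cfg$network$geneset)[[1L]] else focal
    }
    deg <- igraph::degree(interactionGraph(net))
    networkRes <- list(
        all = degreeReport(net),
        focal = degreeReport(net, netFocal),
        powerLaw = fitPowerLaw(deg[deg >= 1]),
        degreeNull = degreeNull(net, netFocal, nReps = cfg$nReps,
                                seed = stageSeed(seed, 66L)),
        focalSubgraph = inducedSubgraphReport(net, netFocal))

    ## ---- single-cell stage ----
    if (isTRUE(cfg$singleCell$simulate)) {
        scArgs <- cfg$singleCell[setdiff(names(cfg$singleCell),
                                         c("simulate", "focalSize"))]
        scArgs$seed <- stageSeed(seed, 33L)
        scCfg <- do.call(singleCellSimConfig, scArgs)
        nFocal <- if (!is.null(cfg$singleCell$focalSize))
            cfg$singleCell$focalSize else max(10L, scCfg$nGenes %/% 10L)
        scFocal <- withr::with_seed(stageSeed(seed, 34L),
            GeneSet("focal", sample(sprintf("gene%05d",
                seq_len(scCfg$nGenes)), nFocal)))
        cc <- simulateSingleCell(scCfg, scFocal)
    } else {
        cc <- readCellCounts(cfg$singleCell$dir)
        scFocal <- if (!is.null(cfg$singleCell$geneset))
            readGeneSets(cfg$singleCell$geneset)[[1L]] else focal
    }
    cc <- qcFilter(cc)
    cc <- logNormalizeCells(cc)
    de <- clusterDEAll(cc)
    scRes <- list(de = de, focalFraction = focalFraction(de, scFocal),
                  plantedDE = S4Vectors::metadata(cc)$planted_de)

    result <- list(pairStats = pairStats, nulls = nulls,
                   embedding = emb, conditionDistance = condDist,
                   conditionDistanceNull = distNull,
                   tree = tree, separation = separation,
                   network = networkRes, singleCell = scRes, seed = seed)

    if (!is.null(cfg$outDir)) writeReportBundle(result, cfg$outDir)
    result
}

writeReportBundle <- function(result, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(result$pairStats, file.path(outDir, "pair_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeNewick(result$tree, file.path(outDir, "nj_tree.nwk"))
    write.table(
        data.frame(sample = result$embedding$sampleIds,
                   result$embedding$coordinates,
                   condition = result$embedding$condition),
        file.path(outDir, "pca_embedding.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- list(
        seed = result$seed,
        percentiles = lapply(result$nulls, percentile),
        focal_values = lapply(result$nulls, focalValue),
        condition_distance = result$conditionDistance,
        condition_distance_percentile =
            percentile(result$conditionDistanceNull),
        separation = result$separation,
        network = list(
            mean_degree_all = result$network$all$meanDegree,
            mean_degree_focal = result$network$focal$meanDegree,
            power_law_alpha = result$network$powerLaw@alpha,
            degree_percentile = percentile(result$network$degreeNull),
            focal_subgraph = result$network$focalSubgraph[
                c("nNodes", "nEdges", "nComponents",
                  "largestComponentFraction")]),
        single_cell = list(
            n_de = sum(result$singleCell$de$adjusted_p < 0.05,
                       na.rm = TRUE),
            focal_fraction = result$singleCell$focalFraction$overall))
    jsonlite::write_json(summary, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(result$singleCell$de, file.path(outDir, "sc_de.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(outDir)
}
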