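## Synthetic-data generators with planted, recoverable structure. Every
## downstream stage (pair statistics, resampling null, PCA/trees, network
## degree analytics, single-cell DE) is validated against these plants.

checkCount <- function(x, field, min = 1L) {
    if (length(x) != 1L || is.na(x) || x != round(x) || x < min)
        stop("invalid '", field, "': must be a single integer >= ", min)
    as.integer(x)
}

checkPositive <- function(x, field, strict = TRUE) {
    if (length(x) != 1L || is.na(x) || (if (strict) x <= 0 else x < 0))
        stop("invalid '", field, "': must be ",
             if (strict) "> 0" else ">= 0")
    as.numeric(x)
}

#' Configuration for the bulk expression simulator
#'
#' Per-gene baseline means are log-normal; per-sample values multiply the
#' baseline by log-normal noise with a condition-specific coefficient of
#' variation. Defaults emulate a paired tumor/normal TPM study: a few
#' thousand expressed genes, ten samples per condition, moderate biological
#' noise that is higher among tumors.
#'
#' @param nGenes number of genes (default 2000).
#' @param nNormal,nTumor samples per condition (default 10 each; >= 2 so
#'   within-condition pairs exist).
#' @param logmeanMu,logmeanSigma log-normal parameters of per-gene baseline
#'   means (defaults 1 and 1, i.e. median TPM ~ e).
#' @param cvNormal,cvTumor multiplicative-noise coefficients of variation
#'   (defaults 0.2 and 0.4; 0 gives deterministic samples).
#' @param focalSize size of the planted focal set (default 100).
#' @param focalMode \code{"invariant"} (focal genes exchangeable with the
#'   rest), \code{"low_noise"} (focal noise CV divided by
#'   \code{focalEffect}), or \code{"divergent"} (focal tumor means scaled by
#'   \code{focalEffect}).
#' @param focalEffect fold-change (divergent) or CV divisor (low_noise);
#'   default 1.
#' @param seed RNG seed.
#' @return A validated list of class \code{"BulkSimConfig"}.
#' @export
bulkSimConfig <- function(nGenes = 2000L, nNormal = 10L, nTumor = 10L,
                          logmeanMu = 1, logmeanSigma = 1,
                          cvNormal = 0.2, cvTumor = 0.4,
                          focalSize = 100L,
                          focalMode = c("invariant", "low_noise", "divergent"),
                          focalEffect = 1, seed = 1L) {
    cfg <- list(
        nGenes = checkCount(nGenes, "nGenes", 2L),
        nNormal = checkCount(nNormal, "nNormal", 2L),
        nTumor = checkCount(nTumor, "nTumor", 2L),
        logmeanMu = {
            if (length(logmeanMu) != 1L || !is.finite(logmeanMu))
                stop("invalid 'logmeanMu': must be a finite number")
            as.numeric(logmeanMu)
        },
        logmeanSigma = checkPositive(logmeanSigma, "logmeanSigma"),
        cvNormal = checkPositive(cvNormal, "cvNormal", strict = FALSE),
        cvTumor = checkPositive(cvTumor, "cvTumor", strict = FALSE),
        focalSize = checkCount(focalSize, "focalSize", 3L),
        focalMode = match.arg(focalMode),
        focalEffect = checkPositive(focalEffect, "focalEffect"),
        seed = checkCount(seed, "seed", 0L))
    if (cfg$focalSize >= cfg$nGenes)
        stop("invalid 'focalSize': must be smaller than nGenes")
    class(cfg) <- "BulkSimConfig"
    cfg
}

## log-normal multiplier with mean 1 and coefficient of variation cv
rNoise <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    s2 <- log(1 + cv^2)
    rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a bulk tumor/normal expression matrix with a planted focal set
#'
#' @param config a [bulkSimConfig()].
#' @return list with elements \code{matrix} (\linkS4class{ExpressionMatrix})
#'   and \code{focal} (\linkS4class{GeneSet}). In \code{"invariant"} mode the
#'   focal genes are a uniform random subset, statistically exchangeable with
#'   the rest; in \code{"divergent"} mode their tumor means are multiplied by
#'   \code{focalEffect}.
#' @examples
#' sim <- simulateBulk(bulkSimConfig(nGenes = 200, focalSize = 20, seed = 7))
#' dim(abundance(sim$matrix))
#' @export
simulateBulk <- function(config) {
    stopifnot(inherits(config, "BulkSimConfig"))
    withr::with_seed(config$seed, {
        geneIds <- sprintf("gene%05d", seq_len(config$nGenes))
        sampleIds <- c(sprintf("N%02d", seq_len(config$nNormal)),
                       sprintf("T%02d", seq_len(config$nTumor)))
        cond <- rep(c("normal", "tumor"), c(config$nNormal, config$nTumor))
        baseline <- rlnorm(config$nGenes, config$logmeanMu,
                           config$logmeanSigma)
        focalIdx <- sample.int(config$nGenes, config$focalSize)
        means <- matrix(baseline, config$nGenes, length(sampleIds))
        if (config$focalMode == "divergent")
            means[focalIdx, cond == "tumor"] <-
                means[focalIdx, cond == "tumor"] * config$focalEffect
        cvGene <- matrix(rep(ifelse(cond == "normal", config$cvNormal,
                                    config$cvTumor),
                             each = config$nGenes),
                         config$nGenes, length(sampleIds))
        if (config$focalMode == "low_noise")
            cvGene[focalIdx, ] <- cvGene[focalIdx, ] / config$focalEffect
        noise <- matrix(1, config$nGenes, length(sampleIds))
        for (cv in unique(as.vector(cvGene))) {
            idx <- cvGene == cv
            noise[idx] <- rNoise(sum(idx), cv)
        }
        values <- means * noise
        dimnames(values) <- list(geneIds, sampleIds)
        list(matrix = ExpressionMatrix(values, cond),
             focal = GeneSet("focal", geneIds[sort(focalIdx)]))
    })
}

#' Configuration for the scale-free network simulator
#'
#' @param nNodes number of genes/nodes (default 2000).
#' @param alpha power-law exponent of the target degree distribution
#'   (must exceed 1; default 2.5).
#' @param focalSize planted focal-set size (default 100).
#' @param focalDegreeBoost multiplicative factor (>= 1) applied to focal
#'   nodes' target degrees before edge realization (default 1).
#' @param maxDegree cap on target degrees (default \code{nNodes - 1}).
#' @param seed RNG seed.
#' @return A validated list of class \code{"NetworkSimConfig"}.
#' @export
networkSimConfig <- function(nNodes = 2000L, alpha = 2.5, focalSize = 100L,
                             focalDegreeBoost = 1, maxDegree = NULL,
                             seed = 1L) {
    cfg <- list(
        nNodes = checkCount(nNodes, "nNodes", 3L),
        alpha = checkPositive(alpha, "alpha"),
        focalSize = checkCount(focalSize, "focalSize", 1L),
        focalDegreeBoost = checkPositive(focalDegreeBoost,
                                         "focalDegreeBoost"),
        maxDegree = if (is.null(maxDegree)) NULL
                    else checkCount(maxDegree, "maxDegree", 1L),
        seed = checkCount(seed, "seed", 0L))
    if (cfg$alpha <= 1) stop("invalid 'alpha': must exceed 1")
    if (cfg$focalDegreeBoost < 1)
        stop("invalid 'focalDegreeBoost': must be >= 1")
    if (cfg$focalSize >= cfg$nNodes)
        stop("invalid 'focalSize': must be smaller than nNodes")
    class(cfg) <- "NetworkSimConfig"
    cfg
}

#' Draw from a discrete power law P(k) proportional to k^-alpha
#'
#' Support is \code{xmin, ..., maxK}; the cap only matters for very heavy
#' tails.
#'
#' @param n number of draws.
#' @param alpha exponent (> 1).
#' @param xmin lower bound (default 1).
#' @param maxK upper support bound (default 1e5).
#' @return integer vector of draws.
#' @export
rPowerLaw <- function(n, alpha, xmin = 1L, maxK = 1e5L) {
    k <- seq.int(xmin, maxK)
    p <- k^(-alpha)
    sample(k, n, replace = TRUE, prob = p)
}

#' Simulate a scale-free interaction network with a planted degree boost
#'
#' Target degrees are drawn from a discrete power law with exponent
#' \code{alpha}; focal nodes' targets are multiplied by
#' \code{focalDegreeBoost}. Edges are realized configuration-model style by
#' random stub matching, rejecting self-loops and multi-edges (erased
#' configuration model), so realized degrees track the targets closely for
#' sparse graphs. An odd stub total is repaired by adding a single stub to
#' the lowest-degree node, announced by message.
#'
#' @param config a [networkSimConfig()].
#' @return list with \code{network} (\linkS4class{InteractionNetwork}) and
#'   \code{focal} (\linkS4class{GeneSet}).
#' @examples
#' sim <- simulateNetwork(networkSimConfig(nNodes = 300, focalSize = 30,
#'                                         seed = 3))
#' igraph::vcount(interactionGraph(sim$network))
#' @export
simulateNetwork <- function(config) {
    stopifnot(inherits(config, "NetworkSimConfig"))
    maxDeg <- min(config$nNodes - 1L,
                  if (is.null(config$maxDegree)) config$nNodes - 1L
                  else config$maxDegree)
    withr::with_seed(config$seed, {
        ids <- sprintf("gene%05d", seq_len(config$nNodes))
        deg <- rPowerLaw(config$nNodes, config$alpha, maxK = maxDeg)
        focalIdx <- sample.int(config$nNodes, config$focalSize)
        deg[focalIdx] <- pmin(maxDeg,
                              as.integer(round(deg[focalIdx] *
                                               config$focalDegreeBoost)))
        if (sum(deg) %% 2L == 1L) {
            low <- which.min(deg)
            deg[low] <- deg[low] + 1L
            message("odd stub total; added one stub to node ", ids[low])
        }
        stubs <- rep.int(seq_len(config$nNodes), deg)
        stubs <- stubs[sample.int(length(stubs))]
        half <- length(stubs) / 2L
        a <- stubs[seq_len(half)]
        b <- stubs[half + seq_len(half)]
        keep <- a != b
        a <- a[keep]; b <- b[keep]
        key <- paste(pmin(a, b), pmax(a, b))
        keep <- !duplicated(key)
        edges <- cbind(ids[a[keep]], ids[b[keep]])
        g <- igraph::graph_from_edgelist(edges, directed = FALSE)
        g <- igraph::add_vertices(g, config$nNodes - igraph::vcount(g),
                                  name = setdiff(ids, igraph::V(g)$name))
        list(network = new("InteractionNetwork", graph = g),
             focal = GeneSet("focal", ids[sort(focalIdx)]))
    })
}

#' Configuration for the clustered single-cell count simulator
#'
#' Counts are negative binomial; per-gene baseline means spread log-normally
#' around \code{nbMean} and vary mildly between clusters. A
#' \code{deFraction} of genes per cluster receives a planted tumor-vs-normal
#' log fold-change of \code{deLogfc}, with an exact \code{focalOverlap}
#' fraction of the planted genes drawn from the focal set.
#'
#' @param nCellsPerClusterPerCondition cells per cluster per condition
#'   (default 100).
#' @param nClusters number of clusters (default 3).
#' @param nGenes number of genes (default 1000).
#' @param nbMean median per-gene mean count (default 5, so nearly all genes
#'   are detected in well over half the cells and survive the 50\% DE
#'   filter).
#' @param nbDispersion negative-binomial size parameter (default 2).
#' @param geneMeanSigma sdlog of the per-gene spread of baseline means
#'   (default 0.4).
#' @param deFraction fraction of genes with a planted condition effect per
#'   cluster (default 0.1).
#' @param deLogfc planted natural-log fold-change magnitude (default 2).
#'   Each planted gene is up- or down-regulated; the up-probability
#'   \eqn{(1 - e^{-l}) / (e^l - e^{-l})} is chosen so the planted effects
#'   are mass-neutral in expectation, keeping library-size normalization
#'   unbiased for the null genes.
#' @param focalOverlap fraction of planted DE genes drawn from the focal set
#'   (default 0.08).
#' @param mitoFractionRange interval for per-cell mitochondrial fractions
#'   (default c(0.01, 0.10)).
#' @param seed RNG seed.
#' @return A validated list of class \code{"SingleCellSimConfig"}.
#' @export
singleCellSimConfig <- function(nCellsPerClusterPerCondition = 100L,
                                nClusters = 3L, nGenes = 1000L,
                                nbMean = 5, nbDispersion = 2,
                                geneMeanSigma = 0.4,
                                deFraction = 0.1, deLogfc = 2,
                                focalOverlap = 0.08,
                                mitoFractionRange = c(0.01, 0.10),
                                seed = 1L) {
    cfg <- list(
        nCells = checkCount(nCellsPerClusterPerCondition,
                            "nCellsPerClusterPerCondition", 3L),
        nClusters = checkCount(nClusters, "nClusters", 1L),
        nGenes = checkCount(nGenes, "nGenes", 10L),
        nbMean = checkPositive(nbMean, "nbMean"),
        nbDispersion = checkPositive(nbDispersion, "nbDispersion"),
        geneMeanSigma = checkPositive(geneMeanSigma, "geneMeanSigma",
                                      strict = FALSE),
        deFraction = checkPositive(deFraction, "deFraction",
                                   strict = FALSE),
        deLogfc = as.numeric(deLogfc),
        focalOverlap = checkPositive(focalOverlap, "focalOverlap",
                                     strict = FALSE),
        mitoFractionRange = as.numeric(mitoFractionRange),
        seed = checkCount(seed, "seed", 0L))
    if (cfg$deFraction > 1) stop("invalid 'deFraction': must lie in [0, 1]")
    if (cfg$focalOverlap > 1)
        stop("invalid 'focalOverlap': must lie in [0, 1]")
    if (length(cfg$mitoFractionRange) != 2L ||
        any(cfg$mitoFractionRange < 0 | cfg$mitoFractionRange > 1) ||
        diff(cfg$mitoFractionRange) < 0)
        stop("invalid 'mitoFractionRange': must be an interval within [0, 1]")
    class(cfg) <- "SingleCellSimConfig"
    cfg
}

#' Simulate clustered single-cell counts with planted DE genes
#'
#' @param config a [singleCellSimConfig()].
#' @param focal a \linkS4class{GeneSet} whose members are among the simulated
#'   gene IDs (\code{gene00001 ...}); planted DE genes include an exact
#'   \code{focalOverlap} fraction from this set.
#' @return A \linkS4class{CellCounts} with ground-truth planted DE genes per
#'   cluster in \code{metadata(x)$planted_de}.
#' @examples
#' cfg <- singleCellSimConfig(nCellsPerClusterPerCondition = 20,
#'                            nClusters = 2, nGenes = 100, seed = 5)
#' focal <- GeneSet("focal", sprintf("gene%05d", 1:10))
#' cc <- simulateSingleCell(cfg, focal)
#' lengths(S4Vectors::metadata(cc)$planted_de)
#' @export
simulateSingleCell <- function(config, focal) {
    stopifnot(inherits(config, "SingleCellSimConfig"),
              is(focal, "GeneSet"))
    geneIds <- sprintf("gene%05d", seq_len(config$nGenes))
    focalIn <- intersect(members(focal), geneIds)
    nDE <- round(config$deFraction * config$nGenes)
    nFocalDE <- round(config$focalOverlap * nDE)
    if (nFocalDE > length(focalIn))
        stop("impossible overlap request: need ", nFocalDE,
             " focal genes among the simulated genes but only ",
             length(focalIn), " are present")
    withr::with_seed(config$seed, {
        baseMean <- rlnorm(config$nGenes, log(config$nbMean),
                           config$geneMeanSigma)
        nCond <- config$nCells
        counts <- list(); meta <- list(); planted <- list()
        for (cl in seq_len(config$nClusters)) {
            clName <- paste0("cluster", cl)
            clFactor <- rlnorm(config$nGenes, 0, 0.3)
            clMean <- baseMean * clFactor
            de <- character(0)
            if (nDE > 0) {
                deFocal <- sample(focalIn, nFocalDE)
                deOther <- sample(setdiff(geneIds, members(focal)),
                                  nDE - nFocalDE)
                de <- c(deFocal, deOther)
            }
            planted[[clName]] <- sort(de)
            tumorMean <- clMean
            ## planted effects are split between up- and down-regulation
            ## with the up-probability that keeps the expected per-cell
            ## library mass unchanged, so library-size normalization stays
            ## unbiased for the non-planted (null) genes
            l <- abs(config$deLogfc)
            if (length(de) && l > 0) {
                pUp <- (1 - exp(-l)) / (exp(l) - exp(-l))
                up <- rbinom(length(de), 1L, pUp) == 1L
                fac <- ifelse(up, exp(l), exp(-l))
                tumorMean[match(de, geneIds)] <-
                    tumorMean[match(de, geneIds)] * fac
            }
            mkCounts <- function(mu, n) {
                matrix(rnbinom(config$nGenes * n,
                               mu = rep(mu, n),
                               size = config$nbDispersion),
                       config$nGenes, n)
            }
            counts[[clName]] <- cbind(mkCounts(clMean, nCond),
                                      mkCounts(tumorMean, nCond))
            meta[[clName]] <- data.frame(
                cluster = clName,
                condition = rep(c("normal", "tumor"), each = nCond))
        }
        counts <- do.call(cbind, counts)
        meta <- do.call(rbind, meta)
        cellIds <- sprintf("cell%05d", seq_len(ncol(counts)))
        dimnames(counts) <- list(geneIds, cellIds)
        mito <- runif(ncol(counts), config$mitoFractionRange[1L],
                      config$mitoFractionRange[2L])
        CellCounts(counts, meta$cluster, meta$condition, mito,
                   plantedDE = planted)
    })
}
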