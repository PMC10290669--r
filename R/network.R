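## Interaction-network analytics: per-set degree reports (mean interactions
## per gene), discrete power-law fitting of the degree distribution, and
## induced-subgraph connectivity.

setMembers <- function(set) {
    if (is(set, "GeneSet")) members(set) else as.character(set)
}

#' Mean interactions per gene for a gene set
#'
#' Degrees are taken from the full graph and restricted to the set members
#' present in it. Genes in the set but absent from the graph are excluded
#' (not counted as degree 0) and reported in \code{nMissing}.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param set a \linkS4class{GeneSet}, gene ID vector, or \code{NULL} for
#'   all nodes.
#' @return list: \code{setName}, \code{meanDegree}, \code{degreeValues}
#'   (named), \code{nGenesInGraph}, \code{nMissing}.
#' @export
degreeReport <- function(net, set = NULL) {
    g <- interactionGraph(net)
    deg <- igraph::degree(g)
    if (is.null(set)) {
        ids <- names(deg); nm <- 0L; label <- "all"
    } else {
        m <- setMembers(set)
        ids <- intersect(m, names(deg))
        nm <- length(m) - length(ids)
        label <- if (is(set, "GeneSet")) setName(set) else "set"
    }
    dv <- deg[ids]
    list(setName = label,
         meanDegree = if (length(dv)) mean(dv) else NA_real_,
         degreeValues = dv,
         nGenesInGraph = length(dv),
         nMissing = nm)
}

#' Degree report after excluding a gene set (e.g. transcription factors)
#'
#' @inheritParams degreeReport
#' @param excluded a \linkS4class{GeneSet} or gene ID vector removed from
#'   \code{set} before reporting.
#' @return as [degreeReport()]; an empty report (with warning) when the
#'   exclusion removes everything.
#' @export
degreeReportExcluding <- function(net, set, excluded) {
    keep <- setdiff(setMembers(set), setMembers(excluded))
    if (!length(keep)) {
        warning("exclusion removed every member of the set")
        return(list(setName = "set-excluded", meanDegree = NA_real_,
                    degreeValues = numeric(0), nGenesInGraph = 0L,
                    nMissing = 0L))
    }
    out <- degreeReport(net, keep)
    out$setName <- paste0(
        if (is(set, "GeneSet")) setName(set) else "set", "-minus-",
        if (is(excluded, "GeneSet")) setName(excluded) else "excluded")
    out
}

## generalized (Hurwitz) zeta for integer xmin >= 1
genZeta <- function(alpha, xmin) {
    z <- pracma::zeta(alpha)
    if (xmin > 1) z <- z - sum(seq_len(xmin - 1)^(-alpha))
    z
}

#' Discrete power-law fit of a degree distribution
#'
#' Maximum-likelihood exponent for \eqn{P(k) \propto k^{-\alpha}}, k >=
#' \code{xmin}, with the normalizing Hurwitz zeta evaluated exactly. The
#' cutoff is fixed (default 1) rather than optimized: the fit describes the
#' full degree distribution, matching how a single power-law curve is
#' overlaid on a degree-density plot.
#'
#' @param degrees positive integer degrees, >= 50 observations at or above
#'   \code{xmin}.
#' @param xmin lower cutoff (default 1).
#' @return A \linkS4class{PowerLawFit}.
#' @export
fitPowerLaw <- function(degrees, xmin = 1L) {
    k <- degrees[degrees >= xmin]
    if (length(k) < 50L)
        stop("need >= 50 degrees at or above xmin (got ", length(k), ")")
    if (any(k != round(k)) || any(k < 1))
        stop("degrees must be positive integers")
    if (length(unique(k)) == 1L)
        stop("degenerate input: all degrees equal, exponent unidentifiable")
    slk <- sum(log(k)); n <- length(k)
    nll <- function(alpha) n * log(genZeta(alpha, xmin)) + alpha * slk
    opt <- optimize(nll, c(1.0001, 20))
    new("PowerLawFit", alpha = opt$minimum, xmin = as.numeric(xmin),
        nTail = as.integer(n), loglik = -opt$objective)
}

#' Induced-subgraph connectivity report
#'
#' Restricts the graph to the set's members and measures their internal
#' structure. Because "connectivity as number of components" is ambiguous
#' (more components means a more fragmented set), both the component count
#' and the largest-component fraction are reported; directional claims
#' should use the latter.
#'
#' @inheritParams degreeReport
#' @param set a \linkS4class{GeneSet} or gene ID vector.
#' @return list: \code{nNodes}, \code{nEdges}, \code{nComponents},
#'   \code{largestComponentFraction}, \code{meanInternalDegree}.
#' @export
inducedSubgraphReport <- function(net, set) {
    g <- interactionGraph(net)
    ids <- intersect(setMembers(set), igraph::V(g)$name)
    if (!length(ids))
        return(list(nNodes = 0L, nEdges = 0L, nComponents = 0L,
                    largestComponentFraction = NA_real_,
                    meanInternalDegree = NA_real_))
    sg <- igraph::induced_subgraph(g, ids)
    comp <- igraph::components(sg)
    list(nNodes = as.integer(igraph::vcount(sg)),
         nEdges = as.integer(igraph::ecount(sg)),
         nComponents = as.integer(comp$no),
         largestComponentFraction = max(comp$csize) / igraph::vcount(sg),
         meanInternalDegree = mean(igraph::degree(sg)))
}

#' Density curve of log-scaled degrees
#'
#' Kernel density of log10(degree) over positive degrees; the returned
#' curve integrates to 1 (within numerical tolerance).
#'
#' @param degrees positive degrees.
#' @param n grid size for [stats::density()] (default 512).
#' @return data.frame with \code{logDegree} and \code{density}.
#' @export
degreeDensity <- function(degrees, n = 512L) {
    k <- degrees[degrees > 0]
    stopifnot(length(k) >= 2L)
    d <- density(log10(k), n = n)
    data.frame(logDegree = d$x, density = d$y)
}

#' Resampling null of a set's mean degree
#'
#' Builds the size-matched random-set null of mean interactions per gene
#' (the whole-graph vs random-sampling comparison) via [resamplingNull()].
#'
#' @inheritParams degreeReport
#' @param focal a \linkS4class{GeneSet}.
#' @param nReps,seed passed to [resamplingNull()].
#' @return A \linkS4class{ResamplingNull} of \code{"meanDegree"}.
#' @export
degreeNull <- function(net, focal, nReps = 100L, seed = 1L) {
    g <- interactionGraph(net)
    deg <- igraph::degree(g)
    resamplingNull(names(deg), focal,
                   function(ids) mean(deg[ids]), "meanDegree",
                   nReps = nReps, seed = seed)
}
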