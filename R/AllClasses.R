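#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom stats cor dist quantile rlnorm rnbinom runif sd var median
#'   optimize optim prcomp hclust cutree p.adjust wilcox.test density
#'   setNames as.dist cophenetic qlnorm qweibull dlnorm dweibull plnorm
#'   pweibull rbinom
#' @importFrom utils head read.delim write.table
NULL

setOldClass("igraph")
setOldClass("phylo")
setOldClass("hclust")

#' ExpressionMatrix: genes-by-samples abundances with condition labels
#'
#' Extends \linkS4class{SummarizedExperiment} with a single \code{"abundance"}
#' assay (TPM or arbitrary proteomic units; \code{NA} allowed for proteomics)
#' and a mandatory \code{condition} column in \code{colData} with values
#' \code{"normal"} or \code{"tumor"}. This is the substrate for all bulk
#' pairwise statistics.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @seealso [ExpressionMatrix()], [condition()], [abundance()]
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
    msg <- character()
    if (!"abundance" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'abundance' is required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, sprintf("duplicate gene identifier: %s",
                 rownames(object)[duplicated(rownames(object))][1L]))
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, sprintf("duplicate sample identifier: %s",
                 colnames(object)[duplicated(colnames(object))][1L]))
    cd <- SummarizedExperiment::colData(object)
    if (!"condition" %in% colnames(cd)) {
        msg <- c(msg, "colData must contain a 'condition' column")
    } else {
        cond <- as.character(cd$condition)
        bad <- setdiff(unique(cond), c("normal", "tumor"))
        if (length(bad))
            msg <- c(msg, sprintf("condition labels must be 'normal' or 'tumor' (found '%s')",
                     bad[1L]))
    }
    a <- SummarizedExperiment::assay(object, "abundance")
    if (any(is.infinite(a)))
        msg <- c(msg, "abundance values must be finite or NA")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs). \code{NA} entries mark missing
#'   proteomic measurements.
#' @param condition character vector, one of \code{"normal"}/\code{"tumor"}
#'   per sample, in column order (or named by sample ID).
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rlnorm(12), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' em <- ExpressionMatrix(m, c("normal", "normal", "tumor"))
#' condition(em)
#' @export
ExpressionMatrix <- function(values, condition) {
    values <- as.matrix(values)
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("'values' must carry gene rownames and sample colnames")
    if (!is.null(names(condition)))
        condition <- condition[colnames(values)]
    if (length(condition) != ncol(values))
        stop("'condition' must label every sample: got ", length(condition),
             " labels for ", ncol(values), " samples")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = values),
        colData = S4Vectors::DataFrame(
            condition = as.character(condition),
            row.names = colnames(values)))
    new("ExpressionMatrix", se)
}

#' GeneSet: a named collection of gene identifiers
#'
#' Gene identifiers are opaque strings matched case-sensitively; no
#' symbol/alias harmonization is attempted.
#'
#' @slot name single character, the set's label.
#' @slot members character vector of unique gene identifiers.
#' @seealso [GeneSet()], [members()], [setName()]
#' @export
setClass("GeneSet",
         representation(name = "character", members = "character"))

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@members) == 0L)
        msg <- c(msg, "a gene set must be non-empty")
    if (anyDuplicated(object@members))
        msg <- c(msg, "gene set members must be unique")
    if (anyNA(object@members))
        msg <- c(msg, "gene set members must not be NA")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSet
#'
#' @param name label of the set.
#' @param members character vector of gene identifiers (deduplicated,
#'   order preserved).
#' @return A \linkS4class{GeneSet}.
#' @examples
#' gs <- GeneSet("oncogenes", c("TP53", "KRAS", "MYC"))
#' members(gs)
#' @export
GeneSet <- function(name, members) {
    new("GeneSet", name = as.character(name),
        members = unique(as.character(members)))
}

#' InteractionNetwork: an undirected simple gene graph
#'
#' Wraps an \pkg{igraph} graph and guarantees it is undirected, with no
#' self-loops and no duplicate edges (redundant interactions collapse to a
#' single instance).
#'
#' @slot graph an undirected simple \pkg{igraph} graph with named vertices.
#' @seealso [InteractionNetwork()], [interactionGraph()]
#' @export
setClass("InteractionNetwork", representation(graph = "igraph"))

setValidity("InteractionNetwork", function(object) {
    g <- object@graph
    msg <- character()
    if (igraph::is_directed(g))
        msg <- c(msg, "graph must be undirected")
    if (!igraph::is_simple(g))
        msg <- c(msg, "graph must be simple (no self-loops or multi-edges)")
    if (is.null(igraph::V(g)$name))
        msg <- c(msg, "vertices must be named by gene identifier")
    if (length(msg)) msg else TRUE
})

#' Construct an InteractionNetwork from an edge table
#'
#' Unordered duplicate pairs (A,B)/(B,A) are collapsed to one edge and
#' self-loops dropped; counts of removed records are reported by message.
#'
#' @param edges two-column character matrix or data.frame of gene pairs, or
#'   an \pkg{igraph} graph (coerced to undirected simple).
#' @return An \linkS4class{InteractionNetwork}.
#' @examples
#' net <- InteractionNetwork(data.frame(a = c("A", "B", "B"),
#'                                      b = c("B", "A", "C")))
#' igraph::ecount(interactionGraph(net))  # 2: A-B deduplicated
#' @export
InteractionNetwork <- function(edges) {
    if (inherits(edges, "igraph")) {
        g <- igraph::as_undirected(edges, mode = "collapse")
        g <- igraph::simplify(g)
        if (is.null(igraph::V(g)$name))
            igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
        return(new("InteractionNetwork", graph = g))
    }
    edges <- as.matrix(edges)
    if (ncol(edges) < 2L)
        stop("'edges' must have two columns (interacting gene pairs)")
    edges <- matrix(as.character(edges[, 1:2]), ncol = 2L)
    loops <- edges[, 1L] == edges[, 2L]
    if (any(loops))
        message("removed ", sum(loops), " self-loop(s)")
    edges <- edges[!loops, , drop = FALSE]
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]), sep = "\r")
    dup <- duplicated(key)
    if (any(dup))
        message("collapsed ", sum(dup),
                " redundant interaction(s), keeping a single instance")
    edges <- edges[!dup, , drop = FALSE]
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    new("InteractionNetwork", graph = g)
}

#' CellCounts: single-cell counts with cluster/condition metadata
#'
#' Extends \linkS4class{SingleCellExperiment} with a \code{"counts"} assay of
#' non-negative integers and mandatory per-cell \code{cluster},
#' \code{condition} (\code{"normal"}/\code{"tumor"}) and \code{mito_fraction}
#' (in [0,1]) columns. Planted ground-truth DE genes (when the object comes
#' from the simulator) live in \code{metadata(x)$planted_de}, a list of gene
#' ID vectors named by cluster.
#'
#' @seealso [CellCounts()], [qcFilter()], [logNormalizeCells()]
#' @export
setClass("CellCounts", contains = "SingleCellExperiment")

setValidity("CellCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        v <- if (methods::is(cts, "sparseMatrix")) cts@x else as.numeric(cts)
        if (length(v) && (any(v < 0) || any(v != round(v))))
            msg <- c(msg, "counts must be non-negative integers")
    }
    cd <- SummarizedExperiment::colData(object)
    for (col in c("cluster", "condition", "mito_fraction"))
        if (!col %in% colnames(cd))
            msg <- c(msg, sprintf("colData must contain '%s'", col))
    if ("mito_fraction" %in% colnames(cd)) {
        mf <- cd$mito_fraction
        if (any(mf < 0 | mf > 1, na.rm = TRUE))
            msg <- c(msg, "mito_fraction must lie in [0, 1]")
    }
    if ("condition" %in% colnames(cd)) {
        bad <- setdiff(unique(as.character(cd$condition)),
                       c("normal", "tumor"))
        if (length(bad))
            msg <- c(msg, sprintf("condition labels must be 'normal' or 'tumor' (found '%s')",
                     bad[1L]))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CellCounts object
#'
#' @param counts integer matrix (dense or sparse), genes in rows, cells in
#'   columns, with dimnames.
#' @param cluster per-cell cluster label.
#' @param condition per-cell \code{"normal"}/\code{"tumor"} label.
#' @param mitoFraction per-cell mitochondrial-count fraction in [0,1].
#' @param plantedDE optional list (named by cluster) of ground-truth DE gene
#'   IDs, stored in \code{metadata()}.
#' @return A \linkS4class{CellCounts}.
#' @export
CellCounts <- function(counts, cluster, condition, mitoFraction,
                       plantedDE = list()) {
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(
            cluster = as.character(cluster),
            condition = as.character(condition),
            mito_fraction = as.numeric(mitoFraction),
            row.names = colnames(counts)))
    S4Vectors::metadata(sce)$planted_de <- plantedDE
    new("CellCounts", sce)
}

#' ResamplingNull: a size-matched random-gene-set null distribution
#'
#' Holds the statistic evaluated on \code{nReps} independent uniform random
#' gene sets of the focal set's size, the focal set's own value, and its
#' mid-rank empirical percentile within the null.
#'
#' @slot statisticName label of the statistic (e.g. \code{"eta2:NvsT"}).
#' @slot setSize number of focal genes found in the universe.
#' @slot nReps number of random draws.
#' @slot values statistic per replicate (length \code{nReps}).
#' @slot focalValue statistic for the focal set.
#' @slot percentile mid-rank percentile of \code{focalValue} in \code{values},
#'   in [0, 1].
#' @slot seed RNG seed used for the draws.
#' @seealso [resamplingNull()], [buildNull()]
#' @export
setClass("ResamplingNull",
         representation(statisticName = "character", setSize = "integer",
                        nReps = "integer", values = "numeric",
                        focalValue = "numeric", percentile = "numeric",
                        seed = "integer"))

setValidity("ResamplingNull", function(object) {
    msg <- character()
    if (length(object@values) != object@nReps)
        msg <- c(msg, "length(values) must equal nReps")
    if (!is.na(object@percentile) &&
        (object@percentile < 0 || object@percentile > 1))
        msg <- c(msg, "percentile must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' DistributionFit: one maximum-likelihood fit of an abundance distribution
#'
#' @slot family one of \code{"log-normal"}, \code{"loglogistic"},
#'   \code{"weibull"}, \code{"pareto"}, \code{"burr"}.
#' @slot params named numeric vector of fitted parameters (its length is the
#'   parameter count entering the AIC).
#' @slot loglik maximized log-likelihood.
#' @slot aic Akaike information criterion, \code{2 * k - 2 * loglik}.
#' @slot n number of observations used.
#' @seealso [fitDistributions()], [bestFit()]
#' @export
setClass("DistributionFit",
         representation(family = "character", params = "numeric",
                        loglik = "numeric", aic = "numeric", n = "integer"))

setValidity("DistributionFit", function(object) {
    msg <- character()
    k <- length(object@params)
    if (is.finite(object@aic) && is.finite(object@loglik) &&
        abs(object@aic - (2 * k - 2 * object@loglik)) > 1e-8)
        msg <- c(msg, "aic must equal 2*k - 2*loglik")
    if (object@n <= k)
        msg <- c(msg, "need more observations than parameters")
    if (length(msg)) msg else TRUE
})

#' PowerLawFit: discrete power-law fit of a degree distribution
#'
#' @slot alpha fitted exponent of \eqn{P(k) \propto k^{-\alpha}}.
#' @slot xmin lower cutoff of the fitted tail.
#' @slot nTail number of observations \eqn{\ge} xmin.
#' @slot loglik maximized log-likelihood over the tail.
#' @seealso [fitPowerLaw()]
#' @export
setClass("PowerLawFit",
         representation(alpha = "numeric", xmin = "numeric",
                        nTail = "integer", loglik = "numeric"))

setValidity("PowerLawFit", function(object) {
    msg <- character()
    if (object@alpha <= 1) msg <- c(msg, "alpha must exceed 1")
    if (object@xmin < 1) msg <- c(msg, "xmin must be >= 1")
    if (length(msg)) msg else TRUE
})
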