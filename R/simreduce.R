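## Sample-level structure: PCA embedding with between-condition Euclidean
## distances, neighbor-joining sample trees, and hierarchical clustering
## with an adjusted-Rand separation score.

#' PCA embedding of samples
#'
#' Samples are observations, the subset's genes are features; features are
#' centered (no unit-variance scaling) and by default log2(x + 1)
#' transformed. The first two principal-component scores are returned with
#' their explained-variance fractions.
#'
#' @param em an \linkS4class{ExpressionMatrix} with >= 3 samples.
#' @param subset a \linkS4class{GeneSet}, gene ID vector, or \code{NULL}.
#' @param logTransform apply log2(x + 1) first (default TRUE).
#' @return list of class \code{"SampleEmbedding"}: \code{sampleIds},
#'   \code{coordinates} (samples x 2), \code{explainedVariance} (length 2),
#'   \code{condition}.
#' @export
pcaEmbed <- function(em, subset = NULL, logTransform = TRUE) {
    stopifnot("need >= 3 samples for PCA" = ncol(em) >= 3L)
    a <- subsetValues(em, subset, logTransform)
    p <- prcomp(t(a), center = TRUE, scale. = FALSE)
    ev <- p$sdev^2 / sum(p$sdev^2)
    k <- min(2L, ncol(p$x))
    coords <- p$x[, seq_len(k), drop = FALSE]
    if (k < 2L) coords <- cbind(coords, 0)
    structure(list(sampleIds = colnames(em),
                   coordinates = coords,
                   explainedVariance = c(ev, 0)[1:2],
                   condition = condition(em)),
              class = "SampleEmbedding")
}

#' Mean normal-tumor Euclidean distance in a 2-D embedding
#'
#' @param embedding a \code{"SampleEmbedding"} from [pcaEmbed()].
#' @param condition optional per-sample labels overriding the embedding's.
#' @return mean Euclidean distance over all normal x tumor sample pairs.
#' @export
conditionDistance <- function(embedding, condition = NULL) {
    cond <- if (is.null(condition)) embedding$condition
            else as.character(condition)
    xy <- embedding$coordinates
    ni <- which(cond == "normal"); ti <- which(cond == "tumor")
    stopifnot(length(ni) >= 1L, length(ti) >= 1L)
    d <- outer(seq_along(ni), seq_along(ti), function(i, j)
        sqrt((xy[ni[i], 1L] - xy[ti[j], 1L])^2 +
             (xy[ni[i], 2L] - xy[ti[j], 2L])^2))
    mean(d)
}

#' Mean normal-tumor distance in full gene space
#'
#' The full-dimensional alternative to [conditionDistance()]: mean distance
#' over all normal x tumor sample pairs computed directly on the (optionally
#' log-transformed) expression values rather than in the 2-D embedding.
#'
#' @inheritParams sampleDistanceMatrix
#' @return mean between-condition distance.
#' @export
conditionDistanceFull <- function(em, subset = NULL, method = "euclidean",
                                  logTransform = TRUE) {
    d <- as.matrix(sampleDistanceMatrix(em, subset, method, logTransform))
    cond <- condition(em)
    mean(d[cond == "normal", cond == "tumor"])
}

#' Between-sample distance matrix
#'
#' @param em an \linkS4class{ExpressionMatrix}.
#' @param subset gene subset (as in [pcaEmbed()]).
#' @param method distance metric for [stats::dist()] (default
#'   \code{"euclidean"}).
#' @param logTransform apply log2(x + 1) first (default TRUE).
#' @return a \code{dist} object over the samples.
#' @export
sampleDistanceMatrix <- function(em, subset = NULL, method = "euclidean",
                                 logTransform = TRUE) {
    a <- subsetValues(em, subset, logTransform)
    dist(t(a), method = method)
}

#' Neighbor-joining sample tree
#'
#' Classical neighbor joining on a symmetric non-negative distance matrix,
#' giving a completely resolved unrooted tree; on an additive input the
#' leaf-to-leaf path lengths reproduce the input distances exactly.
#' Negative branch-length estimates are clamped to zero with the deficit
#' transferred to the adjacent edge; the raw estimates are kept in
#' \code{attr(tree, "rawEdgeLengths")}.
#'
#' @param d a \code{dist} or symmetric matrix with zero diagonal, >= 3
#'   leaves.
#' @return an \pkg{ape} \code{phylo} tree.
#' @examples
#' m <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' tr <- njTree(m)
#' sum(tr$edge.length)  # total branch length 11
#' @export
njTree <- function(d) {
    m <- as.matrix(d)
    stopifnot("need >= 3 leaves" = nrow(m) >= 3L)
    if (any(m < 0)) stop("distance matrix must be non-negative")
    if (max(abs(m - t(m))) > 1e-8) stop("distance matrix must be symmetric")
    tree <- ape::nj(as.dist(m))
    raw <- tree$edge.length
    if (any(tree$edge.length < 0)) {
        ## clamp each negative edge and push its deficit onto the edge's
        ## neighborhood: add to the other edges sharing its child node
        ## (standard practice; leaf-to-leaf distances through the pair of
        ## sibling edges are preserved)
        for (e in which(tree$edge.length < 0)) {
            deficit <- tree$edge.length[e]
            tree$edge.length[e] <- 0
            child <- tree$edge[e, 2L]
            adj <- which(tree$edge[, 1L] == child)
            if (length(adj))
                tree$edge.length[adj] <- tree$edge.length[adj] + deficit
        }
        tree$edge.length[tree$edge.length < 0] <- 0
    }
    attr(tree, "rawEdgeLengths") <- raw
    tree
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering (average linkage by default) on the same kind
#' of distance matrix as [njTree()].
#'
#' @param d a \code{dist} or symmetric matrix.
#' @param method linkage passed to [stats::hclust()] (default
#'   \code{"average"}).
#' @return an \code{hclust} dendrogram.
#' @export
hierarchicalCluster <- function(d, method = "average") {
    hclust(as.dist(as.matrix(d)), method = method)
}

phyloTwoCut <- function(tree) {
    ## 2-group leaf partition: remove the longest internal edge
    nTips <- length(tree$tip.label)
    internal <- which(tree$edge[, 2L] > nTips)
    e <- if (length(internal))
        internal[which.max(tree$edge.length[internal])]
    else which.max(tree$edge.length)
    g <- igraph::graph_from_edgelist(
        matrix(as.character(tree$edge[-e, , drop = FALSE]), ncol = 2L),
        directed = FALSE)
    missing <- setdiff(as.character(unique(as.vector(tree$edge))),
                       igraph::V(g)$name)
    if (length(missing)) g <- igraph::add_vertices(g, length(missing),
                                                   name = missing)
    comp <- igraph::components(g)$membership
    setNames(comp[as.character(seq_len(nTips))], tree$tip.label)
}

#' Condition-separation score of a 2-cluster cut
#'
#' Cuts the dendrogram (or unrooted tree, at its longest internal edge)
#' into two groups and scores agreement with the condition labels by the
#' adjusted Rand index.
#'
#' @param x an \code{hclust}, an \pkg{ape} \code{phylo}, or a precomputed
#'   2-group membership vector.
#' @param condition per-sample \code{"normal"}/\code{"tumor"} labels, named
#'   by sample or in leaf order.
#' @return ARI in [-1, 1]; \code{NA} with a warning when only one condition
#'   is present.
#' @export
separationScore <- function(x, condition) {
    cut2 <- if (inherits(x, "hclust")) cutree(x, k = 2L)
            else if (inherits(x, "phylo")) phyloTwoCut(x)
            else x
    cond <- condition
    if (!is.null(names(cut2)) && !is.null(names(cond)))
        cond <- cond[names(cut2)]
    if (length(unique(cond)) < 2L) {
        warning("only one condition present; separation undefined")
        return(NA_real_)
    }
    mclust::adjustedRandIndex(cut2, cond)
}

#' Tree path-length matrix between leaves
#'
#' Leaf-to-leaf distances along the tree's branches (the additivity check
#' for [njTree()]).
#'
#' @param tree a \code{phylo}.
#' @return symmetric matrix of path lengths, leaves in \code{tip.label}
#'   order.
#' @export
treeLeafDistances <- function(tree) {
    ape::cophenetic.phylo(tree)
}
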