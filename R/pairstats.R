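## Pairwise sample statistics over a gene subset: Pearson r, Spearman rho,
## rank-binned mutual information (Doane's rule for the bin count, plugin
## estimate in nats), and expression noise eta^2 = sigma^2 / mu^2 (squared
## coefficient of variation, population variance), averaged over sample-pair
## groups (normal-normal, tumor-tumor, normal-tumor).

#' Pearson correlation between two samples
#'
#' @param x,y expression values over the same n genes (n >= 3).
#' @return correlation in [-1, 1]; \code{NA} with a warning if either vector
#'   is constant.
#' @export
pearsonR <- function(x, y) {
    stopifnot(length(x) == length(y), length(x) >= 3L)
    if (sd(x) == 0 || sd(y) == 0) {
        warning("constant vector: Pearson correlation undefined")
        return(NA_real_)
    }
    cor(x, y)
}

#' Spearman rank correlation between two samples
#'
#' Computed as Pearson correlation of mid-ranks (ties get average ranks),
#' which equals the classical rank-difference formula when no ties occur.
#'
#' @inheritParams pearsonR
#' @return correlation in [-1, 1].
#' @export
spearmanRho <- function(x, y) {
    stopifnot(length(x) == length(y), length(x) >= 3L)
    rx <- rank(x); ry <- rank(y)
    if (sd(rx) == 0 || sd(ry) == 0) {
        warning("constant vector: Spearman correlation undefined")
        return(NA_real_)
    }
    cor(rx, ry)
}

#' Doane's rule for a histogram bin count
#'
#' \eqn{k = \lceil 1 + \log_2 n + \log_2(1 + |g_1| / \sigma_{g_1}) \rceil}
#' with \eqn{g_1} the sample skewness and
#' \eqn{\sigma_{g_1} = \sqrt{6 (n-2) / ((n+1)(n+3))}}; at least 2 bins are
#' always returned.
#'
#' @param values numeric sample, n >= 4.
#' @return integer bin count.
#' @examples
#' doaneBins(1:8)  # symmetric, returns 4
#' @export
doaneBins <- function(values) {
    n <- length(values)
    stopifnot(n >= 4L)
    m <- mean(values)
    m2 <- mean((values - m)^2)
    g1 <- if (m2 == 0) 0 else mean((values - m)^3) / m2^1.5
    sg1 <- sqrt(6 * (n - 2) / ((n + 1) * (n + 3)))
    k <- ceiling(1 + log2(n) + log2(1 + abs(g1) / sg1))
    max(2L, as.integer(k))
}

#' Plugin mutual information from a joint contingency table
#'
#' @param joint matrix of joint bin counts.
#' @return MI in nats, \eqn{\sum p(x,y) \ln[p(x,y) / (p(x) p(y))]}.
#' @examples
#' miFromJoint(matrix(c(50, 0, 0, 50), 2))  # log(2)
#' @export
miFromJoint <- function(joint) {
    p <- joint / sum(joint)
    px <- rowSums(p); py <- colSums(p)
    idx <- which(p > 0, arr.ind = TRUE)
    sum(p[idx] * log(p[idx] / (px[idx[, 1L]] * py[idx[, 2L]])))
}

rankBins <- function(x, k) {
    n <- length(x)
    pmin(k, pmax(1L, ceiling(k * rank(x, ties.method = "average") / n)))
}

#' Mutual information between two samples (rank-binned plugin estimate)
#'
#' Each vector is rank-transformed; ranks are partitioned into
#' \code{k = doaneBins(ranks)} equal-count bins (one k per pair — both
#' vectors share n, and untied ranks are symmetric so k reduces to
#' \eqn{\lceil 1 + \log_2 n \rceil}); the joint and marginal bin frequencies
#' give the plugin MI in nats. No bias-correction term is subtracted.
#'
#' @inheritParams pearsonR
#' @param bins optional bin-count override (default: Doane's rule).
#' @return MI in nats, >= 0 and <= min(H(X), H(Y)); 0 with a warning when
#'   binning is degenerate (k < 2).
#' @export
mutualInformation <- function(x, y, bins = NULL) {
    stopifnot(length(x) == length(y), length(x) >= 4L)
    k <- if (is.null(bins)) doaneBins(rank(x, ties.method = "average"))
         else as.integer(bins)
    if (k < 2L) {
        warning("degenerate binning (k < 2); returning 0")
        return(0)
    }
    bx <- rankBins(x, k); by <- rankBins(y, k)
    joint <- matrix(tabulate(bx + k * (by - 1L), k * k), k, k)
    miFromJoint(joint)
}

#' Per-gene expression noise between two samples
#'
#' \eqn{\eta^2 = \sigma^2 / \mu^2} with the population (divide-by-n)
#' variance over the two values, which reduces to
#' \eqn{(x - y)^2 / (x + y)^2} — the squared coefficient of variation, so
#' the statistic is scale invariant. Genes with \eqn{x + y = 0} are
#' undefined (\code{NA}).
#'
#' @param x,y the gene's expression value in each of the two samples
#'   (vectorized over genes).
#' @return per-gene noise values.
#' @examples
#' geneNoise(1, 3)  # 0.25
#' @export
geneNoise <- function(x, y) {
    out <- (x - y)^2 / (x + y)^2
    out[x + y == 0] <- NA_real_
    out
}

#' Total average noise between two samples
#'
#' Arithmetic mean of [geneNoise()] over the genes; genes with zero
#' expression in both samples are excluded (their count is returned as the
#' \code{"nExcluded"} attribute).
#'
#' @inheritParams pearsonR
#' @return mean noise (>= 0).
#' @export
totalNoise <- function(x, y) {
    g <- geneNoise(x, y)
    out <- mean(g, na.rm = TRUE)
    attr(out, "nExcluded") <- sum(is.na(g))
    out
}

pairIndices <- function(cond, group) {
    ni <- which(cond == "normal"); ti <- which(cond == "tumor")
    switch(group,
        NvsN = {
            stopifnot("need >= 2 normal samples" = length(ni) >= 2L)
            t(utils::combn(ni, 2L))
        },
        TvsT = {
            stopifnot("need >= 2 tumor samples" = length(ti) >= 2L)
            t(utils::combn(ti, 2L))
        },
        NvsT = {
            stopifnot("need >= 1 sample per condition" =
                          length(ni) >= 1L && length(ti) >= 1L)
            as.matrix(expand.grid(ni, ti))
        },
        stop("unknown group: ", group))
}

subsetValues <- function(em, subset, logTransform = FALSE) {
    a <- abundance(em)
    if (!is.null(subset)) {
        ids <- if (is(subset, "GeneSet")) members(subset)
               else as.character(subset)
        found <- intersect(ids, rownames(a))
        if (!length(found)) stop("no subset genes found in the matrix")
        if (length(found) < length(ids))
            message(length(ids) - length(found),
                    " subset gene(s) absent from the matrix were dropped")
        a <- a[found, , drop = FALSE]
    }
    if (logTransform) a <- log2(a + 1)
    a
}

## All four statistics for every requested pair, on a plain value matrix.
pairStatsOnMatrix <- function(a, pairs,
                              statistics = c("r", "rho", "mi", "eta2")) {
    res <- list()
    if ("r" %in% statistics || "rho" %in% statistics) {
        cols <- sort(unique(as.vector(pairs)))
        if ("r" %in% statistics) {
            cc <- suppressWarnings(cor(a[, cols, drop = FALSE]))
            rownames(cc) <- colnames(cc) <- as.character(cols)
            res$r <- cc[cbind(as.character(pairs[, 1L]),
                              as.character(pairs[, 2L]))]
        }
        if ("rho" %in% statistics) {
            cs <- suppressWarnings(
                cor(a[, cols, drop = FALSE], method = "spearman"))
            rownames(cs) <- colnames(cs) <- as.character(cols)
            res$rho <- cs[cbind(as.character(pairs[, 1L]),
                                as.character(pairs[, 2L]))]
        }
    }
    if ("mi" %in% statistics) {
        k <- doaneBins(rank(a[, 1L], ties.method = "average"))
        bins <- apply(a, 2L, rankBins, k = k)
        res$mi <- vapply(seq_len(nrow(pairs)), function(p) {
            bx <- bins[, pairs[p, 1L]]; by <- bins[, pairs[p, 2L]]
            miFromJoint(matrix(tabulate(bx + k * (by - 1L), k * k), k, k))
        }, 0)
    }
    if ("eta2" %in% statistics) {
        res$eta2 <- vapply(seq_len(nrow(pairs)), function(p) {
            x <- a[, pairs[p, 1L]]; y <- a[, pairs[p, 2L]]
            mean(geneNoise(x, y), na.rm = TRUE)
        }, 0)
    }
    res
}

#' Aggregate pairwise statistics over a sample-pair group
#'
#' Computes each requested statistic on the gene subset's rows for every
#' sample pair in the group — all unordered normal pairs (\code{NvsN}), all
#' unordered tumor pairs (\code{TvsT}), or all normal-by-tumor cross pairs
#' (\code{NvsT}) — then averages them.
#'
#' @param em an \linkS4class{ExpressionMatrix}.
#' @param subset a \linkS4class{GeneSet}, character vector of gene IDs, or
#'   \code{NULL} for the whole matrix.
#' @param group one of \code{"NvsN"}, \code{"TvsT"}, \code{"NvsT"}.
#' @param statistics which of \code{"r"}, \code{"rho"}, \code{"mi"},
#'   \code{"eta2"} to compute (default all).
#' @param logTransform apply log2(x + 1) before computing (default FALSE:
#'   statistics are taken on the abundance scale as given).
#' @return One-row data.frame: \code{gene_subset}, \code{group}, the mean of
#'   each statistic over the pairs, and \code{n_pairs}.
#' @export
aggregatePairs <- function(em, subset = NULL,
                           group = c("NvsN", "TvsT", "NvsT"),
                           statistics = c("r", "rho", "mi", "eta2"),
                           logTransform = FALSE) {
    group <- match.arg(group)
    statistics <- match.arg(statistics, several.ok = TRUE)
    a <- subsetValues(em, subset, logTransform)
    stopifnot("need >= 3 genes for pairwise statistics" = nrow(a) >= 3L)
    pairs <- pairIndices(condition(em), group)
    per <- pairStatsOnMatrix(a, pairs, statistics)
    out <- data.frame(
        gene_subset = if (is.null(subset)) "whole"
                      else if (is(subset, "GeneSet")) setName(subset)
                      else "subset",
        group = group)
    for (s in c("r", "rho", "mi", "eta2"))
        out[[s]] <- if (s %in% statistics) mean(per[[s]]) else NA_real_
    out$n_pairs <- nrow(pairs)
    out
}

#' Full pair-statistic report over all three sample-pair groups
#'
#' @inheritParams aggregatePairs
#' @return Three-row data.frame (one per group), the shape of the bulk
#'   correlation/noise summary tables.
#' @examples
#' sim <- simulateBulk(bulkSimConfig(nGenes = 100, nNormal = 3, nTumor = 3,
#'                                   focalSize = 10, seed = 1))
#' pairStatReport(sim$matrix)
#' @export
pairStatReport <- function(em, subset = NULL,
                           statistics = c("r", "rho", "mi", "eta2"),
                           logTransform = FALSE) {
    do.call(rbind, lapply(c("NvsN", "TvsT", "NvsT"), function(g)
        aggregatePairs(em, subset, g, statistics, logTransform)))
}
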