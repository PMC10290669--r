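## Single-cell stage: QC filtering, log-normalization, per-cluster
## tumor-vs-normal Wilcoxon differential expression, and the focal-set
## fraction among significant DE genes.

#' Quality-control filter for cells
#'
#' Retains cells with strictly more than \code{minGenes} detected genes
#' (count > 0) and a mitochondrial fraction strictly below \code{maxMito}.
#' Removal counts are reported by message; the filter is idempotent.
#'
#' @param cc a \linkS4class{CellCounts}.
#' @param minGenes detected-gene threshold (default 200).
#' @param maxMito mitochondrial-fraction threshold (default 0.15).
#' @return The filtered \linkS4class{CellCounts}.
#' @export
qcFilter <- function(cc, minGenes = 200L, maxMito = 0.15) {
    cts <- SummarizedExperiment::assay(cc, "counts")
    detected <- Matrix::colSums(cts > 0)
    mito <- SummarizedExperiment::colData(cc)$mito_fraction
    keep <- detected > minGenes & mito < maxMito
    message("qcFilter: removed ", sum(!keep), " of ", ncol(cc),
            " cell(s) (", sum(detected <= minGenes), " low-complexity, ",
            sum(mito >= maxMito), " high-mitochondrial)")
    cc[, keep]
}

#' Log-normalize single-cell counts
#'
#' Per cell: \code{log(1 + count / total_counts * scaleFactor)} (natural
#' log), stored as the \code{"lognorm"} assay. Cells with zero total counts
#' yield all-zero normalized values.
#'
#' @param cc a \linkS4class{CellCounts}.
#' @param scaleFactor library-size scale factor (default 10000).
#' @return \code{cc} with the added \code{"lognorm"} assay.
#' @export
logNormalizeCells <- function(cc, scaleFactor = 1e4) {
    cts <- as.matrix(SummarizedExperiment::assay(cc, "counts"))
    totals <- colSums(cts)
    totals[totals == 0] <- 1
    norm <- log1p(sweep(cts, 2L, totals, "/") * scaleFactor)
    SummarizedExperiment::assay(cc, "lognorm") <- norm
    cc
}

#' Per-cluster tumor-vs-normal differential expression
#'
#' Within one cluster, genes detected (count > 0) in at least \code{minPct}
#' of the cells of either condition group are tested by a two-sided
#' Wilcoxon rank-sum test on log-normalized values, with Benjamini-Hochberg
#' adjustment across the cluster's tested genes. The log fold-change is the
#' difference of \code{log(1 + mean normalized expression)} between tumor
#' and normal cells.
#'
#' @param cc a \linkS4class{CellCounts} carrying a \code{"lognorm"} assay
#'   (see [logNormalizeCells()]).
#' @param cluster cluster label to test; both conditions must contribute at
#'   least 3 cells, otherwise the cluster is skipped (empty result, with a
#'   message).
#' @param minPct detection-fraction filter (default 0.5).
#' @return data.frame: \code{cluster}, \code{gene}, \code{p_value},
#'   \code{adjusted_p}, \code{log_fc}, \code{pct_tumor}, \code{pct_normal}.
#' @export
clusterDE <- function(cc, cluster, minPct = 0.5) {
    empty <- data.frame(cluster = character(), gene = character(),
                        p_value = numeric(), adjusted_p = numeric(),
                        log_fc = numeric(), pct_tumor = numeric(),
                        pct_normal = numeric())
    cd <- SummarizedExperiment::colData(cc)
    inCl <- cd$cluster == cluster
    if (!any(inCl)) {
        message("cluster '", cluster, "' not present; skipped")
        return(empty)
    }
    cond <- as.character(cd$condition[inCl])
    if (sum(cond == "normal") < 3L || sum(cond == "tumor") < 3L) {
        message("cluster '", cluster,
                "' lacks >= 3 cells in both conditions; skipped")
        return(empty)
    }
    if (!"lognorm" %in% SummarizedExperiment::assayNames(cc))
        stop("run logNormalizeCells() first: 'lognorm' assay missing")
    cts <- as.matrix(SummarizedExperiment::assay(cc, "counts"))[, inCl,
                                                                drop = FALSE]
    nrm <- as.matrix(SummarizedExperiment::assay(cc, "lognorm"))[, inCl,
                                                                 drop = FALSE]
    tum <- cond == "tumor"
    pctT <- rowMeans(cts[, tum, drop = FALSE] > 0)
    pctN <- rowMeans(cts[, !tum, drop = FALSE] > 0)
    tested <- which(pctT >= minPct | pctN >= minPct)
    if (!length(tested)) return(empty)
    p <- vapply(tested, function(i)
        suppressWarnings(wilcox.test(nrm[i, tum], nrm[i, !tum],
                                     exact = FALSE)$p.value), 0)
    lfc <- log1p(rowMeans(nrm[tested, tum, drop = FALSE])) -
        log1p(rowMeans(nrm[tested, !tum, drop = FALSE]))
    data.frame(cluster = cluster,
               gene = rownames(cc)[tested],
               p_value = p,
               adjusted_p = p.adjust(p, method = "BH"),
               log_fc = lfc,
               pct_tumor = pctT[tested],
               pct_normal = pctN[tested],
               row.names = NULL)
}

#' Differential expression across all clusters
#'
#' Runs [clusterDE()] for every cluster present in both conditions and
#' binds the results.
#'
#' @inheritParams clusterDE
#' @return data.frame as [clusterDE()], rows across clusters.
#' @export
clusterDEAll <- function(cc, minPct = 0.5) {
    cls <- unique(SummarizedExperiment::colData(cc)$cluster)
    do.call(rbind, lapply(sort(cls), clusterDE, cc = cc, minPct = minPct))
}

#' Focal-set fraction among significant DE genes
#'
#' The proportion of significant DE genes (adjusted p below \code{alpha})
#' that belong to the focal set, per cluster and overall (overall counts a
#' gene once per cluster it is significant in).
#'
#' @param de data.frame from [clusterDE()]/[clusterDEAll()].
#' @param focal a \linkS4class{GeneSet}.
#' @param alpha significance threshold on \code{adjusted_p} (default 0.05).
#' @return list: \code{perCluster} (data.frame with \code{cluster},
#'   \code{n_de}, \code{n_focal}, \code{fraction}), \code{overall}, and
#'   \code{noDEGenes} flagging clusters with no significant genes (their
#'   fraction is reported as 0).
#' @export
focalFraction <- function(de, focal, alpha = 0.05) {
    f <- members(focal)
    if (is.null(de) || nrow(de) == 0L) {
        warning("no DE results supplied; fraction reported as 0")
        return(list(perCluster = data.frame(cluster = character(),
                        n_de = integer(), n_focal = integer(),
                        fraction = numeric()),
                    overall = 0, noDEGenes = character()))
    }
    sig <- de[!is.na(de$adjusted_p) & de$adjusted_p < alpha, , drop = FALSE]
    clusters <- unique(de$cluster)
    per <- do.call(rbind, lapply(clusters, function(cl) {
        genes <- sig$gene[sig$cluster == cl]
        data.frame(cluster = cl, n_de = length(genes),
                   n_focal = sum(genes %in% f),
                   fraction = if (length(genes))
                       sum(genes %in% f) / length(genes) else 0)
    }))
    if (is.null(per))
        per <- data.frame(cluster = character(), n_de = integer(),
                          n_focal = integer(), fraction = numeric())
    overall <- if (nrow(sig)) sum(sig$gene %in% f) / nrow(sig) else 0
    list(perCluster = per, overall = overall,
         noDEGenes = per$cluster[per$n_de == 0])
}
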