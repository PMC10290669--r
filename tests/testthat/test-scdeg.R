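# Single-cell QC, normalization, per-cluster Wilcoxon DE and the focal
# fraction.

test_that("QC filter applies both thresholds strictly and is idempotent", {
    counts <- matrix(0L, 300, 3,
                     dimnames = list(sprintf("g%03d", 1:300),
                                     c("low", "highMito", "good")))
    counts[1:150, "low"] <- 1L        # 150 detected genes: removed
    counts[1:250, "highMito"] <- 1L   # mito 0.20: removed
    counts[1:250, "good"] <- 1L       # 250 genes, mito 0.10: retained
    cc <- CellCounts(counts, rep("c1", 3), rep("tumor", 3),
                     c(0.05, 0.20, 0.10))
    out <- suppressMessages(qcFilter(cc))
    expect_identical(colnames(out), "good")
    again <- suppressMessages(qcFilter(out))
    expect_identical(colnames(again), "good")
})

test_that("log-normalization follows the scale-factor formula", {
    counts <- matrix(c(1L, 3L, 0L, 0L, 2L, 2L), 3, 2,
                     dimnames = list(paste0("g", 1:3), c("c1", "c2")))
    cc <- CellCounts(counts, c("c1", "c1"), c("normal", "tumor"),
                     c(0.01, 0.01))
    nn <- SummarizedExperiment::assay(logNormalizeCells(cc), "lognorm")
    expect_equal(nn["g1", "c1"], log(1 + 1 / 4 * 1e4), tolerance = 1e-12)
    expect_equal(nn["g1", "c1"], log(2501), tolerance = 1e-12)
    expect_equal(nn["g3", "c1"], 0)
    # proportional count vectors normalize identically
    counts2 <- cbind(c1 = c(2L, 4L, 6L), c2 = c(1L, 2L, 3L))
    rownames(counts2) <- paste0("g", 1:3)
    cc2 <- logNormalizeCells(CellCounts(counts2, c("x", "x"),
                                        c("normal", "tumor"), c(0, 0)))
    nn2 <- SummarizedExperiment::assay(cc2, "lognorm")
    expect_equal(nn2[, 1], nn2[, 2], tolerance = 1e-12)
})

test_that("DE filter semantics: genes below minPct in both groups are not
           tested", {
    set.seed(20)
    counts <- matrix(rnbinom(200 * 40, mu = 5, size = 2), 200, 40,
                     dimnames = list(sprintf("g%03d", 1:200),
                                     sprintf("c%02d", 1:40)))
    # gene g001 detected in ~30% of cells in both groups
    counts["g001", ] <- rbinom(40, 1, 0.3)
    cc <- logNormalizeCells(CellCounts(
        counts, rep("c1", 40), rep(c("normal", "tumor"), each = 20),
        runif(40, 0, 0.1)))
    de <- clusterDE(cc, "c1", minPct = 0.5)
    expect_false("g001" %in% de$gene)
    # identical expression in both groups: large p-value
    null <- de[order(abs(de$log_fc)), ][1, ]
    expect_gt(null$p_value, 0.05)
    expect_true(all(de$adjusted_p >= de$p_value - 1e-12))
})

test_that("clusters missing a condition are skipped with a message", {
    cc <- smallCellCounts()
    SummarizedExperiment::colData(cc)$condition <- rep("tumor", ncol(cc))
    cc <- logNormalizeCells(cc)
    expect_message(de <- clusterDE(cc, "cluster1"), "skipped")
    expect_identical(nrow(de), 0L)
    expect_message(de2 <- clusterDE(cc, "nope"), "not present")
    expect_identical(nrow(de2), 0L)
})

test_that("planted DE genes are recovered and the focal fraction matches
           the construction", {
    focal <- GeneSet("focal", sprintf("gene%05d", sample(500, 60)))
    cfg <- singleCellSimConfig(nCellsPerClusterPerCondition = 60,
                               nClusters = 2, nGenes = 500,
                               deFraction = 0.1, deLogfc = 2,
                               focalOverlap = 0.1, seed = 17)
    cc <- simulateSingleCell(cfg, focal)
    cc <- logNormalizeCells(suppressMessages(qcFilter(cc, minGenes = 100)))
    de <- clusterDEAll(cc)
    gt <- S4Vectors::metadata(cc)$planted_de
    sig <- de[de$adjusted_p < 0.05, ]
    recall <- mean(vapply(names(gt), function(cl)
        mean(gt[[cl]] %in% sig$gene[sig$cluster == cl]), 0))
    expect_gte(recall, 0.8)
    fpr <- mean(vapply(names(gt), function(cl) {
        tested <- de$gene[de$cluster == cl]
        nulls <- setdiff(tested, gt[[cl]])
        mean(nulls %in% sig$gene[sig$cluster == cl])
    }, 0))
    expect_lte(fpr, 0.05)
    ff <- focalFraction(de, focal)
    expect_equal(ff$overall, 0.1, tolerance = 0.05)
})

test_that("zero planted effect keeps downstream recovery at chance", {
    focal <- GeneSet("focal", sprintf("gene%05d", 1:40))
    cfg <- singleCellSimConfig(nCellsPerClusterPerCondition = 40,
                               nClusters = 1, nGenes = 300,
                               deFraction = 0.1, deLogfc = 0, seed = 23)
    cc <- simulateSingleCell(cfg, focal)
    cc <- logNormalizeCells(cc)
    de <- clusterDEAll(cc)
    expect_lte(mean(de$adjusted_p < 0.05), 0.07)
})

test_that("focal fraction identities and relabeling invariance", {
    de <- data.frame(cluster = "c1", gene = paste0("g", 1:10),
                     p_value = 0.001, adjusted_p = 0.001, log_fc = 1,
                     pct_tumor = 1, pct_normal = 1)
    expect_equal(focalFraction(de, GeneSet("all", paste0("g", 1:10)))$overall,
                 1)
    expect_equal(focalFraction(de, GeneSet("none", "zz"))$overall, 0)
    relab <- de; relab$gene <- paste0("x", 1:10)
    expect_equal(
        focalFraction(de, GeneSet("f", paste0("g", 1:3)))$overall,
        focalFraction(relab, GeneSet("f", paste0("x", 1:3)))$overall)
})
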