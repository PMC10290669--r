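# Synthetic-data generators: determinism, degenerate cases, and recovery of
# planted parameters.

test_that("bulk simulation is reproducible and rejects bad configs", {
    cfg <- bulkSimConfig(nGenes = 100, nNormal = 3, nTumor = 3,
                         focalSize = 10, seed = 4)
    s1 <- simulateBulk(cfg); s2 <- simulateBulk(cfg)
    expect_identical(abundance(s1$matrix), abundance(s2$matrix))
    expect_identical(members(s1$focal), members(s2$focal))
    expect_true(all(abundance(s1$matrix) > 0))
    expect_error(bulkSimConfig(nGenes = 10, focalSize = 10), "focalSize")
    expect_error(bulkSimConfig(cvNormal = -1), "cvNormal")
    expect_error(bulkSimConfig(nNormal = 1), "nNormal")
})

test_that("zero-CV bulk samples are identical gene-wise within condition", {
    sim <- simulateBulk(bulkSimConfig(nGenes = 40, nNormal = 3, nTumor = 2,
                                      cvNormal = 0, cvTumor = 0,
                                      focalSize = 5, seed = 1))
    a <- abundance(sim$matrix)
    expect_identical(a[, "N01"], setNames(a[, "N02"], rownames(a)))
    expect_identical(a[, "T01"], setNames(a[, "T02"], rownames(a)))
})

test_that("divergent mode plants the focal tumor/normal fold change", {
    ratios <- vapply(1:20, function(s) {
        sim <- simulateBulk(bulkSimConfig(nGenes = 400, nNormal = 5,
                                          nTumor = 5, focalSize = 40,
                                          focalMode = "divergent",
                                          focalEffect = 4, seed = s))
        a <- abundance(sim$matrix)
        f <- members(sim$focal)
        cond <- condition(sim$matrix)
        mean(rowMeans(a[f, cond == "tumor"]) /
             rowMeans(a[f, cond == "normal"]))
    }, 0)
    expect_equal(mean(ratios), 4, tolerance = 0.05)
})

test_that("network generator produces a simple graph and repairs odd stub
           totals audibly", {
    cfg <- networkSimConfig(nNodes = 200, focalSize = 20, seed = 2)
    sim1 <- suppressMessages(simulateNetwork(cfg))
    sim2 <- suppressMessages(simulateNetwork(cfg))
    g <- interactionGraph(sim1$network)
    expect_true(igraph::is_simple(g))
    expect_false(igraph::is_directed(g))
    expect_identical(igraph::ecount(g),
                     igraph::ecount(interactionGraph(sim2$network)))
    # handshake lemma
    expect_identical(sum(igraph::degree(g)), 2 * igraph::ecount(g))
})

test_that("tiny network respects the simple-graph edge bound", {
    sim <- suppressMessages(simulateNetwork(
        networkSimConfig(nNodes = 3, alpha = 2.5, focalSize = 1,
                         maxDegree = 2, seed = 6)))
    expect_lte(igraph::ecount(interactionGraph(sim$network)), 3)
})

test_that("degree boost separates focal from background degrees", {
    unboosted <- vapply(1:20, function(s) {
        sim <- suppressMessages(simulateNetwork(
            networkSimConfig(nNodes = 400, focalSize = 40,
                             focalDegreeBoost = 1, seed = s)))
        r <- degreeReport(sim$network, sim$focal)
        all <- degreeReport(sim$network)
        r$meanDegree - all$meanDegree
    }, 0)
    # two-sided sign test: no systematic focal excess without boost
    expect_gt(stats::binom.test(sum(unboosted > 0), 20)$p.value, 0.01)
    boosted <- vapply(1:20, function(s) {
        sim <- suppressMessages(simulateNetwork(
            networkSimConfig(nNodes = 400, focalSize = 40,
                             focalDegreeBoost = 3, seed = s)))
        degreeReport(sim$network, sim$focal)$meanDegree >
            degreeReport(sim$network)$meanDegree
    }, TRUE)
    expect_gte(mean(boosted), 0.95)
})

test_that("single-cell generator plants the requested DE structure", {
    focal <- GeneSet("focal", sprintf("gene%05d", 1:40))
    cfg0 <- singleCellSimConfig(nCellsPerClusterPerCondition = 10,
                                nClusters = 2, nGenes = 200,
                                deFraction = 0, seed = 3)
    cc0 <- simulateSingleCell(cfg0, focal)
    expect_true(all(lengths(S4Vectors::metadata(cc0)$planted_de) == 0))
    cfg <- singleCellSimConfig(nCellsPerClusterPerCondition = 10,
                               nClusters = 3, nGenes = 200,
                               deFraction = 0.1, focalOverlap = 0.1,
                               seed = 3)
    cc <- simulateSingleCell(cfg, focal)
    gt <- S4Vectors::metadata(cc)$planted_de
    expect_length(gt, 3L)
    for (cl in names(gt)) {
        expect_length(gt[[cl]], 20L)  # round(0.1 * 200)
        # overlap is exact by construction: round(0.1 * 20) = 2 focal genes
        expect_identical(sum(gt[[cl]] %in% members(focal)), 2L)
    }
    cts <- SummarizedExperiment::assay(cc, "counts")
    expect_true(all(cts >= 0) && all(cts == round(cts)))
    mf <- SummarizedExperiment::colData(cc)$mito_fraction
    expect_true(all(mf >= 0.01 & mf <= 0.10))
})

test_that("impossible focal overlap is rejected", {
    focal <- GeneSet("focal", sprintf("gene%05d", 1:2))
    cfg <- singleCellSimConfig(nCellsPerClusterPerCondition = 10,
                               nGenes = 100, deFraction = 0.5,
                               focalOverlap = 0.5, seed = 1)
    expect_error(simulateSingleCell(cfg, focal), "impossible overlap")
})

test_that("single-cell generation is seed-reproducible", {
    focal <- GeneSet("focal", sprintf("gene%05d", 1:10))
    cfg <- singleCellSimConfig(nCellsPerClusterPerCondition = 5,
                               nClusters = 2, nGenes = 60, seed = 11)
    c1 <- simulateSingleCell(cfg, focal)
    c2 <- simulateSingleCell(cfg, focal)
    expect_identical(SummarizedExperiment::assay(c1, "counts"),
                     SummarizedExperiment::assay(c2, "counts"))
    expect_identical(S4Vectors::metadata(c1)$planted_de,
                     S4Vectors::metadata(c2)$planted_de)
})
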