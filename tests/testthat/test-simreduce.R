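# PCA embedding, condition distances, neighbor joining and separation
# scoring.

test_that("PCA agrees with a brute-force eigendecomposition up to sign", {
    set.seed(6)
    v <- matrix(rlnorm(20), 5, 4,
                dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:4)))
    em <- ExpressionMatrix(v, c("normal", "normal", "tumor", "tumor"))
    e <- pcaEmbed(em, logTransform = FALSE)
    x <- scale(t(v), center = TRUE, scale = FALSE)
    eig <- eigen(cov(x))
    scores <- x %*% eig$vectors[, 1:2]
    for (j in 1:2)
        expect_lt(min(max(abs(e$coordinates[, j] - scores[, j])),
                      max(abs(e$coordinates[, j] + scores[, j]))), 1e-8)
    ev <- eig$values / sum(eig$values)
    expect_equal(e$explainedVariance, ev[1:2], tolerance = 1e-8)
})

test_that("PCA degenerate cases: duplicated samples and rank-1 data", {
    v <- matrix(c(1, 2, 3, 1, 2, 3, 5, 6, 7), 3, 3,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
    em <- ExpressionMatrix(v, c("normal", "normal", "tumor"))
    e <- pcaEmbed(em, logTransform = FALSE)
    expect_equal(e$coordinates[1, ], e$coordinates[2, ], tolerance = 1e-10)
    # samples on a line in gene space
    line <- outer(c(1, 2, 3), c(0, 1, 2)) + 1
    dimnames(line) <- dimnames(v)
    el <- pcaEmbed(ExpressionMatrix(line, c("normal", "normal", "tumor")),
                   logTransform = FALSE)
    expect_equal(el$explainedVariance, c(1, 0), tolerance = 1e-10)
})

test_that("conditionDistance matches geometry and a brute-force loop", {
    emb <- structure(list(
        sampleIds = paste0("s", 1:4),
        coordinates = rbind(c(0, 0), c(0, 0), c(3, 4), c(3, 4)),
        explainedVariance = c(0.8, 0.2),
        condition = c("normal", "normal", "tumor", "tumor")),
        class = "SampleEmbedding")
    expect_equal(conditionDistance(emb), 5)
    set.seed(8)
    emb$coordinates <- matrix(rnorm(8), 4, 2)
    brute <- mean(vapply(1:2, function(i)
        vapply(3:4, function(j)
            sqrt(sum((emb$coordinates[i, ] - emb$coordinates[j, ])^2)), 0),
        numeric(2)))
    expect_equal(conditionDistance(emb), brute, tolerance = 1e-12)
    zero <- emb; zero$coordinates[] <- 0
    expect_equal(conditionDistance(zero), 0)
})

test_that("full-space condition distance matches a brute-force loop", {
    em <- tinyExpression(nNormal = 3L, nTumor = 3L)
    a <- log2(abundance(em) + 1)
    brute <- mean(vapply(1:3, function(i)
        vapply(4:6, function(j) sqrt(sum((a[, i] - a[, j])^2)), 0),
        numeric(3)))
    expect_equal(conditionDistanceFull(em), brute, tolerance = 1e-12)
})

test_that("NJ reconstructs the additive 4-taxon tree exactly", {
    m <- additiveFourTaxon()
    tr <- njTree(m)
    d <- treeLeafDistances(tr)
    expect_equal(d[rownames(m), colnames(m)], m, tolerance = 1e-9)
    # topology AB|CD: the path A-B avoids the path C-D's internal node
    expect_equal(d["A", "B"], 3, tolerance = 1e-9)
    expect_equal(sum(tr$edge.length), 11, tolerance = 1e-9)  # 1+2+3+4+1
    expect_identical(ape::Ntip(tr), 4L)
    expect_true(ape::is.binary(tr))
})

test_that("NJ is invariant to leaf-order permutations", {
    m <- additiveFourTaxon()
    base <- treeLeafDistances(njTree(m))
    set.seed(10)
    for (i in 1:10) {
        p <- sample(4)
        d <- treeLeafDistances(njTree(m[p, p]))
        expect_equal(d[rownames(base), colnames(base)], base,
                     tolerance = 1e-9)
    }
})

test_that("NJ solves the 3-leaf closed form and validates inputs", {
    m <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    tr <- njTree(m)
    # three-point formulas: la = (ab + ac - bc)/2 etc.
    d <- treeLeafDistances(tr)
    expect_equal(d[rownames(m), colnames(m)], m, tolerance = 1e-9)
    bad <- m; bad[1, 2] <- 99
    expect_error(njTree(bad), "symmetric")
    neg <- m; neg[1, 2] <- neg[2, 1] <- -1
    expect_error(njTree(neg), "non-negative")
})

test_that("total branch length grows with nested feature sets", {
    sim <- simulateBulk(bulkSimConfig(nGenes = 200, nNormal = 4,
                                      nTumor = 4, focalSize = 50, seed = 5))
    whole <- njTree(sampleDistanceMatrix(sim$matrix))
    sub <- njTree(sampleDistanceMatrix(sim$matrix, sim$focal))
    expect_lte(sum(sub$edge.length), sum(whole$edge.length))
})

test_that("separation score is 1 for clean splits, NA when degenerate,
           and centered for random labels", {
    cut2 <- c(a = 1, b = 1, c = 2, d = 2)
    cond <- c(a = "normal", b = "normal", c = "tumor", d = "tumor")
    expect_equal(separationScore(cut2, cond), 1)
    expect_warning(s <- separationScore(cut2, rep("tumor", 4)),
                   "one condition")
    expect_true(is.na(s))
    set.seed(12)
    scores <- replicate(200, {
        separationScore(sample(1:2, 8, TRUE),
                        sample(c("normal", "tumor"), 8, TRUE)) })
    expect_lt(abs(mean(scores, na.rm = TRUE)), 0.05)
})

test_that("hierarchical clustering separates well-separated conditions", {
    sim <- simulateBulk(bulkSimConfig(nGenes = 100, nNormal = 4, nTumor = 4,
                                      focalSize = 10,
                                      focalMode = "divergent",
                                      focalEffect = 1, seed = 2))
    # make every tumor sample globally shifted so the split is clean
    a <- abundance(sim$matrix)
    a[, condition(sim$matrix) == "tumor"] <-
        a[, condition(sim$matrix) == "tumor"] * 8
    em <- ExpressionMatrix(a, condition(sim$matrix))
    hc <- hierarchicalCluster(sampleDistanceMatrix(em))
    expect_true(all(diff(hc$height) >= -1e-9))  # monotone merges
    expect_equal(separationScore(hc, condition(em)), 1)
    tr <- njTree(sampleDistanceMatrix(em))
    expect_equal(separationScore(tr, condition(em)), 1)
})
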