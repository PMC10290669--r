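# Pairwise sample statistics: correlations, Doane binning, mutual
# information, and expression noise, checked against hand-derived values
# and brute-force oracles.

test_that("Pearson and Spearman reproduce hand-derived values", {
    expect_equal(pearsonR(c(1, 2, 3), c(1, 2, 3)), 1)
    expect_equal(pearsonR(c(1, 2, 3), c(3, 2, 1)), -1)
    expect_equal(pearsonR(c(1, 2, 3), c(1, 3, 2)), 0.5, tolerance = 1e-9)
    expect_equal(spearmanRho(c(1, 2, 3), c(1, 3, 2)), 0.5, tolerance = 1e-9)
    expect_equal(spearmanRho(1:5, 1:5), 1)
    # rank invariance under strictly monotone transforms
    x <- rlnorm(20)
    expect_equal(spearmanRho(exp(x), x), 1)
    expect_warning(p <- pearsonR(rep(2, 5), 1:5), "constant")
    expect_true(is.na(p))
})

test_that("Pearson matches a brute-force evaluation of the definition", {
    set.seed(11)
    for (i in 1:5) {
        x <- rlnorm(30); y <- rlnorm(30)
        brute <- sum((x - mean(x)) * (y - mean(y))) /
            (sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2)))
        expect_equal(pearsonR(x, y), brute, tolerance = 1e-12)
    }
})

test_that("Doane's rule gives the derived bin counts and is monotone in skew", {
    expect_identical(doaneBins(1:8), 4L)       # symmetric: 1 + log2(8)
    expect_identical(doaneBins(c(1, 2, 3, 4)), 3L)  # ceil(1 + 2)
    set.seed(3)
    sym <- rnorm(64)
    skewed <- exp(sym * 2)
    expect_gte(doaneBins(skewed), doaneBins(sort(sym) + rev(sort(sym))))
    # skewness correction never reduces the count below Sturges on the
    # same n
    expect_gte(doaneBins(skewed), doaneBins(seq_len(64)))
})

test_that("mutual information has the closed-form values on known joints", {
    expect_equal(miFromJoint(matrix(25, 2, 2)), 0)
    expect_equal(miFromJoint(matrix(c(50, 0, 0, 50), 2, 2)), log(2),
                 tolerance = 1e-12)
    # perfectly dependent ranks give MI = the bin-marginal entropy
    # (equal-count bins are only approximately uniform when k does not
    # divide n, so compare against the entropy computed from the realized
    # bin sizes)
    x <- 1:64; k <- doaneBins(rank(x))
    p <- as.vector(table(ceiling(k * rank(x) / length(x)))) / length(x)
    expect_equal(mutualInformation(x, x), -sum(p * log(p)),
                 tolerance = 1e-9)
    expect_gte(mutualInformation(rnorm(100), rnorm(100)), 0)
})

test_that("plugin MI bias on independent data matches the chi-square
           approximation and shrinks with n", {
    # For independent vectors binned into k x k equal-count cells, the
    # plugin MI is approximately chi2_{(k-1)^2} / (2n), mean (k-1)^2/(2n).
    set.seed(21)
    n <- 1000L; k <- doaneBins(rank(runif(n)))
    mi <- replicate(20, mutualInformation(runif(n), runif(n)))
    theory <- (k - 1)^2 / (2 * n)
    se <- sqrt(2 * (k - 1)^2) / (2 * n) / sqrt(20)
    expect_lt(mean(mi), theory + 4 * se)
    expect_gt(mean(mi), theory - 4 * se)
    mi4k <- replicate(5, mutualInformation(runif(4000), runif(4000)))
    expect_lt(mean(mi4k), mean(mi))  # bias decays with n
})

test_that("MI is invariant under strictly monotone per-sample transforms", {
    set.seed(9)
    x <- rlnorm(200); y <- x + rnorm(200)
    expect_equal(mutualInformation(x, y),
                 mutualInformation(log(x), exp(y / 10)), tolerance = 1e-12)
})

test_that("gene noise is the squared CV with population variance", {
    expect_equal(geneNoise(5, 5), 0)
    expect_equal(geneNoise(1, 3), 0.25)   # sigma2_pop = 1, mu2 = 4
    expect_equal(geneNoise(2, 6), 0.25)   # scale invariance
    expect_true(is.na(geneNoise(0, 0)))
})

test_that("total noise equals a brute-force per-gene loop", {
    set.seed(5)
    x <- rlnorm(50); y <- rlnorm(50)
    brute <- mean(vapply(1:50, function(i) {
        v <- c(x[i], y[i])
        mean((v - mean(v))^2) / mean(v)^2
    }, 0))
    expect_equal(as.numeric(totalNoise(x, y)), brute, tolerance = 1e-12)
    expect_equal(as.numeric(totalNoise(x, x)), 0)
    # two genes with eta2 = 0.25 and 0 average to 0.125
    expect_equal(as.numeric(totalNoise(c(1, 2), c(3, 2))), 0.125)
})

test_that("eta2 is invariant to global rescaling of the matrix", {
    em <- tinyExpression()
    em2 <- ExpressionMatrix(abundance(em) * 37.5, condition(em))
    r1 <- pairStatReport(em); r2 <- pairStatReport(em2)
    expect_equal(r1$eta2, r2$eta2, tolerance = 1e-12)
    expect_equal(r1$rho, r2$rho)
    expect_equal(r1$mi, r2$mi)
})

test_that("aggregatePairs counts sample pairs by combinatorics", {
    em <- tinyExpression(nNormal = 3L, nTumor = 4L)
    expect_identical(aggregatePairs(em, group = "NvsN")$n_pairs, 3L)
    expect_identical(aggregatePairs(em, group = "TvsT")$n_pairs, 6L)
    expect_identical(aggregatePairs(em, group = "NvsT")$n_pairs, 12L)
    em2 <- tinyExpression(nNormal = 2L, nTumor = 2L)
    expect_identical(aggregatePairs(em2, group = "NvsN")$n_pairs, 1L)
})

test_that("subset = all genes equals passing no subset", {
    em <- tinyExpression()
    whole <- pairStatReport(em)
    asSet <- pairStatReport(em, GeneSet("all", rownames(em)))
    expect_equal(whole[, c("r", "rho", "mi", "eta2")],
                 asSet[, c("r", "rho", "mi", "eta2")])
})

test_that("aggregated means agree with a per-pair loop oracle", {
    em <- tinyExpression(nNormal = 3L, nTumor = 3L)
    a <- abundance(em)
    rep <- aggregatePairs(em, group = "NvsT")
    ni <- 1:3; ti <- 4:6
    loopR <- mean(vapply(ni, function(i)
        vapply(ti, function(j) cor(a[, i], a[, j]), 0), numeric(3)))
    loopEta <- mean(vapply(ni, function(i)
        vapply(ti, function(j) as.numeric(totalNoise(a[, i], a[, j])), 0),
        numeric(3)))
    expect_equal(rep$r, loopR, tolerance = 1e-12)
    expect_equal(rep$eta2, loopEta, tolerance = 1e-12)
})

test_that("zero-noise generator gives r = rho = 1 and eta2 = 0 within
           conditions", {
    sim <- simulateBulk(bulkSimConfig(nGenes = 50, nNormal = 3, nTumor = 3,
                                      cvNormal = 0, cvTumor = 0,
                                      focalSize = 5, seed = 8))
    nn <- aggregatePairs(sim$matrix, group = "NvsN",
                         statistics = c("r", "rho", "eta2"))
    expect_equal(nn$r, 1)
    expect_equal(nn$rho, 1)
    expect_equal(nn$eta2, 0)
})
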