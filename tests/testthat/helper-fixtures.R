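# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

tinyExpression <- function(values = NULL, nNormal = 2L, nTumor = 2L) {
    if (is.null(values)) {
        set.seed(42)
        values <- matrix(rlnorm(20 * (nNormal + nTumor), 1, 1),
                         20, nNormal + nTumor)
    }
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
    colnames(values) <- c(sprintf("N%d", seq_len(nNormal)),
                          sprintf("T%d", seq_len(nTumor)))
    ExpressionMatrix(values, rep(c("normal", "tumor"), c(nNormal, nTumor)))
}

# unrooted 4-taxon tree with leaf edges A:1 B:2 C:3 D:4 and internal edge 1
additiveFourTaxon <- function() {
    m <- matrix(c(0, 3, 5, 6,
                  3, 0, 6, 7,
                  5, 6, 0, 7,
                  6, 7, 7, 0), 4, 4, byrow = TRUE,
                dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    m
}

starGraph <- function() {
    InteractionNetwork(cbind("hub", paste0("leaf", 1:5)))
}

smallCellCounts <- function(nGenes = 50L, nCells = 12L, seed = 7L) {
    set.seed(seed)
    counts <- matrix(rnbinom(nGenes * nCells, mu = 5, size = 2),
                     nGenes, nCells,
                     dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                     sprintf("c%03d", seq_len(nCells))))
    CellCounts(counts,
               cluster = rep("cluster1", nCells),
               condition = rep(c("normal", "tumor"), each = nCells / 2),
               mitoFraction = runif(nCells, 0.01, 0.1))
}
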