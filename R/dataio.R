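## Readers and writers for every external format the pipeline touches:
## TSV/CSV expression matrices with a condition sidecar, GMT gene sets,
## two-column edge lists, Newick trees, MTX + metadata for cell counts,
## JSON reports. All strictly validated; parse failures name the offender.

delimFor <- function(path) if (grepl("\\.csv$", path, TRUE)) "," else "\t"

#' Read a genes-by-samples expression matrix with condition labels
#'
#' @param path TSV (or \code{.csv}) file: header row of sample IDs, first
#'   column of gene IDs. Missing values may be empty fields or \code{NA}.
#' @param conditionPath two-column TSV/CSV (header \code{sample},
#'   \code{condition}) mapping every sample to \code{normal}/\code{tumor}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readExpression <- function(path, conditionPath) {
    df <- read.delim(path, sep = delimFor(path), check.names = FALSE,
                     na.strings = c("NA", ""))
    if (ncol(df) < 2L)
        stop("malformed header in '", path,
             "': need a gene column plus at least one sample column")
    genes <- as.character(df[[1L]])
    if (anyDuplicated(genes))
        stop("duplicate gene identifier in '", path, "': ",
             genes[duplicated(genes)][1L])
    values <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(values) <- "double"
    rownames(values) <- genes
    cond <- read.delim(conditionPath, sep = delimFor(conditionPath),
                       check.names = FALSE)
    if (!all(c("sample", "condition") %in% colnames(cond)))
        stop("condition file '", conditionPath,
             "' must have columns 'sample' and 'condition'")
    missing <- setdiff(colnames(values), cond$sample)
    if (length(missing))
        stop("sample missing from condition file: ", missing[1L])
    lab <- setNames(as.character(cond$condition), cond$sample)
    ExpressionMatrix(values, lab[colnames(values)])
}

#' Write an ExpressionMatrix plus its condition sidecar
#'
#' @param em an \linkS4class{ExpressionMatrix}.
#' @param path output matrix TSV path.
#' @param conditionPath output sample-to-condition TSV path.
#' @return invisibly, the matrix path.
#' @export
writeExpression <- function(em, path, conditionPath) {
    df <- data.frame(gene = rownames(em),
                     abundance(em), check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample = colnames(em),
                           condition = condition(em)),
                conditionPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Drop genes with any missing value
#'
#' Proteomic matrices may carry missing abundances; no imputation is done —
#' genes with one or more missing entries are removed outright, the count
#' reported by message.
#'
#' @param em an \linkS4class{ExpressionMatrix}.
#' @return The restricted \linkS4class{ExpressionMatrix}; a warning is
#'   emitted if nothing survives.
#' @export
dropMissingGenes <- function(em) {
    a <- abundance(em)
    keep <- rowSums(is.na(a)) == 0L
    message("dropMissingGenes: removed ", sum(!keep), " of ", nrow(a),
            " gene(s) with missing values")
    if (!any(keep))
        warning("all genes contained missing values; empty matrix returned")
    em[keep, ]
}

#' Read gene sets from a GMT file
#'
#' Each GMT line is \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param path GMT file path.
#' @return Named list of \linkS4class{GeneSet} objects.
#' @export
readGeneSets <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(seq_along(lines), function(i) {
        parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(parts) < 3L)
            stop("parse failure in '", path, "' at line ", i,
                 ": need name, description and at least one gene")
        GeneSet(parts[1L], parts[-(1:2)])
    })
    setNames(sets, vapply(sets, setName, ""))
}

#' Read a gene set from a one-identifier-per-line file
#'
#' @param path text file, one gene ID per line (blank lines ignored).
#' @param name label for the set (default: the file's base name).
#' @return A \linkS4class{GeneSet}.
#' @export
readGeneList <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
    ids <- trimws(readLines(path))
    GeneSet(name, ids[nzchar(ids)])
}

#' Write gene sets as GMT
#'
#' @param sets a \linkS4class{GeneSet} or list of them.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGeneSets <- function(sets, path) {
    if (is(sets, "GeneSet")) sets <- list(sets)
    lines <- vapply(sets, function(s)
        paste(c(setName(s), "na", members(s)), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Read an undirected edge list
#'
#' Two whitespace/tab-separated columns of gene IDs per line. Unordered
#' duplicates and self-loops are removed (a message reports how many), so
#' permuting input lines yields the same edge set.
#'
#' @param path edge-list TSV path.
#' @param header logical; does the first line carry column names
#'   (default FALSE)?
#' @return An \linkS4class{InteractionNetwork}.
#' @export
readEdgeList <- function(path, header = FALSE) {
    df <- read.delim(path, header = header, sep = "",
                     colClasses = "character")
    if (ncol(df) < 2L)
        stop("parse failure in '", path, "': need two columns per line")
    InteractionNetwork(df[, 1:2])
}

#' Write an InteractionNetwork as a two-column TSV edge list
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeEdgeList <- function(net, path) {
    el <- igraph::as_edgelist(interactionGraph(net))
    write.table(el, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write / read a sample tree in Newick format
#'
#' Thin wrappers over \pkg{ape} with configurable branch-length precision.
#'
#' @param tree an \pkg{ape} \code{phylo} object.
#' @param path Newick file path.
#' @param digits branch-length precision (default 10).
#' @return \code{writeNewick}: invisibly, \code{path}; \code{readNewick}:
#'   a \code{phylo}.
#' @export
writeNewick <- function(tree, path, digits = 10) {
    ape::write.tree(tree, file = path, digits = digits)
    invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) ape::read.tree(path)

#' Write a CellCounts object as MTX plus metadata TSVs
#'
#' Produces \code{counts.mtx}, \code{genes.tsv}, \code{cells.tsv} (columns
#' \code{cell}, \code{cluster}, \code{condition}, \code{mito_fraction}) and,
#' when planted ground truth is present, \code{ground_truth.json}.
#'
#' @param cc a \linkS4class{CellCounts}.
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
writeCellCounts <- function(cc, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- SummarizedExperiment::assay(cc, "counts")
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"),
                    file.path(dir, "counts.mtx"))
    writeLines(rownames(cc), file.path(dir, "genes.tsv"))
    cd <- SummarizedExperiment::colData(cc)
    write.table(data.frame(cell = colnames(cc),
                           cluster = cd$cluster,
                           condition = cd$condition,
                           mito_fraction = cd$mito_fraction),
                file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    gt <- S4Vectors::metadata(cc)$planted_de
    if (length(gt))
        jsonlite::write_json(gt, file.path(dir, "ground_truth.json"))
    invisible(dir)
}

#' Read a CellCounts object written by [writeCellCounts()]
#'
#' @param dir directory containing \code{counts.mtx}, \code{genes.tsv},
#'   \code{cells.tsv} and optionally \code{ground_truth.json}.
#' @return A \linkS4class{CellCounts}.
#' @export
readCellCounts <- function(dir) {
    m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
    genes <- readLines(file.path(dir, "genes.tsv"))
    cells <- read.delim(file.path(dir, "cells.tsv"))
    if (nrow(m) != length(genes))
        stop("genes.tsv lists ", length(genes), " genes but counts.mtx has ",
             nrow(m), " rows")
    if (ncol(m) != nrow(cells))
        stop("cells.tsv lists ", nrow(cells), " cells but counts.mtx has ",
             ncol(m), " columns")
    dimnames(m) <- list(genes, cells$cell)
    gtPath <- file.path(dir, "ground_truth.json")
    gt <- if (file.exists(gtPath))
        lapply(jsonlite::read_json(gtPath), unlist) else list()
    CellCounts(m, cells$cluster, cells$condition, cells$mito_fraction,
               plantedDE = gt)
}
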