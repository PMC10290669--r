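#' Accessors for package classes
#'
#' Small accessor generics: \code{condition()} returns per-sample (or
#' per-cell) condition labels; \code{abundance()} the expression matrix;
#' \code{members()} and \code{setName()} the contents of a
#' \linkS4class{GeneSet}; \code{interactionGraph()} the underlying
#' \pkg{igraph} graph; \code{nullValues()}, \code{focalValue()} and
#' \code{percentile()} the parts of a \linkS4class{ResamplingNull}.
#'
#' @param x an object of the documented class.
#' @return The slot value (see Details of each class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname accessors
#' @export
setMethod("condition", "SummarizedExperiment", function(x)
    setNames(as.character(SummarizedExperiment::colData(x)$condition),
             colnames(x)))

#' @rdname accessors
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @rdname accessors
#' @export
setMethod("abundance", "ExpressionMatrix", function(x)
    SummarizedExperiment::assay(x, "abundance"))

#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname accessors
#' @export
setMethod("members", "GeneSet", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))

#' @rdname accessors
#' @export
setMethod("setName", "GeneSet", function(x) x@name)

#' @rdname accessors
#' @export
setGeneric("interactionGraph", function(x) standardGeneric("interactionGraph"))

#' @rdname accessors
#' @export
setMethod("interactionGraph", "InteractionNetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setGeneric("nullValues", function(x) standardGeneric("nullValues"))

#' @rdname accessors
#' @export
setMethod("nullValues", "ResamplingNull", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("focalValue", function(x) standardGeneric("focalValue"))

#' @rdname accessors
#' @export
setMethod("focalValue", "ResamplingNull", function(x) x@focalValue)

#' @rdname accessors
#' @export
setGeneric("percentile", function(x) standardGeneric("percentile"))

#' @rdname accessors
#' @export
setMethod("percentile", "ResamplingNull", function(x) x@percentile)

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet '", object@name, "' with ", length(object@members),
        " gene(s)\n", sep = "")
    cat("  ", paste(head(object@members, 6L), collapse = ", "),
        if (length(object@members) > 6L) ", ..." else "", "\n", sep = "")
})

setMethod("show", "InteractionNetwork", function(object) {
    g <- object@graph
    cat("InteractionNetwork: ", igraph::vcount(g), " genes, ",
        igraph::ecount(g), " interactions\n", sep = "")
})

setMethod("show", "ResamplingNull", function(object) {
    cat("ResamplingNull of '", object@statisticName, "' (set size ",
        object@setSize, ", ", object@nReps, " replicates)\n", sep = "")
    cat("  focal value: ", format(object@focalValue, digits = 6),
        "; null mean: ", format(mean(object@values), digits = 6),
        "; percentile: ", format(object@percentile, digits = 4), "\n",
        sep = "")
})

setMethod("show", "DistributionFit", function(object) {
    cat("DistributionFit [", object@family, "], n = ", object@n,
        ", loglik = ", format(object@loglik, digits = 7),
        ", AIC = ", format(object@aic, digits = 7), "\n", sep = "")
    cat("  params: ",
        paste(names(object@params), format(object@params, digits = 5),
              sep = " = ", collapse = ", "), "\n", sep = "")
})

setMethod("show", "PowerLawFit", function(object) {
    cat("PowerLawFit: alpha = ", format(object@alpha, digits = 5),
        ", xmin = ", object@xmin, ", tail n = ", object@nTail, "\n", sep = "")
})
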