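## Size-matched random-gene-set resampling null. "Invariance" of a focal
## set is the testable statement that its statistic is typical of the
## distribution obtained from repeated uniform size-matched draws.

#' Draw a uniform random gene set from a universe
#'
#' The universe is sorted before drawing so the draw depends only on the
#' RNG state and the universe's contents, never on its input order.
#'
#' @param universe character vector of gene IDs.
#' @param size draw size (<= length of universe).
#' @param name label for the returned set (default "random").
#' @return A \linkS4class{GeneSet}.
#' @export
drawRandomSet <- function(universe, size, name = "random") {
    universe <- sort(unique(as.character(universe)))
    stopifnot(size <= length(universe))
    GeneSet(name, sample(universe, size))
}

midrankPercentile <- function(values, focal) {
    (sum(values < focal) + 0.5 * sum(values == focal)) / length(values)
}

#' Build a resampling null for an arbitrary set statistic
#'
#' Evaluates \code{statFun} on the focal members and on \code{nReps}
#' independent size-matched uniform draws from the universe, and locates the
#' focal value by its mid-rank percentile
#' \eqn{(\#\{null < focal\} + 0.5\,\#\{null = focal\}) / n_{reps}}.
#' Focal genes are not excluded from the universe (set
#' \code{excludeFocal = TRUE} for the variant).
#'
#' @param universe character vector of gene IDs to draw from.
#' @param focal a \linkS4class{GeneSet} or character vector; members absent
#'   from the universe are dropped with a message, and the draws match the
#'   intersection size.
#' @param statFun function(character gene IDs) -> single numeric.
#' @param statisticName label stored in the result.
#' @param nReps number of random draws (default 100).
#' @param seed RNG seed for the draws.
#' @param excludeFocal drop focal genes from the sampling universe
#'   (default FALSE).
#' @return A \linkS4class{ResamplingNull}.
#' @examples
#' un <- sprintf("g%03d", 1:50)
#' vals <- setNames(seq_along(un), un)
#' rn <- resamplingNull(un, un[1:5], function(ids) mean(vals[ids]),
#'                      "mean value", nReps = 50, seed = 1)
#' percentile(rn)
#' @export
resamplingNull <- function(universe, focal, statFun,
                           statisticName = "statistic", nReps = 100L,
                           seed = 1L, excludeFocal = FALSE) {
    universe <- sort(unique(as.character(universe)))
    focalIds <- if (is(focal, "GeneSet")) members(focal)
                else as.character(focal)
    inUniverse <- intersect(focalIds, universe)
    dropped <- length(focalIds) - length(inUniverse)
    if (dropped)
        message("resamplingNull: dropped ", dropped,
                " focal gene(s) absent from the universe")
    size <- length(inUniverse)
    if (size < 3L)
        stop("focal set too small after intersection (", size,
             " < 3): statistics are unstable")
    pool <- if (excludeFocal) setdiff(universe, inUniverse) else universe
    focalValue <- statFun(inUniverse)
    values <- withr::with_seed(seed,
        vapply(seq_len(nReps), function(i) statFun(sample(pool, size)), 0))
    new("ResamplingNull", statisticName = statisticName,
        setSize = as.integer(size), nReps = as.integer(nReps),
        values = values, focalValue = as.numeric(focalValue),
        percentile = midrankPercentile(values, focalValue),
        seed = as.integer(seed))
}

#' Resampling null for a bulk pair statistic or mean expression
#'
#' Convenience wrapper around [resamplingNull()] with the statistic drawn
#' from [aggregatePairs()] (\code{"r"}, \code{"rho"}, \code{"mi"},
#' \code{"eta2"} on a sample-pair group) or \code{"mean"} (mean expression
#' of the set over all samples). The universe is the matrix's gene set
#' (apply [filterLowExpression()] upstream to compare against expressed
#' genes).
#'
#' @param em an \linkS4class{ExpressionMatrix}.
#' @param focal a \linkS4class{GeneSet}.
#' @param statistic one of \code{"r"}, \code{"rho"}, \code{"mi"},
#'   \code{"eta2"}, \code{"mean"}.
#' @param group sample-pair group for the pair statistics (ignored for
#'   \code{"mean"}).
#' @param nReps,seed,excludeFocal passed to [resamplingNull()].
#' @param logTransform passed to [aggregatePairs()].
#' @return A \linkS4class{ResamplingNull} named
#'   \code{"<statistic>:<group>"}.
#' @export
buildNull <- function(em, focal,
                      statistic = c("r", "rho", "mi", "eta2", "mean"),
                      group = c("NvsT", "NvsN", "TvsT"), nReps = 100L,
                      seed = 1L, excludeFocal = FALSE,
                      logTransform = FALSE) {
    statistic <- match.arg(statistic)
    group <- match.arg(group)
    a <- abundance(em)
    statFun <- if (statistic == "mean") {
        function(ids) mean(a[ids, ])
    } else {
        function(ids)
            aggregatePairs(em, ids, group, statistic,
                           logTransform)[[statistic]]
    }
    name <- if (statistic == "mean") "mean"
            else paste0(statistic, ":", group)
    resamplingNull(rownames(em), focal, statFun, name, nReps, seed,
                   excludeFocal)
}
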