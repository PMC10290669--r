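## Candidate abundance distributions and AIC model selection. Burr means the
## Burr type-XII (three-parameter) family; loglogistic is its two-parameter
## special case (shape1 = 1); Pareto means Pareto type I with the threshold
## profiled at the sample minimum. Density/distribution/quantile functions
## for these families are defined here.

#' Loglogistic, Burr XII and Pareto I distribution functions
#'
#' \code{dllogis}/\code{pllogis}/\code{qllogis}: loglogistic with
#' \code{shape} c and \code{scale} s, density
#' \eqn{(c/s)(x/s)^{c-1} / (1+(x/s)^c)^2}.
#' \code{dburr}/\code{pburr}/\code{qburr}: Burr XII with \code{shape1} k,
#' \code{shape2} c and \code{scale} s, density
#' \eqn{(kc/s)(x/s)^{c-1} / (1+(x/s)^c)^{k+1}}; \code{shape1 = 1} recovers
#' the loglogistic.
#' \code{dpareto1}/\code{ppareto1}/\code{qpareto1}: Pareto type I with
#' \code{shape} \eqn{\alpha} and threshold \code{min}, density
#' \eqn{\alpha\,min^\alpha / x^{\alpha+1}} for \eqn{x \ge min}.
#'
#' @param x,q quantiles. @param p probabilities. @param shape,shape1,shape2
#'   shape parameters. @param scale scale parameter. @param min Pareto
#'   threshold. @param log,lower.tail as in standard distribution functions.
#' @return numeric vector of densities, probabilities or quantiles.
#' @name abundance-distributions
NULL

#' @rdname abundance-distributions
#' @export
dllogis <- function(x, shape, scale, log = FALSE)
    dburr(x, 1, shape, scale, log = log)

#' @rdname abundance-distributions
#' @export
pllogis <- function(q, shape, scale, lower.tail = TRUE)
    pburr(q, 1, shape, scale, lower.tail = lower.tail)

#' @rdname abundance-distributions
#' @export
qllogis <- function(p, shape, scale) scale * (p / (1 - p))^(1 / shape)

#' @rdname abundance-distributions
#' @export
dburr <- function(x, shape1, shape2, scale, log = FALSE) {
    ld <- rep(-Inf, length(x))
    ok <- x > 0
    z <- x[ok] / scale
    ld[ok] <- log(shape1) + log(shape2) - log(scale) +
        (shape2 - 1) * log(z) - (shape1 + 1) * log1p(z^shape2)
    if (log) ld else exp(ld)
}

#' @rdname abundance-distributions
#' @export
pburr <- function(q, shape1, shape2, scale, lower.tail = TRUE) {
    p <- ifelse(q <= 0, 0, 1 - (1 + (pmax(q, 0) / scale)^shape2)^(-shape1))
    if (lower.tail) p else 1 - p
}

#' @rdname abundance-distributions
#' @export
qburr <- function(p, shape1, shape2, scale)
    scale * ((1 - p)^(-1 / shape1) - 1)^(1 / shape2)

#' @rdname abundance-distributions
#' @export
dpareto1 <- function(x, shape, min, log = FALSE) {
    ld <- ifelse(x >= min,
                 log(shape) + shape * log(min) - (shape + 1) * log(x),
                 -Inf)
    if (log) ld else exp(ld)
}

#' @rdname abundance-distributions
#' @export
ppareto1 <- function(q, shape, min, lower.tail = TRUE) {
    p <- ifelse(q < min, 0, 1 - (min / q)^shape)
    if (lower.tail) p else 1 - p
}

#' @rdname abundance-distributions
#' @export
qpareto1 <- function(p, shape, min) min * (1 - p)^(-1 / shape)

distFamilies <- c("log-normal", "loglogistic", "weibull", "pareto", "burr")

## ML fits for the custom families, by direct optimization on log-parameters
## (unconstrained, smooth). Loglogistic starts from a quantile-matching
## guess; Burr starts at the fitted loglogistic (its shape1 = 1 submodel) so
## the three-parameter likelihood never falls below the nested one.
fitLlogis <- function(x) {
    qs <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    shape0 <- 2 * log(3) / max(log(qs[3]) - log(qs[1]), 1e-6)
    nll <- function(p) -sum(dllogis(x, exp(p[1]), exp(p[2]), log = TRUE))
    o <- optim(log(c(shape0, qs[2])), nll, method = "BFGS")
    list(params = c(shape = exp(o$par[1]), scale = exp(o$par[2])),
         loglik = -o$value)
}

fitBurr <- function(x) {
    ll <- fitLlogis(x)
    nll <- function(p)
        -sum(dburr(x, exp(p[1]), exp(p[2]), exp(p[3]), log = TRUE))
    o <- optim(c(0, log(ll$params["shape"]), log(ll$params["scale"])),
               nll, method = "BFGS")
    ## never report a worse likelihood than the nested loglogistic start
    if (-o$value < ll$loglik - 1e-8)
        o <- list(par = c(0, log(ll$params[c("shape", "scale")])),
                  value = -ll$loglik)
    list(params = c(shape1 = unname(exp(o$par[1])),
                    shape2 = unname(exp(o$par[2])),
                    scale = unname(exp(o$par[3]))),
         loglik = -o$value)
}

fitOneFamily <- function(x, family) {
    n <- length(x)
    fit <- switch(family,
        "log-normal" = {
            f <- fitdistrplus::fitdist(x, "lnorm")
            list(params = f$estimate, loglik = f$loglik)
        },
        "weibull" = {
            f <- fitdistrplus::fitdist(x, "weibull")
            list(params = f$estimate, loglik = f$loglik)
        },
        "loglogistic" = fitLlogis(x),
        "burr" = fitBurr(x),
        "pareto" = {
            ## profile MLE: threshold = min(x), closed-form shape
            xm <- min(x)
            shape <- n / sum(log(x / xm))
            ll <- n * log(shape) + n * shape * log(xm) -
                (shape + 1) * sum(log(x))
            list(params = c(shape = shape, min = xm), loglik = ll)
        },
        stop("unknown family: ", family))
    k <- length(fit$params)
    new("DistributionFit", family = family, params = fit$params,
        loglik = fit$loglik, aic = 2 * k - 2 * fit$loglik, n = n)
}

#' Fit candidate distributions to positive abundances
#'
#' Fits log-normal, loglogistic, Weibull, Pareto (type I) and Burr XII by
#' maximum likelihood. Zeros (and negatives) are excluded before fitting and
#' their count reported by message. Families whose optimization fails are
#' reported as failed by warning and listed in the \code{"failed"} attribute,
#' never fabricated.
#'
#' @param values numeric abundances; at least 50 strictly positive values
#'   must remain after zero-exclusion.
#' @param families subset of families to fit (default all five).
#' @return Named list of \linkS4class{DistributionFit} objects (converged
#'   fits only) with attribute \code{"failed"}.
#' @examples
#' fits <- fitDistributions(rlnorm(200, 1, 1))
#' bestFit(fits)@family
#' @export
fitDistributions <- function(values, families = distFamilies) {
    families <- match.arg(families, distFamilies, several.ok = TRUE)
    x <- values[!is.na(values)]
    nZero <- sum(x <= 0)
    if (nZero)
        message("fitDistributions: excluded ", nZero,
                " zero/negative value(s) before fitting")
    x <- x[x > 0]
    if (length(x) == 0L) stop("all values are zero; nothing to fit")
    if (length(x) < 50L)
        stop("too few positive values to fit (", length(x), " < 50)")
    fits <- list(); failed <- character()
    for (fam in families) {
        f <- tryCatch(fitOneFamily(x, fam), error = function(e) e)
        if (inherits(f, "error")) {
            warning("fit of '", fam, "' failed: ", conditionMessage(f))
            failed <- c(failed, fam)
        } else fits[[fam]] <- f
    }
    attr(fits, "failed") <- failed
    fits
}

#' Select the minimum-AIC fit
#'
#' Ties (exactly equal AIC) are broken by fewer parameters, then by the
#' fixed family order log-normal, loglogistic, weibull, pareto, burr.
#'
#' @param fits list of \linkS4class{DistributionFit} from
#'   [fitDistributions()].
#' @return The winning \linkS4class{DistributionFit}.
#' @export
bestFit <- function(fits) {
    fits <- Filter(function(f) is.finite(f@aic), fits)
    if (!length(fits)) stop("no successful fits to select from")
    aic <- vapply(fits, function(f) f@aic, 0)
    k <- vapply(fits, function(f) length(f@params), 0L)
    famRank <- match(vapply(fits, function(f) f@family, ""), distFamilies)
    fits[[order(aic, k, famRank)[1L]]]
}

#' Quantile of a fitted distribution
#'
#' @param fit a \linkS4class{DistributionFit}.
#' @param p probability.
#' @return the p-quantile under the fitted parameters.
#' @export
fitQuantile <- function(fit, p) {
    pr <- fit@params
    switch(fit@family,
        "log-normal" = qlnorm(p, pr["meanlog"], pr["sdlog"]),
        "weibull" = qweibull(p, pr["shape"], pr["scale"]),
        "loglogistic" = qllogis(p, pr["shape"], pr["scale"]),
        "burr" = qburr(p, pr["shape1"], pr["shape2"], pr["scale"]),
        "pareto" = qpareto1(p, pr["shape"], pr["min"]))
}

#' Filter low-expression genes via fitted-distribution tail quantiles
#'
#' Each sample's positive abundances are fitted with [fitDistributions()]
#' and its threshold set to the \code{q}-quantile of the best-AIC fit. A
#' gene is retained if its value exceeds the threshold in at least
#' \code{minSampleFrac} of the samples. This operationalizes threshold
#' choice from how closely the empirical distribution follows the fitted
#' one; both knobs are explicit and logged.
#'
#' @param em an \linkS4class{ExpressionMatrix}.
#' @param q tail quantile in (0, 0.5) (default 0.05).
#' @param minSampleFrac minimum fraction of samples above threshold
#'   (default 0.5).
#' @return The filtered \linkS4class{ExpressionMatrix}; attribute
#'   \code{"thresholds"} holds the per-sample cutoffs.
#' @export
filterLowExpression <- function(em, q = 0.05, minSampleFrac = 0.5) {
    stopifnot(q > 0, q < 0.5)
    a <- abundance(em)
    thr <- vapply(seq_len(ncol(a)), function(j) {
        fits <- suppressMessages(fitDistributions(a[, j]))
        unname(fitQuantile(bestFit(fits), q))
    }, 0)
    keep <- rowMeans(sweep(a, 2L, thr, ">")) >= minSampleFrac
    message("filterLowExpression: retained ", sum(keep), " of ", nrow(a),
            " gene(s) at q = ", q, ", minSampleFrac = ", minSampleFrac)
    if (!any(keep)) warning("no genes survive the expression filter")
    out <- em[keep, ]
    attr(out, "thresholds") <- setNames(thr, colnames(a))
    out
}
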