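#' Accessors for EMG parameter objects and fits
#'
#' \code{emgMu}, \code{emgSigma} and \code{emgLambda} return the normal-mean
#' (typical decoding time), normal-s.d. and exponential-rate components of an
#' \linkS4class{EMGParams} or a fitted \linkS4class{EMGFit}.
#'
#' @param x an \code{EMGParams} or \code{EMGFit}.
#' @return numeric(1).
#' @name emg-accessors
#' @aliases emgMu emgSigma emgLambda emgParams
NULL

#' @rdname emg-accessors
#' @export
setGeneric("emgMu", function(x) standardGeneric("emgMu"))
#' @rdname emg-accessors
#' @export
setGeneric("emgSigma", function(x) standardGeneric("emgSigma"))
#' @rdname emg-accessors
#' @export
setGeneric("emgLambda", function(x) standardGeneric("emgLambda"))
#' @rdname emg-accessors
#' @export
setGeneric("emgParams", function(x) standardGeneric("emgParams"))

setMethod("emgMu", "EMGParams", function(x) x@mu)
setMethod("emgSigma", "EMGParams", function(x) x@sigma)
setMethod("emgLambda", "EMGParams", function(x) x@lambda)
setMethod("emgMu", "EMGFit", function(x) x@params@mu)
setMethod("emgSigma", "EMGFit", function(x) x@params@sigma)
setMethod("emgLambda", "EMGFit", function(x) x@params@lambda)
setMethod("emgParams", "EMGFit", function(x) x@params)

#' @importFrom stats logLik
#' @export
setMethod("logLik", "EMGFit", function(object, ...) {
    structure(object@loglik, df = 3L, nobs = object@n, class = "logLik")
})

#' Fit status accessors
#'
#' @param x an \linkS4class{EMGFit}.
#' @return \code{isConverged}: logical(1); \code{fitStatus}: character(1);
#'   \code{nSamples}: integer(1).
#' @name fit-accessors
#' @aliases isConverged fitStatus nSamples
NULL

#' @rdname fit-accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @rdname fit-accessors
#' @export
setGeneric("fitStatus", function(x) standardGeneric("fitStatus"))
#' @rdname fit-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

setMethod("isConverged", "EMGFit", function(x) x@converged)
setMethod("fitStatus", "EMGFit", function(x) x@status)
setMethod("nSamples", "EMGFit", function(x) x@n)

#' Accessors for CodonNFCTable and DecodingRateTable
#'
#' \code{nfcSamples} returns the pooled NFC sample vector of one codon (or
#' the full named list); \code{codons} lists the codons present;
#' \code{decodingTimes} and \code{decodingRates} return named per-codon
#' \code{mu} and \code{1/mu} vectors; \code{filterReport} returns the
#' per-gene preprocessing report.
#'
#' @param x a \linkS4class{CodonNFCTable} or \linkS4class{DecodingRateTable}.
#' @param codon optional codon string to extract a single bucket.
#' @return See details per function.
#' @name table-accessors
#' @aliases nfcSamples codons decodingTimes decodingRates filterReport
NULL

#' @rdname table-accessors
#' @export
setGeneric("nfcSamples", function(x, codon) standardGeneric("nfcSamples"))
#' @rdname table-accessors
#' @export
setGeneric("codons", function(x) standardGeneric("codons"))
#' @rdname table-accessors
#' @export
setGeneric("decodingTimes", function(x) standardGeneric("decodingTimes"))
#' @rdname table-accessors
#' @export
setGeneric("decodingRates", function(x) standardGeneric("decodingRates"))
#' @rdname table-accessors
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))

setMethod("nfcSamples", "CodonNFCTable", function(x, codon) {
    if (missing(codon)) return(x@samples)
    if (!codon %in% names(x@samples)) return(numeric(0))
    x@samples[[codon]]
})
setMethod("codons", "CodonNFCTable", function(x) names(x@samples))
setMethod("codons", "DecodingRateTable", function(x) x@table$codon)
setMethod("decodingTimes", "DecodingRateTable", function(x)
    stats::setNames(x@table$mu, x@table$codon))
setMethod("decodingRates", "DecodingRateTable", function(x)
    stats::setNames(x@table$rate, x@table$codon))
setMethod("filterReport", "CodonNFCTable", function(x) x@report)

#' Coerce a DecodingRateTable to data.frame
#'
#' @param x a \linkS4class{DecodingRateTable}.
#' @param ... ignored.
#' @return data.frame with one row per fitted codon.
#' @export
as.data.frame.DecodingRateTable <- function(x, ...) x@table

setMethod("show", "EMGParams", function(object) {
    cat(sprintf("EMGParams: mu = %.6g, sigma = %.6g, lambda = %.6g (1/lambda = %.6g)\n",
                object@mu, object@sigma, object@lambda, 1 / object@lambda))
})

setMethod("show", "EMGFit", function(object) {
    cat(sprintf("EMGFit [%s]: n = %d, converged = %s\n", object@status,
                object@n, object@converged))
    if (object@status != "unfit") {
        cat(sprintf("  mu = %.6g, sigma = %.6g, lambda = %.6g, loglik = %.6g\n",
                    object@params@mu, object@params@sigma,
                    object@params@lambda, object@loglik))
    }
})

setMethod("show", "CodonNFCTable", function(object) {
    ns <- lengths(object@samples)
    cat(sprintf("CodonNFCTable: %d codon types, %d NFC samples from %d genes\n",
                length(ns), object@positionsUsed, object@genesUsed))
    if (length(ns))
        cat(sprintf("  samples per codon: min %d, median %.0f, max %d\n",
                    min(ns), stats::median(ns), max(ns)))
})

setMethod("show", "DecodingRateTable", function(object) {
    tab <- object@table
    cat(sprintf("DecodingRateTable: %d codons\n", nrow(tab)))
    if (nrow(tab))
        cat(sprintf("  typical decoding time mu: %.4g - %.4g; rate: %.4g - %.4g\n",
                    min(tab$mu), max(tab$mu), min(tab$rate), max(tab$rate)))
    if (length(object@metadata))
        cat("  metadata:", paste(names(object@metadata),
            vapply(object@metadata, function(v) paste(format(v), collapse = ","),
                   character(1)), sep = "=", collapse = "; "), "\n")
})
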