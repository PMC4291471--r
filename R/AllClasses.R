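#' @import methods
NULL

#' EMGParams: parameters of an exponentially modified Gaussian
#'
#' Parameter triple of the exponentially modified Gaussian (EMG) used to
#' model a codon's normalized footprint count (NFC) distribution: the sum of
#' a normal component (typical, pause-free decoding time; mean \code{mu},
#' s.d. \code{sigma}, NFC units) and an exponential component (rare pauses
#' and ribosomal traffic jams; \emph{rate} \code{lambda}, so the mean pause
#' contribution is \code{1/lambda}).
#'
#' @slot mu numeric(1), mean of the normal component (typical decoding time).
#' @slot sigma positive numeric(1), s.d. of the normal component.
#' @slot lambda positive numeric(1), rate of the exponential component.
#'
#' @aliases EMGParams-class
#' @exportClass EMGParams
#' @export EMGParams
#' @examples
#' EMGParams(mu = 0.2, sigma = 0.05, lambda = 5)
EMGParams <- setClass("EMGParams",
    representation(mu = "numeric", sigma = "numeric", lambda = "numeric"))

setValidity("EMGParams", function(object) {
    msg <- character(0)
    if (length(object@mu) != 1L || !is.finite(object@mu))
        msg <- c(msg, "mu must be a single finite number")
    if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
        object@sigma <= 0)
        msg <- c(msg, "sigma must be a single positive number")
    if (length(object@lambda) != 1L || !is.finite(object@lambda) ||
        object@lambda <= 0)
        msg <- c(msg, "lambda must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' EMGFit: maximum-likelihood EMG fit for one codon
#'
#' Result of fitting an EMG to one codon's pooled NFC samples by maximum
#' likelihood. \code{status} is \code{"ok"} for a usable fit, \code{"unfit"}
#' when the codon had fewer than \code{minSamples} NFC samples, and
#' \code{"atypical"} when the fitted \code{mu} was non-positive (a decoding
#' time must be positive; such codons are excluded from rate tables).
#'
#' @slot params \linkS4class{EMGParams}, the fitted parameters.
#' @slot init \linkS4class{EMGParams}, the method-of-moments start.
#' @slot loglik numeric(1), maximized log-likelihood (NA when unfit).
#' @slot n integer(1), number of NFC samples fitted.
#' @slot converged logical(1), optimizer status and gradient-norm check.
#' @slot nIter integer(1), objective evaluations used.
#' @slot status character(1), one of "ok", "unfit", "atypical".
#'
#' @aliases EMGFit-class
#' @exportClass EMGFit
#' @export EMGFit
EMGFit <- setClass("EMGFit",
    representation(params = "EMGParams", init = "EMGParams",
                   loglik = "numeric", n = "integer", converged = "logical",
                   nIter = "integer", status = "character"))

setValidity("EMGFit", function(object) {
    msg <- character(0)
    if (!object@status %in% c("ok", "unfit", "atypical"))
        msg <- c(msg, "status must be 'ok', 'unfit' or 'atypical'")
    if (object@status != "unfit" && object@converged &&
        !is.finite(object@loglik))
        msg <- c(msg, "loglik must be finite for a converged fit")
    if (length(msg)) msg else TRUE
})

#' CodonNFCTable: pooled NFC samples per codon type
#'
#' Container for the per-codon normalized footprint count distributions:
#' for each sense codon, the vector of NFC values pooled over all analyzed
#' genes and surviving positions. Only sense codons appear (stop codons are
#' never decoded and are excluded unconditionally).
#'
#' @slot samples named list; names are sense codons, elements numeric vectors
#'   of positive NFC values.
#' @slot genesUsed integer(1), genes contributing at least one sample.
#' @slot positionsUsed integer(1), total surviving codon positions.
#' @slot report data.frame with per-gene filter outcomes (gene_id, statistic,
#'   kept, reason).
#'
#' @aliases CodonNFCTable-class
#' @exportClass CodonNFCTable
#' @export CodonNFCTable
CodonNFCTable <- setClass("CodonNFCTable",
    representation(samples = "list", genesUsed = "integer",
                   positionsUsed = "integer", report = "data.frame"))

setValidity("CodonNFCTable", function(object) {
    msg <- character(0)
    nm <- names(object@samples)
    if (is.null(nm) && length(object@samples))
        msg <- c(msg, "samples must be a named list")
    bad <- setdiff(nm, senseCodons())
    if (length(bad))
        msg <- c(msg, paste0("non-sense-codon keys: ",
                             paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' DecodingRateTable: per-codon typical decoding times and rates
#'
#' Per-codon table of the fitted typical decoding time \code{mu} and the
#' derived typical decoding rate \code{1/mu}, together with the remaining
#' EMG parameters and fit bookkeeping. Only codons with a converged fit and
#' \code{mu > 0} are present.
#'
#' @slot table data.frame with columns codon, mu, sigma, lambda, inv_lambda,
#'   rate, n_samples, converged.
#' @slot metadata named list of run provenance (label, config hash, seed).
#'
#' @aliases DecodingRateTable-class
#' @exportClass DecodingRateTable
#' @export DecodingRateTable
DecodingRateTable <- setClass("DecodingRateTable",
    representation(table = "data.frame", metadata = "list"))

setValidity("DecodingRateTable", function(object) {
    tab <- object@table
    need <- c("codon", "mu", "sigma", "lambda", "inv_lambda", "rate",
              "n_samples", "converged")
    msg <- character(0)
    if (!all(need %in% names(tab)))
        msg <- c(msg, paste0("missing columns: ",
                             paste(setdiff(need, names(tab)), collapse = ", ")))
    else {
        if (nrow(tab) > 61L) msg <- c(msg, "more than 61 codon entries")
        if (nrow(tab) && any(tab$mu <= 0))
            msg <- c(msg, "all mu must be positive")
        if (nrow(tab) && any(abs(tab$rate * tab$mu - 1) > 1e-9))
            msg <- c(msg, "rate must equal 1/mu")
        if (anyDuplicated(tab$codon)) msg <- c(msg, "duplicate codons")
    }
    if (length(msg)) msg else TRUE
})
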