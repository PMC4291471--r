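## mtdr_index module: decoding times -> rates -> geometric-mean ORF scores.
##
## The typical decoding rate of a codon is the reciprocal of its typical
## decoding time mu (the only dimensionally consistent conversion), and the
## MTDR index of an ORF is the geometric mean of its codons' rates. Target
## ORFs are scored over ALL their sense codons by default: the 20-codon end
## trim is an estimation-side artifact filter, not part of scoring (a
## trimEnds flag reproduces the trimmed variant).

#' Build a decoding-rate table from per-codon EMG fits
#'
#' Keeps codons whose fit converged with status \code{"ok"} and positive
#' \code{mu}; the typical decoding rate is \code{1/mu}. Unfit and atypical
#' codons are absent from the table (scoring handles them via its
#' missing-codon policy).
#'
#' @param fits named list of \linkS4class{EMGFit} (names are codons), as
#'   returned by \code{\link{fitAllCodons}}.
#' @param metadata named list of provenance (label, config hash, seed).
#' @return A \linkS4class{DecodingRateTable}.
#' @export
ratesFromTimes <- function(fits, metadata = list()) {
    if (!length(fits)) stop("no fits supplied")
    keep <- vapply(fits, function(f)
        fitStatus(f) == "ok" && isConverged(f) && emgMu(f) > 0, logical(1))
    if (!any(keep))
        stop("no converged fit with positive typical decoding time")
    fits <- fits[keep]
    tab <- data.frame(
        codon = names(fits),
        mu = vapply(fits, emgMu, numeric(1)),
        sigma = vapply(fits, emgSigma, numeric(1)),
        lambda = vapply(fits, emgLambda, numeric(1)),
        inv_lambda = 1 / vapply(fits, emgLambda, numeric(1)),
        rate = 1 / vapply(fits, emgMu, numeric(1)),
        n_samples = vapply(fits, nSamples, integer(1)),
        converged = vapply(fits, isConverged, logical(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    new("DecodingRateTable", table = tab, metadata = metadata)
}

#' Construct a decoding-rate table directly from known times
#'
#' Used to score ORFs under known (e.g. simulation ground-truth) decoding
#' times rather than fitted ones.
#'
#' @param mu named numeric vector of positive decoding times, names codons.
#' @param metadata named list of provenance.
#' @return A \linkS4class{DecodingRateTable}.
#' @export
rateTableFromTimes <- function(mu, metadata = list()) {
    stopifnot(!is.null(names(mu)), all(mu > 0))
    tab <- data.frame(codon = names(mu), mu = unname(mu), sigma = NA_real_,
                      lambda = NA_real_, inv_lambda = NA_real_,
                      rate = 1 / unname(mu),
                      n_samples = NA_integer_, converged = TRUE,
                      stringsAsFactors = FALSE)
    new("DecodingRateTable", table = tab, metadata = metadata)
}

#' MTDR index of one ORF
#'
#' Geometric mean of the typical decoding rates of the ORF's codons. A
#' terminal stop codon is never scored; internal stop codons are skipped
#' with a warning. Codons absent from the rate table are excluded and
#' counted (\code{policy = "skip"}, default) or raise an error
#' (\code{policy = "strict"}).
#'
#' @param orf character(1) nucleotide sequence (in frame) or a length-1
#'   \link[Biostrings]{DNAStringSet} / \code{DNAString}.
#' @param table a \linkS4class{DecodingRateTable}.
#' @param policy \code{"skip"} or \code{"strict"} for codons without a rate.
#' @param trimEnds logical; if TRUE the first and last 20 codons of the ORF
#'   are not scored (estimation-style trimming; default FALSE).
#' @return list(mtdr, n_used, n_skipped, skipped_codons).
#' @export
#' @examples
#' tab <- rateTableFromTimes(c(AAA = 0.5, GGG = 0.125))
#' computeMtdr("AAAGGG", tab)$mtdr  # sqrt(2 * 8) = 4
computeMtdr <- function(orf, table, policy = c("skip", "strict"),
                        trimEnds = FALSE) {
    policy <- match.arg(policy)
    if (is(orf, "DNAStringSet")) orf <- as.character(orf[[1L]])
    else if (is(orf, "DNAString")) orf <- as.character(orf)
    cods <- splitCodons(toupper(chartr("U", "T", orf)))
    if (!length(cods)) stop("empty ORF")
    if (cods[length(cods)] %in% stopCodons())
        cods <- cods[-length(cods)]
    if (!length(cods)) stop("ORF contains only a stop codon")
    internal <- cods %in% stopCodons()
    if (any(internal)) {
        warning(sum(internal), " internal stop codon(s) skipped")
        cods <- cods[!internal]
    }
    if (trimEnds) {
        if (length(cods) <= 40L)
            stop("ORF too short to score with trimEnds = TRUE")
        cods <- cods[21L:(length(cods) - 20L)]
    }
    rate <- decodingRates(table)
    have <- cods %in% names(rate)
    if (policy == "strict" && !all(have))
        stop("codon(s) without a decoding rate: ",
             paste(unique(cods[!have]), collapse = ", "))
    if (!any(have))
        stop("no codon of the ORF has a decoding rate")
    list(mtdr = geomMean(rate[cods[have]]),
         n_used = sum(have), n_skipped = sum(!have),
         skipped_codons = cods[!have])
}

#' MTDR indexes for a batch of ORFs
#'
#' Applies \code{\link{computeMtdr}} to each ORF, preserving input order.
#' Under the skip policy, per-ORF failures (e.g. no scorable codon) become
#' NA rows with the reason in \code{note} instead of aborting the batch.
#'
#' @param orfs a \link[Biostrings]{DNAStringSet} or named character vector.
#' @param table a \linkS4class{DecodingRateTable}.
#' @inheritParams computeMtdr
#' @return data.frame(gene_id, mtdr, n_used, n_skipped, note), one row per
#'   ORF in input order.
#' @export
scoreMtdr <- function(orfs, table, policy = c("skip", "strict"),
                      trimEnds = FALSE) {
    policy <- match.arg(policy)
    seqs <- if (is(orfs, "DNAStringSet")) as.character(orfs) else orfs
    if (!length(seqs))
        return(data.frame(gene_id = character(0), mtdr = numeric(0),
                          n_used = integer(0), n_skipped = integer(0),
                          note = character(0), stringsAsFactors = FALSE))
    ids <- names(seqs)
    if (is.null(ids)) ids <- sprintf("orf%04d", seq_along(seqs))
    rows <- lapply(seq_along(seqs), function(i) {
        res <- if (policy == "strict") {
            computeMtdr(seqs[[i]], table, policy = "strict",
                        trimEnds = trimEnds)
        } else {
            tryCatch(computeMtdr(seqs[[i]], table, policy = "skip",
                                 trimEnds = trimEnds),
                     error = function(e)
                         list(mtdr = NA_real_, n_used = 0L, n_skipped = 0L,
                              note = conditionMessage(e)))
        }
        data.frame(gene_id = ids[i], mtdr = res$mtdr, n_used = res$n_used,
                   n_skipped = res$n_skipped,
                   note = if (is.null(res$note)) "" else res$note,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' One-call estimation pipeline: profiles + ORFs -> decoding-rate table
#'
#' Convenience wrapper running preprocessing, per-codon EMG fitting and
#' rate-table construction.
#'
#' @param profiles named list of codon-resolution count vectors.
#' @param orfs a \link[Biostrings]{DNAStringSet}.
#' @param cfg a \code{\link{filterConfig}}.
#' @param label free-text condition label recorded in the table metadata.
#' @param seed deterministic restart seed for \code{\link{fitEmg}}.
#' @param ... further options passed to \code{\link{fitEmg}}.
#' @return list(table = \linkS4class{DecodingRateTable},
#'   fits = named list of \linkS4class{EMGFit},
#'   nfc = \linkS4class{CodonNFCTable}).
#' @export
estimateDecodingRates <- function(profiles, orfs, cfg = filterConfig(),
                                  label = "run", seed = 1L, ...) {
    nfc <- buildNfcTable(profiles, orfs, cfg)
    if (!length(nfcSamples(nfc)))
        stop("no gene passed the preprocessing filters")
    fits <- fitAllCodons(nfc, seed = seed, ...)
    tab <- ratesFromTimes(fits, metadata = list(
        label = label, config = configHash(cfg), seed = seed))
    list(table = tab, fits = fits, nfc = nfc)
}
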