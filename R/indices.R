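## codon_indices module: CAI and tAI reference implementations, plus the
## reciprocal decoding-time transforms (DTCAI / DTtAI) used as comparison
## time proxies for the EMG-estimated typical decoding times.

#' Codon adaptation index weights (Sharp-Li)
#'
#' Relative adaptiveness of each sense codon in a highly expressed reference
#' gene set: within every synonymous family,
#' \code{w = (count + pseudo) / max(count + pseudo)}, so the most frequent
#' synonym has weight 1. The pseudo-count floor keeps absent codons at a
#' small positive weight (a zero weight would annihilate the geometric
#' mean). Single-codon families (ATG, TGG) get w = 1.
#'
#' @param referenceOrfs \link[Biostrings]{DNAStringSet} of reference ORFs.
#' @param pseudo pseudo-count added to every codon count (default 0.5).
#' @return Named numeric vector of 61 weights in (0, 1].
#' @export
caiWeights <- function(referenceOrfs, pseudo = 0.5) {
    if (!length(referenceOrfs)) stop("empty reference set")
    cods <- unlist(lapply(as.character(referenceOrfs), splitCodons),
                   use.names = FALSE)
    cods <- cods[!cods %in% stopCodons()]
    counts <- table(factor(cods, levels = senseCodons()))
    counts <- as.numeric(counts) + pseudo
    names(counts) <- senseCodons()
    aa <- codonAminoAcid(senseCodons())
    fam_max <- tapply(counts, aa, max)
    ## families entirely absent from the reference (possible with pseudo = 0)
    ## get zero weights rather than 0/0
    w <- ifelse(fam_max[aa] > 0, counts / fam_max[aa], 0)
    names(w) <- senseCodons()
    if (any(w <= 0))
        warning("zero CAI weight for codon(s) absent from the reference; ",
                "use a positive pseudo-count to score ORFs containing them")
    w
}

#' Codon adaptation index of an ORF
#'
#' Geometric mean of the reference weights of the ORF's sense codons. By
#' Sharp-Li convention, codons of single-codon families (ATG, TGG) are
#' excluded from the mean (configurable).
#'
#' @param orf character(1) nucleotide sequence or Biostrings object.
#' @param weights named weight vector from \code{\link{caiWeights}}.
#' @param excludeSingleFamilies logical; drop ATG and TGG (default TRUE).
#' @return numeric(1) in (0, 1].
#' @export
cai <- function(orf, weights, excludeSingleFamilies = TRUE) {
    if (is(orf, "DNAStringSet")) orf <- as.character(orf[[1L]])
    else if (is(orf, "DNAString")) orf <- as.character(orf)
    cods <- splitCodons(toupper(chartr("U", "T", orf)))
    cods <- cods[!cods %in% stopCodons()]
    if (excludeSingleFamilies) cods <- cods[!cods %in% c("ATG", "TGG")]
    cods <- cods[cods %in% names(weights)]
    if (!length(cods)) stop("no scorable codons for CAI")
    if (any(weights[cods] <= 0))
        stop("zero-weight codon in ORF; refit weights with pseudo > 0")
    geomMean(weights[cods])
}

#' Wobble-interaction penalties for tAI (dos Reis defaults)
#'
#' Selective constraints s for the nine codon-anticodon pairing classes of
#' the dos Reis tAI scheme, in the order: Watson-Crick T, C, A, G wobble
#' positions, then G:U, I:C, I:A, U:G and the modified-C:A (prokaryotic
#' ATA) interaction.
#'
#' @return numeric vector of length 9.
#' @export
dosReisSValues <- function() {
    c(0, 0, 0, 0, 0.41, 0.28, 0.9999, 0.68, 0.89)
}

#' tRNA adaptation index weights (dos Reis)
#'
#' Absolute adaptiveness of each sense codon:
#' \code{W = sum over recognizing anticodons of (1 - s) * tGCN}, walking
#' the 16 codon boxes with the standard wobble rules (perfect pair plus one
#' wobble pair per codon-ending base), the methionine special case and,
#' for prokaryotes, the lysidine-modified CAT anticodon reading ATA.
#' Weights are normalized to max 1; zero weights are replaced by the
#' geometric mean of the nonzero weights (dos Reis convention), keeping the
#' geometric mean defined.
#'
#' @param tgcn named numeric vector of tRNA gene copy numbers per anticodon
#'   (5'->3' anticodon strings, e.g. the anticodon reading TTT is AAA).
#' @param s wobble penalties, default \code{\link{dosReisSValues}}.
#' @param prokaryote logical; apply the ATA special case (default FALSE).
#' @return Named numeric vector of 61 weights in (0, 1].
#' @export
taiWeights <- function(tgcn, s = dosReisSValues(), prokaryote = FALSE) {
    stopifnot(length(s) == 9L)
    if (!length(tgcn) || all(tgcn == 0)) stop("all-zero tRNA copy numbers")
    all64 <- allCodons()
    ## tGCN reordered so entry i is the copy number of the anticodon that
    ## perfectly pairs codon i (reverse complement).
    perfect <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(all64)))
    gcn <- ifelse(perfect %in% names(tgcn), tgcn[perfect], 0)
    p <- 1 - s
    W <- numeric(64L)
    for (i in seq(1L, 61L, by = 4L)) {
        W[i]      <- p[1L] * gcn[i]      + p[5L] * gcn[i + 1L]  # NNT
        W[i + 1L] <- p[2L] * gcn[i + 1L] + p[6L] * gcn[i]      # NNC
        W[i + 2L] <- p[3L] * gcn[i + 2L] + p[7L] * gcn[i]      # NNA
        W[i + 3L] <- p[4L] * gcn[i + 3L] + p[8L] * gcn[i + 2L] # NNG
    }
    names(W) <- all64
    W["ATG"] <- p[4L] * gcn[all64 == "ATG"]   # Met: CAT anticodon only
    if (prokaryote) W["ATA"] <- p[9L]         # lysidine-modified CAT
    W <- W[senseCodons()]
    if (max(W) <= 0) stop("all tAI weights are zero")
    w <- W / max(W)
    if (any(w == 0)) {
        gm <- geomMean(w[w > 0])
        w[w == 0] <- gm
    }
    w
}

#' tRNA adaptation index of an ORF
#'
#' Geometric mean of the tAI weights of the ORF's sense codons.
#'
#' @param orf character(1) nucleotide sequence or Biostrings object.
#' @param weights named weight vector from \code{\link{taiWeights}}.
#' @return numeric(1) in (0, 1].
#' @export
tai <- function(orf, weights) {
    if (is(orf, "DNAStringSet")) orf <- as.character(orf[[1L]])
    else if (is(orf, "DNAString")) orf <- as.character(orf)
    cods <- splitCodons(toupper(chartr("U", "T", orf)))
    cods <- cods[!cods %in% stopCodons()]
    cods <- cods[cods %in% names(weights)]
    if (!length(cods)) stop("no scorable codons for tAI")
    geomMean(weights[cods])
}

#' Decoding-time transform of adaptiveness weights
#'
#' Converts per-codon adaptiveness weights into decoding-time proxies
#' (DTCAI from CAI weights, DTtAI from tAI weights): the reciprocal of the
#' weight by default (\code{w = 1} is the fastest codon, DT = 1), or
#' \code{-log(w)} with \code{transform = "log"}. Both are strictly
#' decreasing in the weight, so rank comparisons against fitted typical
#' decoding times are transform-independent.
#'
#' @param weights positive named weight vector.
#' @param transform \code{"reciprocal"} (default) or \code{"log"}.
#' @return Named numeric vector of per-codon decoding-time proxies.
#' @export
decodingTimeTransform <- function(weights,
                                  transform = c("reciprocal", "log")) {
    transform <- match.arg(transform)
    stopifnot(all(weights > 0))
    if (transform == "reciprocal") 1 / weights else -base::log(weights)
}

#' Read a tRNA gene copy number table
#'
#' TSV \code{anticodon<TAB>copies}.
#'
#' @param path input TSV.
#' @return Named numeric vector keyed by anticodon.
#' @export
readTgcn <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                             check.names = FALSE,
                             colClasses = c("character", "numeric"))
    stats::setNames(tab[[2L]], toupper(chartr("U", "T", tab[[1L]])))
}
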