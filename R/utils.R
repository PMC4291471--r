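## Internal helpers shared across modules.

#' Sense codons
#'
#' The 61 sense codons of the standard genetic code, in T/C/A/G base order
#' (stop codons TAA, TAG, TGA removed). All per-codon tables in the package
#' are keyed by this set.
#'
#' @return Character vector of length 61.
#' @export
#' @examples
#' length(senseCodons())
senseCodons <- function() {
    bases <- c("T", "C", "A", "G")
    all64 <- as.vector(t(outer(
        as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
    setdiff(all64, c("TAA", "TAG", "TGA"))
}

## All 64 codons in T/C/A/G order (the order the tAI box scheme walks).
allCodons <- function() {
    bases <- c("T", "C", "A", "G")
    as.vector(t(outer(as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
}

stopCodons <- function() c("TAA", "TAG", "TGA")

## Amino acid per codon from the standard code; used to group synonymous
## families for CAI. Biostrings ships the canonical table.
codonAminoAcid <- function(codons) {
    gc <- Biostrings::GENETIC_CODE
    unname(gc[codons])
}

## Split an in-frame nucleotide string into codons. Sequence length must be
## a multiple of 3 (validated at ingest).
splitCodons <- function(seq) {
    n <- nchar(seq)
    if (n == 0L) return(character(0))
    if (n %% 3L != 0L)
        stop("sequence length ", n, " is not a multiple of 3")
    substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

## Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
## state afterwards so library code never clobbers user randomness.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("seed must be a single finite number")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Short md5 fingerprint of an R object (config provenance in output files).
configHash <- function(x) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(deparse(x), tf)
    substr(unname(tools::md5sum(tf)), 1L, 12L)
}

## Geometric mean of a positive vector.
geomMean <- function(x) exp(mean(log(x)))
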