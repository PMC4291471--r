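## preprocess module: gene/position filters and per-codon NFC pooling.
##
## Order of operations is fixed: gene filter (on the full, untrimmed
## profile) -> end trimming -> low-count position filter -> per-gene mean
## normalization -> pooling by codon type. Ribosome profiles are unreliable
## for sparsely covered genes, carry an initiation-proximal density ramp
## over roughly the first 20 codons (and for some organisms a terminal
## excess), and individual positions with fewer than one footprint count
## are dominated by mapping noise; each filter targets one of these.

#' Preprocessing filter configuration
#'
#' @param trimStart,trimEnd codons removed from each profile end before
#'   normalization (default 20 each; removes the 5' ramp and terminal
#'   excess).
#' @param geneStat summary statistic for the whole-gene coverage filter,
#'   \code{"median"} (default) or \code{"mean"}.
#' @param geneThreshold a gene is kept iff \code{geneStat(counts) >
#'   geneThreshold} (strict; default 1).
#' @param codonMinFc positions with footprint count below this are excluded
#'   (default 1).
#' @param minLenAfterTrim minimum surviving codons for a gene to contribute
#'   (default 1).
#' @param denominator positions over which the per-gene normalizing mean is
#'   taken: \code{"passing"} (default; trimmed positions that also pass
#'   \code{codonMinFc}, so the mean NFC of contributing positions is exactly
#'   1) or \code{"all_trimmed"} (all trimmed positions).
#' @return A validated \code{FilterConfig} list.
#' @export
#' @examples
#' cfg <- filterConfig()
#' cfg$trimStart
filterConfig <- function(trimStart = 20L, trimEnd = 20L,
                         geneStat = c("median", "mean"), geneThreshold = 1,
                         codonMinFc = 1, minLenAfterTrim = 1L,
                         denominator = c("passing", "all_trimmed")) {
    geneStat <- match.arg(geneStat)
    denominator <- match.arg(denominator)
    stopifnot(trimStart >= 0, trimEnd >= 0, geneThreshold >= 0,
              codonMinFc >= 0, minLenAfterTrim >= 1)
    structure(list(trimStart = as.integer(trimStart),
                   trimEnd = as.integer(trimEnd),
                   geneStat = geneStat, geneThreshold = geneThreshold,
                   codonMinFc = codonMinFc,
                   minLenAfterTrim = as.integer(minLenAfterTrim),
                   denominator = denominator),
              class = "FilterConfig")
}

#' Whole-gene coverage filter
#'
#' Keeps a gene iff the configured summary statistic of its full, untrimmed
#' footprint-count profile strictly exceeds \code{geneThreshold}. Genes with
#' mostly-zero profiles produce unreliable NFC values and would bias the
#' per-codon distributions.
#'
#' @param profiles named list of numeric count vectors.
#' @param cfg a \code{\link{filterConfig}}.
#' @return list(kept = retained profiles, report = per-gene data.frame with
#'   gene_id, statistic, kept, reason).
#' @export
filterGenes <- function(profiles, cfg = filterConfig()) {
    if (!length(profiles)) stop("no profiles supplied")
    statFun <- if (cfg$geneStat == "median") stats::median else mean
    stat <- vapply(profiles, statFun, numeric(1))
    keep <- stat > cfg$geneThreshold
    report <- data.frame(
        gene_id = names(profiles), statistic = unname(stat),
        kept = unname(keep),
        reason = ifelse(keep, "",
                        sprintf("%s FC %.4g <= %.4g", cfg$geneStat,
                                stat, cfg$geneThreshold)),
        stringsAsFactors = FALSE)
    list(kept = profiles[keep], report = report)
}

#' Trim profile ends
#'
#' Removes the first \code{trimStart} and last \code{trimEnd} codon
#' positions. Returns NULL when fewer than \code{minLenAfterTrim} positions
#' would remain (such genes are excluded and show up in the report).
#'
#' @param counts numeric count vector for one gene.
#' @param cfg a \code{\link{filterConfig}}.
#' @return Trimmed numeric vector, or NULL if the gene is too short.
#' @export
trimProfile <- function(counts, cfg = filterConfig()) {
    n <- length(counts)
    if (n < cfg$trimStart + cfg$trimEnd + cfg$minLenAfterTrim) return(NULL)
    counts[(cfg$trimStart + 1L):(n - cfg$trimEnd)]
}

#' Normalize a trimmed profile to NFC values
#'
#' Positions with count below \code{codonMinFc} are excluded; remaining
#' counts are divided by the per-gene mean (over the positions selected by
#' \code{cfg$denominator}), yielding normalized footprint counts (NFC) that
#' are comparable across genes with different mRNA levels and initiation
#' rates.
#'
#' @param counts trimmed numeric count vector.
#' @param cfg a \code{\link{filterConfig}}.
#' @return data.frame(position, nfc); positions index the trimmed profile
#'   (1-based). Zero rows when no position passes.
#' @export
normalizeProfile <- function(counts, cfg = filterConfig()) {
    pass <- which(counts >= cfg$codonMinFc)
    if (!length(pass))
        return(data.frame(position = integer(0), nfc = numeric(0)))
    denom <- if (cfg$denominator == "passing") mean(counts[pass])
             else mean(counts)
    if (denom <= 0)
        return(data.frame(position = integer(0), nfc = numeric(0)))
    data.frame(position = pass, nfc = counts[pass] / denom)
}

#' Build the pooled per-codon NFC table
#'
#' Runs the full preprocessing chain on a set of profiles and their ORF
#' sequences: gene filter, end trimming, position filter, normalization,
#' then pooling of each surviving (position, NFC) pair into the bucket of
#' the codon at that position. Stop codons never enter the table. Genes in
#' the profiles but absent from the ORF set, or whose profile length does
#' not match the ORF codon count, are skipped with a warning.
#'
#' @param profiles named list of numeric count vectors (codon resolution).
#' @param orfs a \link[Biostrings]{DNAStringSet} of matching ORFs.
#' @param cfg a \code{\link{filterConfig}}.
#' @return A \linkS4class{CodonNFCTable}.
#' @export
buildNfcTable <- function(profiles, orfs, cfg = filterConfig()) {
    flt <- filterGenes(profiles, cfg)
    report <- flt$report
    orfSeqs <- stats::setNames(as.character(orfs), names(orfs))
    buckets <- lapply(stats::setNames(nm = senseCodons()),
                      function(...) list())
    genesUsed <- 0L
    positionsUsed <- 0L
    markReason <- function(id, why) {
        report$kept[report$gene_id == id] <<- FALSE
        report$reason[report$gene_id == id] <<- why
    }
    for (id in names(flt$kept)) {
        counts <- flt$kept[[id]]
        if (!id %in% names(orfSeqs)) {
            warning("gene ", id, " has no ORF sequence; skipped")
            markReason(id, "no ORF sequence")
            next
        }
        cods <- splitCodons(orfSeqs[[id]])
        if (length(cods) != length(counts)) {
            warning("gene ", id, ": profile length ", length(counts),
                    " != ORF codon count ", length(cods), "; skipped")
            markReason(id, "profile/ORF length mismatch")
            next
        }
        trimmed <- trimProfile(counts, cfg)
        if (is.null(trimmed)) {
            markReason(id, "too short after trimming")
            next
        }
        nfc <- normalizeProfile(trimmed, cfg)
        if (!nrow(nfc)) {
            markReason(id, "no position passed codonMinFc")
            next
        }
        codAt <- cods[cfg$trimStart + nfc$position]
        sense <- !codAt %in% stopCodons()
        if (!any(sense)) {
            markReason(id, "no sense-codon position survived")
            next
        }
        genesUsed <- genesUsed + 1L
        positionsUsed <- positionsUsed + sum(sense)
        sp <- split(nfc$nfc[sense], codAt[sense])
        for (cc in names(sp))
            buckets[[cc]][[length(buckets[[cc]]) + 1L]] <- sp[[cc]]
    }
    samples <- lapply(buckets, function(b) unlist(b, use.names = FALSE))
    samples <- samples[lengths(samples) > 0L]
    new("CodonNFCTable", samples = samples, genesUsed = genesUsed,
        positionsUsed = positionsUsed, report = report)
}

#' Write a per-gene preprocessing report
#'
#' TSV with columns gene_id, statistic, kept, reason. Positions in reasons
#' are 1-based inclusive.
#'
#' @param x a \linkS4class{CodonNFCTable}.
#' @param path output TSV path.
#' @param metadata named list written as \code{#} comment lines.
#' @export
writeFilterReport <- function(x, path, metadata = list()) {
    writeCommentedTsv(filterReport(x), path, metadata)
}
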