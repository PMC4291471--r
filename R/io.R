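## io module: every external file format the pipeline touches.
##
## Profiles are consumed at CODON resolution: one non-negative real count per
## codon position. Counts are reals, not integers, because upstream pipelines
## often emit multi-mapping-weighted or length-normalized coverage. gene_id
## matching across files is exact, case-sensitive string match.

#' Read open reading frames from a FASTA file
#'
#' Reads ORF nucleotide sequences (the scoring targets and, for estimation,
#' the codon identities behind each profile position). Sequences are
#' upper-cased and U is mapped to T, so RNA FASTA works. The gene id is the
#' first whitespace-delimited token of the header.
#'
#' @param path FASTA file (multi-line sequences allowed).
#' @param strict logical; if TRUE a sequence whose length is not a multiple
#'   of 3 is an error, otherwise the record is dropped with a warning.
#' @return A \link[Biostrings]{DNAStringSet}, one entry per retained record.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 demo", "atggaa"), fa)
#' readOrfFasta(fa)
readOrfFasta <- function(path, strict = FALSE) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    raw <- Biostrings::readBStringSet(path)
    seqs <- toupper(as.character(raw))
    seqs <- chartr("U", "T", seqs)
    ids <- vapply(strsplit(names(raw), "\\s+"), `[`, character(1), 1L)
    bad_char <- grepl("[^ACGT]", seqs)
    if (any(bad_char))
        stop("non-ACGTU characters in record(s): ",
             paste(ids[bad_char], collapse = ", "))
    bad_len <- nchar(seqs) %% 3L != 0L | nchar(seqs) == 0L
    if (any(bad_len)) {
        if (strict)
            stop("sequence length not a positive multiple of 3: ",
                 paste(ids[bad_len], collapse = ", "))
        warning("dropping ", sum(bad_len),
                " record(s) whose length is not a positive multiple of 3: ",
                paste(ids[bad_len], collapse = ", "))
        seqs <- seqs[!bad_len]
        ids <- ids[!bad_len]
    }
    if (strict) {
        aa <- lapply(seqs, function(s) {
            cods <- splitCodons(s)
            ncod <- length(cods)
            any(cods[-ncod] %in% stopCodons())
        })
        internal <- vapply(aa, isTRUE, logical(1))
        if (any(internal))
            stop("internal stop codon in record(s): ",
                 paste(ids[internal], collapse = ", "))
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    out
}

#' Read codon-resolution ribosome footprint-count profiles
#'
#' The profile dialect is a TSV with header \code{gene_id<TAB>counts}, where
#' \code{counts} is a comma-separated list of non-negative decimal numbers,
#' one per codon position. Row order is preserved; duplicate gene ids and
#' negative counts are errors.
#'
#' @param path profiles TSV.
#' @param ntInput logical; if TRUE the counts are per-nucleotide and are
#'   summed over non-overlapping triplets into codon counts (the length must
#'   then be a multiple of 3).
#' @return Named list of numeric vectors, one per gene, input order.
#' @export
readProfiles <- function(path, ntInput = FALSE) {
    if (!file.exists(path)) stop("profiles file not found: ", path)
    tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                             comment.char = "#", check.names = FALSE)
    if (!all(c("gene_id", "counts") %in% names(tab)))
        stop("profiles TSV must have header 'gene_id<TAB>counts'")
    if (anyDuplicated(tab$gene_id))
        stop("duplicate gene_id in profiles: ",
             paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
    counts <- lapply(seq_len(nrow(tab)), function(i) {
        field <- tab$counts[i]
        if (is.na(field) || !nzchar(trimws(field)))
            stop("empty counts field for gene ", tab$gene_id[i])
        x <- suppressWarnings(as.numeric(strsplit(field, ",", fixed = TRUE)[[1]]))
        if (anyNA(x))
            stop("non-numeric count for gene ", tab$gene_id[i])
        if (any(x < 0))
            stop("negative count for gene ", tab$gene_id[i])
        x
    })
    names(counts) <- tab$gene_id
    if (ntInput) counts <- lapply(counts, ntToCodonCounts)
    counts
}

#' Sum per-nucleotide counts into codon counts
#'
#' Convenience for pipelines that emit per-nucleotide coverage: sums each
#' non-overlapping triplet. How upstream pipelines assign reads to codons
#' varies (full-footprint coverage vs. a single inferred A-site position);
#' this helper uses the sum-of-triplet convention.
#'
#' @param x numeric vector of per-nucleotide counts; length must be a
#'   multiple of 3.
#' @return numeric vector of codon counts, length \code{length(x)/3}.
#' @export
ntToCodonCounts <- function(x) {
    if (length(x) %% 3L != 0L)
        stop("nucleotide profile length ", length(x),
             " is not a multiple of 3")
    as.vector(tapply(x, rep(seq_len(length(x) / 3L), each = 3L), sum))
}

#' Read a two-column expression table
#'
#' Reads per-gene positive measurements (protein abundance, mRNA level, or
#' mean read count) from a TSV \code{gene_id<TAB>value}. Rows whose value is
#' non-numeric or non-positive are dropped, with the dropped count reported
#' via \code{message}.
#'
#' @param path expression TSV.
#' @return Named numeric vector of positive values.
#' @export
readExpressionTable <- function(path) {
    if (!file.exists(path)) stop("expression file not found: ", path)
    tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                             comment.char = "#", check.names = FALSE)
    if (ncol(tab) < 2L) stop("expression TSV must have two columns")
    vals <- suppressWarnings(as.numeric(tab[[2L]]))
    keep <- !is.na(vals) & vals > 0
    if (any(!keep))
        message("readExpressionTable: dropped ", sum(!keep),
                " row(s) with non-positive or non-numeric values")
    stats::setNames(vals[keep], tab[[1L]][keep])
}

## Shared TSV writer: `#` metadata comment lines, then header + data.
## Values serialized at 12 significant digits so tables round-trip to well
## under 1e-9 relative error.
writeCommentedTsv <- function(df, path, metadata = list()) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (k in names(metadata))
        writeLines(sprintf("# %s=%s", k,
                           paste(format(metadata[[k]]), collapse = ",")), con)
    fmt <- df
    num <- vapply(fmt, is.numeric, logical(1))
    fmt[num] <- lapply(fmt[num], function(v) formatC(v, digits = 12,
                                                     format = "g"))
    utils::write.table(fmt, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(NULL)
}

#' Write and read a decoding-rate table
#'
#' Fixed column order: codon, mu, sigma, lambda, inv_lambda, rate, n_samples,
#' converged. Metadata (run label, config hash, seed) is carried in leading
#' \code{#} comment lines. Values round-trip losslessly at 12 significant
#' digits.
#'
#' @param x a \linkS4class{DecodingRateTable}.
#' @param path output/input TSV path.
#' @return \code{readDecodingTable} returns a \linkS4class{DecodingRateTable}.
#' @export
writeDecodingTable <- function(x, path) {
    stopifnot(is(x, "DecodingRateTable"))
    writeCommentedTsv(x@table, path, x@metadata)
}

#' @rdname writeDecodingTable
#' @export
readDecodingTable <- function(path) {
    if (!file.exists(path)) stop("decoding table not found: ", path)
    meta <- readTsvMetadata(path)
    tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                             check.names = FALSE,
                             colClasses = c(codon = "character"))
    tab$converged <- as.logical(tab$converged)
    ## rate is derived; recompute so it matches 1/mu exactly after the
    ## 12-digit serialization
    tab$rate <- 1 / tab$mu
    new("DecodingRateTable", table = tab, metadata = meta)
}

readTsvMetadata <- function(path) {
    lines <- readLines(path, n = 50L)
    lines <- lines[startsWith(lines, "# ")]
    if (!length(lines)) return(list())
    kv <- strsplit(sub("^# ", "", lines), "=", fixed = TRUE)
    stats::setNames(lapply(kv, function(p) paste(p[-1L], collapse = "=")),
                    vapply(kv, `[`, character(1), 1L))
}

#' Write and read MTDR score tables
#'
#' Fixed column order: gene_id, mtdr, n_used, n_skipped, note. An empty
#' score set writes a header-only file.
#'
#' @param scores data.frame as returned by \code{\link{scoreMtdr}}.
#' @param path output/input TSV path.
#' @param metadata named list written as \code{#} comment lines.
#' @return \code{readMtdrScores} returns the scores data.frame.
#' @export
writeMtdrScores <- function(scores, path, metadata = list()) {
    need <- c("gene_id", "mtdr", "n_used", "n_skipped", "note")
    stopifnot(all(need %in% names(scores)))
    writeCommentedTsv(scores[need], path, metadata)
}

#' @rdname writeMtdrScores
#' @export
readMtdrScores <- function(path) {
    if (!file.exists(path)) stop("scores file not found: ", path)
    utils::read.delim(path, header = TRUE, comment.char = "#",
                      check.names = FALSE,
                      colClasses = c(gene_id = "character", note = "character"))
}

#' Write ORFs to FASTA
#'
#' @param orfs a \link[Biostrings]{DNAStringSet}.
#' @param path output FASTA path.
#' @export
writeOrfFasta <- function(orfs, path) {
    Biostrings::writeXStringSet(orfs, path)
    invisible(NULL)
}

#' Write codon-resolution profiles in the package's TSV dialect
#'
#' @param profiles named list of numeric count vectors.
#' @param path output TSV path.
#' @param metadata named list written as \code{#} comment lines.
#' @export
writeProfiles <- function(profiles, path, metadata = list()) {
    df <- data.frame(
        gene_id = names(profiles),
        counts = vapply(profiles, function(v)
            paste(formatC(v, digits = 12, format = "g"), collapse = ","),
            character(1)),
        stringsAsFactors = FALSE)
    writeCommentedTsv(df, path, metadata)
}
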