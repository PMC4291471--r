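## Shared fixture builders; everything is generated in code at test time.

## Write a FASTA string to a temp file, return its path.
tmpFasta <- function(lines) {
    path <- tempfile(fileext = ".fa")
    writeLines(lines, path)
    path
}

## Write a profiles TSV (gene_id<TAB>counts) to a temp file.
tmpProfilesTsv <- function(rows) {
    path <- tempfile(fileext = ".tsv")
    writeLines(c("gene_id\tcounts", rows), path)
    path
}

tmpExpressionTsv <- function(rows) {
    path <- tempfile(fileext = ".tsv")
    writeLines(c("gene_id\tvalue", rows), path)
    path
}

## Named DNAStringSet from a character vector.
orfSet <- function(seqs) {
    out <- Biostrings::DNAStringSet(seqs)
    if (is.null(names(seqs)))
        names(out) <- sprintf("g%d", seq_along(seqs))
    else names(out) <- names(seqs)
    out
}

## A small simulation config that keeps unit tests fast; acceptance tests
## use the package defaults instead.
smallSimConfig <- function(seed = 1L, ...) {
    simConfig(nGenes = 30L, lengthRange = c(60L, 120L), dropoutD0 = Inf,
              ramp = 1, seed = seed, ...)
}

## Textbook Pearson sum formula (independent of stats::cor's internals).
brutePearson <- function(a, b) {
    ma <- mean(a); mb <- mean(b)
    sum((a - ma) * (b - mb)) / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

## Brute-force Spearman oracle: average ranks, then Pearson.
bruteSpearman <- function(x, y) brutePearson(rank(x), rank(y))

## Brute-force partial Spearman oracle: Pearson of the OLS
## residuals-of-ranks after regressing each on rank(z).
brutePartialSpearman <- function(x, y, z) {
    rx <- rank(x); ry <- rank(y); rz <- rank(z)
    brutePearson(residuals(lm(rx ~ rz)), residuals(lm(ry ~ rz)))
}
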