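## stats_validation module: the validation statistics used to benchmark the
## MTDR index - Spearman and partial Spearman correlation, the
## protein-abundance regression with coefficient confidence intervals, the
## held-out ribosomal-load protocol, and condition-comparison tests.

correlationResult <- function(rho, p, n, kind, ok = TRUE,
                              note = "") {
    structure(list(rho = rho, p = p, n = n, kind = kind, ok = ok,
                   note = note),
              class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
    cat(sprintf("%s correlation: rho = %.4g, p = %.3g, n = %d%s\n",
                x$kind, x$rho, x$p, x$n,
                if (x$ok) "" else paste0(" [", x$note, "]")))
    invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data, with a two-sided p-value
#' from the t approximation \code{t = rho * sqrt((n-2)/(1-rho^2))} on
#' \code{n - 2} degrees of freedom. Pairs with missing values are dropped.
#' A constant input vector leaves rho undefined (flagged, not an error).
#'
#' @param x,y paired numeric vectors.
#' @return A \code{CorrelationResult}: list(rho, p, n, kind, ok, note).
#' @export
#' @examples
#' spearmanCor(1:5, c(2, 1, 4, 3, 5))$rho
spearmanCor <- function(x, y) {
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n < 3L) stop("need at least 3 complete pairs")
    rx <- rank(x); ry <- rank(y)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
        return(correlationResult(NA_real_, NA_real_, n, "spearman",
                                 ok = FALSE, note = "constant input"))
    rho <- stats::cor(rx, ry)
    p <- spearmanPvalue(rho, n, df = n - 2L)
    correlationResult(rho, p, n, "spearman")
}

spearmanPvalue <- function(rho, n, df) {
    if (abs(rho) >= 1) return(0)
    tstat <- rho * sqrt(df / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = df)
}

#' Partial Spearman correlation
#'
#' Rank-transforms all three vectors and applies the first-order partial
#' Pearson formula
#' \code{(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))}; the p-value
#' uses the t approximation on \code{n - 3} degrees of freedom. When x or y
#' is (anti)perfectly rank-correlated with z the partial correlation is
#' undefined and the result is flagged.
#'
#' @param x,y,z paired numeric vectors; complete triples only are used.
#' @return A \code{CorrelationResult} of kind \code{"partial_spearman"}.
#' @export
partialSpearman <- function(x, y, z) {
    keep <- is.finite(x) & is.finite(y) & is.finite(z)
    x <- x[keep]; y <- y[keep]; z <- z[keep]
    n <- length(x)
    if (n < 4L) stop("need at least 4 complete triples")
    rx <- rank(x); ry <- rank(y); rz <- rank(z)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0 || stats::sd(rz) == 0)
        return(correlationResult(NA_real_, NA_real_, n, "partial_spearman",
                                 ok = FALSE, note = "constant input"))
    rxy <- stats::cor(rx, ry)
    rxz <- stats::cor(rx, rz)
    ryz <- stats::cor(ry, rz)
    if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
        return(correlationResult(NA_real_, NA_real_, n, "partial_spearman",
                                 ok = FALSE,
                                 note = "perfect rank correlation with z"))
    rho <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    p <- spearmanPvalue(rho, n, df = n - 3L)
    correlationResult(rho, p, n, "partial_spearman")
}

#' Linear regression of protein abundance on three efficiency indexes
#'
#' Ordinary least squares fit of
#' \code{PA = c + w1 * MTDR + w2 * tAI + w3 * CAI}, with 95\% confidence
#' intervals on each coefficient from the t distribution on \code{n - 4}
#' degrees of freedom. A coefficient whose interval excludes zero
#' contributes significantly to the prediction.
#'
#' @param pa protein abundance vector (response).
#' @param mtdr,tai,cai predictor vectors.
#' @param level confidence level (default 0.95).
#' @return list(coefficients, ci95 (matrix low/high), contributes (logical),
#'   n, r2).
#' @export
fitPaRegression <- function(pa, mtdr, tai, cai, level = 0.95) {
    df <- data.frame(pa = pa, mtdr = mtdr, tai = tai, cai = cai)
    df <- df[stats::complete.cases(df) &
             apply(is.finite(as.matrix(df)), 1L, all), ]
    n <- nrow(df)
    if (n <= 10L) stop("need more than 10 complete cases, got ", n)
    X <- cbind(1, df$mtdr, df$tai, df$cai)
    qrX <- qr(X)
    if (qrX$rank < 4L) {
        kap <- kappa(X, exact = TRUE)
        stop("rank-deficient design (rank ", qrX$rank,
             ", condition number ", format(kap, digits = 4), ")")
    }
    fit <- stats::lm(pa ~ mtdr + tai + cai, data = df)
    coefs <- stats::coef(fit)
    names(coefs) <- c("c", "w1", "w2", "w3")
    ci <- stats::confint(fit, level = level)
    rownames(ci) <- names(coefs)
    colnames(ci) <- c("low", "high")
    contributes <- ci[, "low"] > 0 | ci[, "high"] < 0
    list(coefficients = coefs, ci95 = ci, contributes = contributes,
         n = n, r2 = summary(fit)$r.squared)
}

#' Held-out ribosomal-load prediction
#'
#' Splits the genes passing the coverage filter ("highly expressed" genes,
#' the estimation population) into two random halves under a fixed seed,
#' estimates the typical codon decoding times on half A, scores the half-B
#' ORFs with the resulting rate table, and returns the Spearman correlation
#' between the half-B MTDR indexes and their observed mean footprint counts
#' (ribosomal load). A positive correlation shows the index predicts
#' ribosome load on genes it never saw.
#'
#' @param profiles named list of codon-resolution count vectors.
#' @param orfs a \link[Biostrings]{DNAStringSet}.
#' @param cfg a \code{\link{filterConfig}}.
#' @param splitSeed integer seed for the 50/50 split (recorded in output).
#' @param minGenes minimum genes per half (default 10).
#' @param ... further arguments to \code{\link{fitEmg}}.
#' @return list(correlation = CorrelationResult, splitSeed, nA, nB,
#'   scores = half-B score data.frame with mean_fc column).
#' @export
ribosomalLoadValidation <- function(profiles, orfs, cfg = filterConfig(),
                                    splitSeed = 1L, minGenes = 10L, ...) {
    flt <- filterGenes(profiles, cfg)
    ids <- names(flt$kept)
    if (length(ids) < 2L * minGenes)
        stop("need at least ", 2L * minGenes,
             " genes passing the filter, got ", length(ids))
    half <- withSeed(splitSeed,
                     sample(ids, size = floor(length(ids) / 2)))
    idsA <- half
    idsB <- setdiff(ids, half)
    est <- estimateDecodingRates(profiles[idsA],
                                 orfs[names(orfs) %in% idsA], cfg,
                                 label = "split-A", ...)
    orfB <- orfs[names(orfs) %in% idsB]
    scores <- scoreMtdr(orfB, est$table, policy = "skip")
    meanFc <- vapply(profiles[scores$gene_id], mean, numeric(1))
    scores$mean_fc <- unname(meanFc)
    ok <- is.finite(scores$mtdr) & is.finite(scores$mean_fc)
    corr <- spearmanCor(scores$mtdr[ok], scores$mean_fc[ok])
    list(correlation = corr, splitSeed = splitSeed,
         nA = length(idsA), nB = length(idsB), scores = scores)
}

#' Compare MTDR between two experimental conditions
#'
#' Given per-gene MTDR scores and ribosomal loads (mean footprint counts)
#' under two conditions, computes on the shared genes: the Spearman
#' correlation between the per-gene MTDR ratio and the load ratio, and
#' two-sample t and Wilcoxon rank-sum tests comparing the MTDR ratios of
#' the genes in the top vs. bottom \code{q} quantile of the load ratio.
#'
#' @param scoresA,scoresB named numeric vectors of positive MTDR values.
#' @param loadA,loadB named numeric vectors of positive ribosomal loads.
#' @param q quantile fraction defining the top/bottom groups (default 0.30).
#' @return list(ratio_correlation = CorrelationResult, t_p, wilcoxon_p,
#'   n, top_ids, bottom_ids).
#' @export
conditionComparison <- function(scoresA, scoresB, loadA, loadB, q = 0.30) {
    ids <- Reduce(intersect, list(names(scoresA), names(scoresB),
                                  names(loadA), names(loadB)))
    vals <- cbind(scoresA[ids], scoresB[ids], loadA[ids], loadB[ids])
    ids <- ids[apply(is.finite(vals) & vals > 0, 1L, all)]
    if (length(ids) < 10L)
        stop("need at least 10 shared genes with positive values, got ",
             length(ids))
    mr <- scoresA[ids] / scoresB[ids]
    lr <- loadA[ids] / loadB[ids]
    corr <- if (stats::sd(mr) == 0 || stats::sd(lr) == 0)
        correlationResult(NA_real_, NA_real_, length(ids), "spearman",
                          ok = FALSE, note = "degenerate ratios")
    else spearmanCor(mr, lr)
    ord <- order(lr)
    k <- max(1L, floor(q * length(ids)))
    bottom <- ids[ord[seq_len(k)]]
    top <- ids[ord[seq.int(length(ids) - k + 1L, length(ids))]]
    if (stats::sd(c(mr[top], mr[bottom])) == 0) {
        ## identical groups: no evidence of any difference
        tp <- 1
        wp <- 1
    } else {
        tp <- tryCatch(stats::t.test(mr[top], mr[bottom])$p.value,
                       error = function(e) NA_real_)
        wp <- tryCatch(suppressWarnings(
            stats::wilcox.test(mr[top], mr[bottom], correct = TRUE)$p.value),
            error = function(e) NA_real_)
    }
    list(ratio_correlation = corr, t_p = tp, wilcoxon_p = wp,
         n = length(ids), top_ids = top, bottom_ids = bottom)
}

#' Benjamini-Hochberg adjustment helper
#'
#' Raw p-values are reported throughout the package (matching the
#' validation protocols); this optional helper wraps
#' \code{stats::p.adjust(method = "BH")} for users who want FDR control.
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
adjustBH <- function(p) stats::p.adjust(p, method = "BH")
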