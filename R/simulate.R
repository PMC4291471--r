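## synthetic_data module: ORF and ribosome-profile generator with the exact
## statistical structure the estimator assumes, so every pipeline stage is
## testable without external downloads.
##
## Per gene: a sequencing depth d is drawn from a log-normal (real Ribo-seq
## libraries put most genes at very low coverage); per codon position the
## count is d times a positive EMG draw under that codon's true parameters;
## the first `rampLen` codons carry a multiplicative initiation-proximal
## excess; positions are zeroed (dropout) with probability exp(-d/d0),
## reproducing depth-dependent sparsity. All outputs are pure functions of
## (config, seed).

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: 200 genes of
#' 200-400 codons, 61 distinct true typical decoding times equally spaced
#' on [0.1, 1.0] NFC units, normal s.d. proportional to the time (25\% CV),
#' a common pause rate lambda = 3 (mean pause contribution 1/3), log-normal
#' per-gene depth (meanlog log(10), sdlog 1), depth-dependent dropout scale
#' d0 = 4, and a 1.3x ramp over the first 20 codons.
#'
#' @param nGenes number of genes.
#' @param lengthRange integer 2-vector, codon-count range (stop excluded).
#' @param codonUsage named probability vector over the 61 sense codons
#'   (default uniform).
#' @param trueMu named vector of true typical decoding times per codon
#'   (default \code{seq(0.1, 1, length.out = 61)} assigned in sense-codon
#'   order).
#' @param trueSigma named vector of normal s.d. per codon (default
#'   \code{0.25 * trueMu}).
#' @param trueLambda named vector of exponential rates (default 3).
#' @param depthMeanlog,depthSdlog log-normal parameters of per-gene mean
#'   depth.
#' @param dropoutD0 depth scale of the dropout probability
#'   \code{exp(-d/d0)}; \code{Inf} disables dropout.
#' @param ramp multiplicative count excess over the first \code{rampLen}
#'   codons.
#' @param rampLen codons affected by the ramp (default 20).
#' @param usageBias strength of per-gene codon-usage bias toward fast
#'   codons: each gene draws an adaptation exponent b ~ Uniform(0,
#'   usageBias) and samples codons with probability proportional to
#'   \code{codonUsage * (1/trueMu)^b}. Models the gene-to-gene codon usage
#'   bias found in real genomes (the signal CAI measures); 0 disables it.
#' @param loadCoupling translational-selection coupling between a gene's
#'   speed and its expression: the gene's depth is multiplied by
#'   \code{exp(loadCoupling * (log trueMTDR - mean log trueMTDR))}. Models
#'   selection of highly translated genes for fast codons, the mechanism
#'   behind the positive MTDR/ribosomal-load correlation; 0 disables it.
#' @param seed integer master seed.
#' @return A validated \code{SimConfig} list.
#' @export
simConfig <- function(nGenes = 200L, lengthRange = c(200L, 400L),
                      codonUsage = NULL, trueMu = NULL, trueSigma = NULL,
                      trueLambda = NULL, depthMeanlog = log(10),
                      depthSdlog = 1, dropoutD0 = 4, ramp = 1.3,
                      rampLen = 20L, usageBias = 1, loadCoupling = 2,
                      seed = 1L) {
    sense <- senseCodons()
    if (is.null(codonUsage))
        codonUsage <- stats::setNames(rep(1 / 61, 61L), sense)
    if (is.null(trueMu))
        trueMu <- stats::setNames(seq(0.1, 1, length.out = 61L), sense)
    if (is.null(trueSigma)) trueSigma <- 0.25 * trueMu
    if (is.null(trueLambda))
        trueLambda <- stats::setNames(rep(3, length(trueMu)), names(trueMu))
    stopifnot(nGenes >= 1, length(lengthRange) == 2L,
              lengthRange[1L] >= 1, lengthRange[2L] >= lengthRange[1L],
              abs(sum(codonUsage) - 1) < 1e-8,
              all(names(codonUsage) %in% sense),
              all(trueMu > 0), all(trueSigma > 0), all(trueLambda > 0),
              dropoutD0 > 0, ramp > 0, rampLen >= 0, usageBias >= 0,
              is.finite(loadCoupling))
    structure(list(nGenes = as.integer(nGenes),
                   lengthRange = as.integer(lengthRange),
                   codonUsage = codonUsage, trueMu = trueMu,
                   trueSigma = trueSigma, trueLambda = trueLambda,
                   depthMeanlog = depthMeanlog, depthSdlog = depthSdlog,
                   dropoutD0 = dropoutD0, ramp = ramp,
                   rampLen = as.integer(rampLen), usageBias = usageBias,
                   loadCoupling = loadCoupling,
                   seed = as.integer(seed)),
              class = "SimConfig")
}

#' Simulate ORF sequences
#'
#' Gene lengths are uniform on \code{lengthRange}; codons are i.i.d. draws
#' from \code{codonUsage}; a terminal TAA stop is appended. Deterministic
#' under \code{cfg$seed} (offset by \code{seedOffset} to obtain independent
#' but reproducible sets, e.g. held-out ORFs).
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param nGenes override for the number of ORFs (default \code{cfg$nGenes}).
#' @param seedOffset integer added to the master seed.
#' @param prefix gene-id prefix.
#' @return A named \link[Biostrings]{DNAStringSet}.
#' @export
simulateOrfs <- function(cfg = simConfig(), nGenes = cfg$nGenes,
                         seedOffset = 0L, prefix = "g") {
    withSeed(cfg$seed + seedOffset, {
        lenPool <- seq.int(cfg$lengthRange[1L], cfg$lengthRange[2L])
        lens <- lenPool[sample.int(length(lenPool), nGenes,
                                   replace = TRUE)]
        rate <- 1 / cfg$trueMu[names(cfg$codonUsage)]
        b <- if (cfg$usageBias > 0)
            stats::runif(nGenes, 0, cfg$usageBias) else numeric(nGenes)
        seqs <- vapply(seq_len(nGenes), function(i) {
            usage <- cfg$codonUsage * rate^b[i]
            paste0(paste(sample(names(cfg$codonUsage), lens[i],
                                replace = TRUE, prob = usage),
                         collapse = ""),
                   "TAA")
        }, character(1))
        out <- Biostrings::DNAStringSet(seqs)
        names(out) <- sprintf("%s%04d", prefix, seq_len(nGenes))
        out
    })
}

## Positive EMG draw: rejection sampling at 0 (counts cannot be negative).
## Mildly biases the smallest-mu codons upward; accounted for in the
## package's documented recovery expectations.
rEmgPositive <- function(n, mu, sigma, lambda, eps = 1e-9) {
    x <- remg(n, mu, sigma, lambda)
    bad <- which(x <= 0)
    guard <- 0L
    while (length(bad)) {
        x[bad] <- remg(length(bad), mu, sigma, lambda)
        bad <- bad[x[bad] <= 0]
        guard <- guard + 1L
        if (guard > 1000L) {   # pathological parameters; floor instead
            x[bad] <- eps
            break
        }
    }
    pmax(x, eps)
}

#' Simulate codon-resolution ribosome profiles for given ORFs
#'
#' See the module description: depth times positive EMG draw per position,
#' ramp on the first codons, depth-dependent dropout. The terminal stop
#' codon gets a zero count (stop codons are not decoded).
#'
#' @param orfs a named \link[Biostrings]{DNAStringSet}.
#' @param cfg a \code{\link{simConfig}} providing the true parameters.
#' @param seedOffset integer added to the master seed.
#' @return Named list of numeric count vectors (one per codon position).
#' @export
simulateProfiles <- function(orfs, cfg = simConfig(), seedOffset = 1L) {
    seqs <- as.character(orfs)
    ## translational selection: depth multiplied by the gene's true speed
    ## (centered in log space so the overall depth scale is unchanged)
    speedFactor <- rep(1, length(seqs))
    if (cfg$loadCoupling != 0) {
        trueTab <- rateTableFromTimes(cfg$trueMu)
        trueMtdr <- scoreMtdr(orfs, trueTab, policy = "skip")$mtdr
        lm0 <- base::log(trueMtdr) - mean(base::log(trueMtdr))
        speedFactor <- exp(cfg$loadCoupling * lm0)
    }
    withSeed(cfg$seed + seedOffset, {
        depths <- speedFactor *
            stats::rlnorm(length(seqs), meanlog = cfg$depthMeanlog,
                          sdlog = cfg$depthSdlog)
        profiles <- vector("list", length(seqs))
        for (i in seq_along(seqs)) {
            cods <- splitCodons(seqs[[i]])
            counts <- numeric(length(cods))
            sense <- !cods %in% stopCodons()
            missing <- setdiff(unique(cods[sense]), names(cfg$trueMu))
            if (length(missing))
                stop("no true parameters for codon(s): ",
                     paste(missing, collapse = ", "))
            for (cc in unique(cods[sense])) {
                at <- which(cods == cc)
                counts[at] <- depths[i] *
                    rEmgPositive(length(at), cfg$trueMu[[cc]],
                                 cfg$trueSigma[[cc]], cfg$trueLambda[[cc]])
            }
            if (cfg$rampLen > 0L) {
                rampIdx <- seq_len(min(cfg$rampLen, length(counts)))
                counts[rampIdx] <- counts[rampIdx] * cfg$ramp
            }
            if (is.finite(cfg$dropoutD0)) {
                pDrop <- exp(-depths[i] / cfg$dropoutD0)
                drop <- stats::runif(length(counts)) < pDrop
                counts[drop] <- 0
            }
            profiles[[i]] <- counts
        }
        stats::setNames(profiles, names(orfs))
    })
}

#' End-to-end parameter and index recovery on synthetic data
#'
#' The package's own benchmark harness: simulates ORFs and profiles under
#' \code{cfg}, runs preprocessing and per-codon EMG fitting, and compares
#' the estimated typical decoding times against the generating truth; then
#' simulates \code{nHeldOut} fresh ORFs and compares their MTDR indexes
#' under the estimated rate table against the true-parameter table.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param filterCfg a \code{\link{filterConfig}}.
#' @param nHeldOut held-out ORFs for the index-level comparison.
#' @param ... further arguments to \code{\link{fitEmg}}.
#' @return list with elements \code{perCodon} (data.frame codon, true_mu,
#'   est_mu, n_samples, converged), \code{muSpearman}, \code{mtdrSpearman}
#'   (CorrelationResults), \code{nFitted}, \code{table}, \code{heldOut}
#'   (score data.frame with true and estimated MTDR).
#' @export
endToEndRecovery <- function(cfg = simConfig(), filterCfg = filterConfig(),
                             nHeldOut = 100L, ...) {
    orfs <- simulateOrfs(cfg)
    profiles <- simulateProfiles(orfs, cfg)
    est <- estimateDecodingRates(profiles, orfs, filterCfg,
                                 label = "synthetic", seed = cfg$seed, ...)
    estMu <- decodingTimes(est$table)
    perCodon <- data.frame(
        codon = names(estMu),
        true_mu = unname(cfg$trueMu[names(estMu)]),
        est_mu = unname(estMu),
        n_samples = est$table@table$n_samples,
        converged = est$table@table$converged,
        stringsAsFactors = FALSE)
    muSp <- spearmanCor(perCodon$true_mu, perCodon$est_mu)
    heldOrfs <- simulateOrfs(cfg, nGenes = nHeldOut, seedOffset = 2L,
                             prefix = "h")
    trueTable <- rateTableFromTimes(cfg$trueMu,
                                    metadata = list(label = "truth"))
    scoresEst <- scoreMtdr(heldOrfs, est$table, policy = "skip")
    scoresTrue <- scoreMtdr(heldOrfs, trueTable, policy = "strict")
    held <- data.frame(gene_id = scoresEst$gene_id,
                       mtdr_est = scoresEst$mtdr,
                       mtdr_true = scoresTrue$mtdr,
                       stringsAsFactors = FALSE)
    mtdrSp <- spearmanCor(held$mtdr_true, held$mtdr_est)
    list(perCodon = perCodon, muSpearman = muSp, mtdrSpearman = mtdrSp,
         nFitted = nrow(perCodon), table = est$table, heldOut = held,
         nfc = est$nfc)
}

#' Write a full synthetic data set to disk
#'
#' FASTA + profiles TSV + true-parameter TSV, with seed and config hash in
#' the TSV headers.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param outPrefix path prefix for \code{<prefix>.fa},
#'   \code{<prefix>_profiles.tsv}, \code{<prefix>_true_params.tsv}.
#' @return Invisibly, the three file paths.
#' @export
writeSimulation <- function(cfg = simConfig(), outPrefix = "sim") {
    orfs <- simulateOrfs(cfg)
    profiles <- simulateProfiles(orfs, cfg)
    meta <- list(seed = cfg$seed, config = configHash(cfg))
    faPath <- paste0(outPrefix, ".fa")
    prPath <- paste0(outPrefix, "_profiles.tsv")
    tpPath <- paste0(outPrefix, "_true_params.tsv")
    writeOrfFasta(orfs, faPath)
    writeProfiles(profiles, prPath, meta)
    writeCommentedTsv(data.frame(codon = names(cfg$trueMu),
                                 mu = unname(cfg$trueMu),
                                 sigma = unname(cfg$trueSigma),
                                 lambda = unname(cfg$trueLambda),
                                 stringsAsFactors = FALSE),
                      tpPath, meta)
    invisible(c(fasta = faPath, profiles = prPath, trueParams = tpPath))
}
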