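test_that("ORF simulation is deterministic and follows codon usage", {
    cfg <- smallSimConfig(seed = 4)
    a <- simulateOrfs(cfg)
    b <- simulateOrfs(cfg)
    expect_identical(as.character(a), as.character(b))

    ## concentrated usage gives poly-codon ORFs
    usage <- setNames(rep(0, 61), senseCodons())
    usage["AAA"] <- 1
    mono <- simulateOrfs(simConfig(nGenes = 3, lengthRange = c(5, 5),
                                   codonUsage = usage, seed = 1))
    expect_true(all(as.character(mono) == paste0(strrep("AAA", 5), "TAA")))

    ## empirical codon frequencies within multinomial bounds (per-gene
    ## usage bias off so the draw is exactly multinomial)
    cfg2 <- simConfig(nGenes = 120, lengthRange = c(280, 280),
                      usageBias = 0, loadCoupling = 0, seed = 8)
    orfs <- simulateOrfs(cfg2)
    cods <- unlist(lapply(as.character(orfs), function(s)
        substring(s, seq(1, nchar(s) - 3, 3), seq(3, nchar(s) - 3, 3))))
    n <- length(cods)
    freq <- table(factor(cods, levels = senseCodons())) / n
    p <- cfg2$codonUsage[senseCodons()]
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(freq - p) < 3.5 * se))
})

test_that("profile counts scale with depth and match the EMG mean", {
    ## dropout off, ramp off, single long gene: mean(count/d) ~ mu + 1/lambda
    usage <- setNames(rep(0, 61), senseCodons())
    usage[c("AAA", "GGG")] <- 0.5
    cfg <- simConfig(nGenes = 4, lengthRange = c(2500, 2500),
                     codonUsage = usage, dropoutD0 = Inf, ramp = 1,
                     depthMeanlog = log(50), depthSdlog = 0,
                     usageBias = 0, loadCoupling = 0, seed = 5)
    orfs <- simulateOrfs(cfg)
    profiles <- simulateProfiles(orfs, cfg)
    cods <- substring(as.character(orfs[[1]]), seq(1, 7500, 3),
                      seq(3, 7500, 3))
    all_counts <- unlist(profiles)
    all_cods <- unlist(lapply(as.character(orfs), function(s)
        substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))))
    for (cc in c("AAA", "GGG")) {
        m <- mean(all_counts[all_cods == cc]) / 50
        expect_equal(m, cfg$trueMu[[cc]] + 1 / cfg$trueLambda[[cc]],
                     tolerance = 0.02)
    }
})

test_that("profiles are bit-identical under the same seed", {
    cfg <- smallSimConfig(seed = 6)
    orfs <- simulateOrfs(cfg)
    expect_identical(simulateProfiles(orfs, cfg),
                     simulateProfiles(orfs, cfg))
    ## unknown codon parameters are an error
    cfg2 <- cfg
    cfg2$trueMu <- cfg$trueMu[1:5]
    expect_error(simulateProfiles(orfs, cfg2), "no true parameters")
})

test_that("dropout increases as depth decreases", {
    cfg <- function(d) simConfig(nGenes = 40, lengthRange = c(100, 100),
                                 depthMeanlog = log(d), depthSdlog = 0,
                                 dropoutD0 = 4, ramp = 1, usageBias = 0,
                                 loadCoupling = 0, seed = 9)
    zeroFrac <- function(cf) {
        orfs <- simulateOrfs(cf)
        mean(unlist(simulateProfiles(orfs, cf)) == 0)
    }
    fractions <- vapply(c(1, 4, 16), function(d) zeroFrac(cfg(d)),
                        numeric(1))
    expect_true(all(diff(fractions) < 0))
})

test_that("uniformly shallow libraries leave nothing to analyze", {
    cfg <- simConfig(nGenes = 20, lengthRange = c(80, 100),
                     depthMeanlog = log(0.05), depthSdlog = 0.01,
                     dropoutD0 = 0.5, seed = 10)
    orfs <- simulateOrfs(cfg)
    profiles <- simulateProfiles(orfs, cfg)
    kept <- filterGenes(profiles, filterConfig())
    expect_length(kept$kept, 0)
})

test_that("ramp inflates only the first codons and trimming removes it", {
    usage <- setNames(rep(0, 61), senseCodons())
    usage["AAA"] <- 1
    mk <- function(ramp) simConfig(nGenes = 200, lengthRange = c(60, 60),
                                   codonUsage = usage, dropoutD0 = Inf,
                                   ramp = ramp, depthMeanlog = log(20),
                                   depthSdlog = 0, seed = 11)
    orfs <- simulateOrfs(mk(2))
    pr <- simulateProfiles(orfs, mk(2))
    m <- colMeans(do.call(rbind, pr))      # 61 positions incl. stop
    expect_gt(mean(m[1:20]) / mean(m[21:60]), 1.8)
    ## the standard 20-codon trim removes the whole ramp region
    trimmed <- trimProfile(pr[[1]], filterConfig())
    expect_length(trimmed, 21)
    expect_identical(trimmed, pr[[1]][21:41])
})

test_that("end-to-end recovery distinguishes null from signal", {
    ## all codons identical: estimated times nearly flat, MTDR variance ~ 0
    flat <- simConfig(nGenes = 60, lengthRange = c(150, 200),
                      trueMu = setNames(rep(0.4, 61), senseCodons()),
                      trueSigma = setNames(rep(0.1, 61), senseCodons()),
                      dropoutD0 = Inf, ramp = 1, depthMeanlog = log(20),
                      depthSdlog = 0.3, seed = 12)
    rep0 <- endToEndRecovery(flat, nHeldOut = 40L, minSamples = 100L)
    expect_lt(sd(rep0$perCodon$est_mu) / mean(rep0$perCodon$est_mu), 0.2)
    expect_lt(sd(rep0$heldOut$mtdr_est) / mean(rep0$heldOut$mtdr_est),
              0.05)
})

test_that("simulation files round-trip through the io layer", {
    cfg <- smallSimConfig(seed = 14)
    prefix <- file.path(tempdir(), "simtest")
    paths <- writeSimulation(cfg, prefix)
    orfs <- readOrfFasta(paths[["fasta"]])
    profiles <- readProfiles(paths[["profiles"]])
    expect_equal(length(orfs), cfg$nGenes)
    expect_equal(names(profiles), names(orfs))
    expect_equal(profiles, simulateProfiles(simulateOrfs(cfg), cfg),
                 tolerance = 1e-9)
})
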