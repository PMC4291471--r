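test_that("EMG density normalizes and matches its closed-form moments", {
    p <- EMGParams(mu = 0.2, sigma = 0.05, lambda = 5)
    total <- integrate(function(x) demg(x, p), -Inf, Inf,
                       rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
    m <- integrate(function(x) x * demg(x, p), -Inf, Inf,
                   rel.tol = 1e-10)$value
    v <- integrate(function(x) (x - m)^2 * demg(x, p), -Inf, Inf,
                   rel.tol = 1e-10)$value
    expect_equal(m, 0.2 + 1 / 5, tolerance = 1e-6)
    expect_equal(v, 0.05^2 + 1 / 25, tolerance = 1e-6)
})

test_that("EMG density approaches the normal density as lambda grows", {
    x <- c(-1, 0, 1)
    expect_equal(demg(x, mu = 0, sigma = 1, lambda = 1e6), dnorm(x),
                 tolerance = 1e-3)
})

test_that("stable log-density agrees with the naive erfc form", {
    ## naive closed form, usable only where erfc does not underflow
    naive <- function(x, mu, sigma, lambda) {
        (lambda / 2) * exp((lambda / 2) * (2 * mu + lambda * sigma^2 -
                                           2 * x)) *
            pracma::erfc((mu + lambda * sigma^2 - x) / (sqrt(2) * sigma))
    }
    x <- seq(-0.2, 1.5, length.out = 40)
    expect_equal(demg(x, 0.2, 0.1, 3), naive(x, 0.2, 0.1, 3),
                 tolerance = 1e-8)
    expect_equal(log(naive(x, 0.3, 0.05, 8)),
                 demg(x, 0.3, 0.05, 8, log = TRUE), tolerance = 1e-8)
})

test_that("log-likelihood is additive and matches the density", {
    p <- EMGParams(mu = 0.2, sigma = 0.05, lambda = 5)
    x0 <- 0.25
    expect_equal(emgLogLik(x0, p), demg(x0, p, log = TRUE))
    set.seed(3)
    x <- remg(50, p)
    expect_equal(emgLogLik(c(x, x), p), 2 * emgLogLik(x, p))
    expect_error(emgLogLik(numeric(0), p), "empty")
})

test_that("analytic likelihood gradient matches central differences", {
    set.seed(11)
    x <- remg(300, 0.2, 0.05, 5)
    for (theta in list(c(0.2, 0.05, 5), c(0.25, 0.08, 3.3),
                       c(0.05, 0.2, 12))) {
        an <- mtdr:::emgLogLikGrad(x, theta[1], theta[2], theta[3])
        h <- 1e-6
        fd <- vapply(1:3, function(i) {
            tp <- theta; tm <- theta
            tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
            (emgLogLik(x, EMGParams(mu = tp[1], sigma = tp[2],
                                    lambda = tp[3])) -
             emgLogLik(x, EMGParams(mu = tm[1], sigma = tm[2],
                                    lambda = tm[3]))) / (2 * h)
        }, numeric(1))
        expect_equal(unname(an), fd, tolerance = 1e-4)
    }
})

test_that("moment initialization is close on large clean samples", {
    set.seed(5)
    x <- remg(1e5, 0.2, 0.05, 5)
    init <- emgInitMoments(x)
    expect_lt(abs(emgMu(init) - 0.2) / 0.2, 0.15)
    expect_lt(abs(emgSigma(init) - 0.05) / 0.05, 0.15)
    expect_lt(abs(1 / emgLambda(init) - 0.2) / 0.2, 0.15)
})

test_that("moment initialization survives degenerate skewness", {
    set.seed(6)
    sym <- rnorm(500)                      # skewness ~ 0
    init <- emgInitMoments(sym)
    expect_gt(emgLambda(init), 1 / sd(sym))   # near-Gaussian start
    expect_equal(emgSigma(init), sd(sym), tolerance = 0.1)

    neg <- -rexp(500)                      # negative skew, clamped
    init2 <- emgInitMoments(neg)
    expect_true(is.finite(emgMu(init2)) && emgSigma(init2) > 0)
    expect_error(emgInitMoments(rep(1, 10)), "variance")
})

test_that("maximum-likelihood fit recovers generating parameters", {
    set.seed(7)
    x <- remg(10000, 0.20, 0.05, 5)
    fit <- fitEmg(x)
    expect_true(isConverged(fit))
    expect_equal(fitStatus(fit), "ok")
    expect_lt(abs(emgMu(fit) - 0.20), 0.01)
    expect_lt(abs(emgSigma(fit) - 0.05), 0.01)
    expect_lt(abs(1 / emgLambda(fit) - 0.2), 0.02)
    ## MLE dominance over the generating parameters on the same sample
    expect_gte(logLik(fit)[1],
               emgLogLik(x, EMGParams(mu = 0.2, sigma = 0.05,
                                      lambda = 5)) - 1e-6)
    ## and over its own moment start
    expect_gte(logLik(fit)[1], emgLogLik(x, fit@init) - 1e-9)
})

test_that("small samples yield unfit status without crashing", {
    fit <- fitEmg(rnorm(10))
    expect_equal(fitStatus(fit), "unfit")
    expect_false(isConverged(fit))
    expect_equal(nSamples(fit), 10L)
})

test_that("fitting is location- and scale-equivariant", {
    set.seed(8)
    x <- remg(5000, 0.2, 0.05, 5)
    base <- fitEmg(x)
    shift <- fitEmg(x + 1.7)
    expect_equal(emgMu(shift), emgMu(base) + 1.7, tolerance = 1e-6)
    expect_equal(emgSigma(shift), emgSigma(base), tolerance = 1e-6)
    expect_equal(emgLambda(shift), emgLambda(base), tolerance = 1e-6)
    k <- 3.5
    scaled <- fitEmg(k * x)
    expect_equal(emgMu(scaled) / (k * emgMu(base)), 1, tolerance = 1e-6)
    expect_equal(emgSigma(scaled) / (k * emgSigma(base)), 1,
                 tolerance = 1e-6)
    expect_equal(emgLambda(scaled) * k / emgLambda(base), 1,
                 tolerance = 1e-6)
})

test_that("fitAllCodons fits each bucket of an NFC table", {
    sim <- smallSimConfig(seed = 9)
    orfs <- simulateOrfs(sim)
    profiles <- simulateProfiles(orfs, sim)
    tab <- buildNfcTable(profiles, orfs,
                         filterConfig(trimStart = 5, trimEnd = 5))
    fits <- fitAllCodons(tab, minSamples = 20L)
    expect_equal(names(fits), codons(tab))
    expect_true(all(vapply(fits, nSamples, integer(1)) ==
                    lengths(nfcSamples(tab))))
})
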