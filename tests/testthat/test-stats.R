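test_that("Spearman correlation matches monotone expectations", {
    x <- c(0.5, 1, 2, 3.5, 7)
    expect_equal(spearmanCor(x, x^2)$rho, 1)       # monotone invariance
    expect_equal(spearmanCor(x, -x)$rho, -1)
    ## hand-rankable 5-point case, oracle-computed: sum d^2 = 4,
    ## rho = 1 - 6*4/(5*24) = 0.8
    r <- spearmanCor(1:5, c(2, 1, 4, 3, 5))
    expect_equal(r$rho, 0.8)
    expect_equal(r$rho, bruteSpearman(1:5, c(2, 1, 4, 3, 5)))
    ## constant vector flagged undefined, not an error
    flat <- spearmanCor(rep(1, 5), 1:5)
    expect_false(flat$ok)
    expect_true(is.na(flat$rho))
    expect_error(spearmanCor(1:2, 2:3), "at least 3")
})

test_that("Spearman agrees with brute force and cor.test across seeds", {
    set.seed(101)
    for (i in 1:50) {
        n <- sample(5:60, 1)
        x <- rnorm(n)
        y <- rnorm(n) + if (i %% 2) 0.5 * x else 0
        r <- spearmanCor(x, y)
        expect_equal(r$rho, bruteSpearman(x, y), tolerance = 1e-12)
        ## independent reference implementation
        expect_equal(r$rho,
                     unname(cor.test(x, y, method = "spearman",
                                     exact = FALSE)$estimate),
                     tolerance = 1e-12)
    }
    ## ties handled by average ranks
    x <- c(1, 1, 2, 3, 3, 4)
    y <- c(2, 1, 3, 3, 5, 6)
    expect_equal(spearmanCor(x, y)$rho, bruteSpearman(x, y),
                 tolerance = 1e-12)
})

test_that("partial Spearman equals the residual-of-ranks construction", {
    set.seed(7)
    for (i in 1:20) {
        n <- sample(6:50, 1)
        x <- rnorm(n); z <- rnorm(n)
        y <- 0.4 * x + 0.4 * z + rnorm(n)
        expect_equal(partialSpearman(x, y, z)$rho,
                     brutePartialSpearman(x, y, z), tolerance = 1e-12)
    }
    ## hand 6-point triple
    x <- c(3, 1, 4, 1.5, 9, 2.6)
    y <- c(2, 7, 1, 8, 2.8, 1.8)
    z <- c(1, 6, 1.8, 0.3, 3, 9)
    expect_equal(partialSpearman(x, y, z)$rho,
                 brutePartialSpearman(x, y, z), tolerance = 1e-12)
})

test_that("partial Spearman handles independence and degeneracy", {
    set.seed(9)
    n <- 10000
    x <- rnorm(n); y <- 0.5 * x + rnorm(n); z <- rnorm(n)
    ## z independent of (x, y): partial ~ plain Spearman
    expect_equal(partialSpearman(x, y, z)$rho, spearmanCor(x, y)$rho,
                 tolerance = 0.03)
    ## y perfectly rank-correlated with z: undefined, flagged
    deg <- partialSpearman(x, z, z)
    expect_false(deg$ok)
    expect_true(is.na(deg$rho))
})

test_that("PA regression recovers coefficients with honest intervals", {
    set.seed(21)
    n <- 300
    mtdrV <- runif(n, 1, 5)
    taiV <- runif(n, 0.2, 0.9)
    caiV <- runif(n, 0.2, 0.9)
    pa <- 2 + 3 * mtdrV + rnorm(n, sd = 0.5)
    reg <- fitPaRegression(pa, mtdrV, taiV, caiV)
    expect_true(reg$ci95["w1", "low"] < 3 && 3 < reg$ci95["w1", "high"])
    expect_true(reg$contributes[["w1"]])
    expect_false(reg$contributes[["w2"]])
    expect_false(reg$contributes[["w3"]])
    expect_true(reg$ci95["w2", "low"] < 0 && 0 < reg$ci95["w2", "high"])

    ## zero-noise limit: coefficients exact
    paExact <- 1.5 + 2 * mtdrV - 0.7 * taiV + 0.3 * caiV
    ## lm warns about the perfect fit; that is the point of the check
    regE <- suppressWarnings(fitPaRegression(paExact, mtdrV, taiV, caiV))
    expect_equal(unname(regE$coefficients), c(1.5, 2, -0.7, 0.3),
                 tolerance = 1e-8)
    expect_equal(regE$r2, 1, tolerance = 1e-8)

    ## duplicated predictor: rank-deficiency error
    expect_error(fitPaRegression(pa, mtdrV, mtdrV, caiV), "rank-deficient")
    expect_error(fitPaRegression(pa[1:5], mtdrV[1:5], taiV[1:5], caiV[1:5]),
                 "more than 10")
})

test_that("regression matches the closed-form two-predictor solution", {
    set.seed(33)
    n <- 60
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- 1 + 2 * x1 - 3 * x2 + rnorm(n)
    ## closed form via normal equations on [1, x1, x2, x3] with x3
    ## independent noise
    x3 <- rnorm(n)
    X <- cbind(1, x1, x2, x3)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    reg <- fitPaRegression(y, x1, x2, x3)
    expect_equal(unname(reg$coefficients), as.vector(beta),
                 tolerance = 1e-10)
})

test_that("condition comparison detects shifts and flags degeneracy", {
    set.seed(17)
    n <- 200
    ids <- sprintf("g%03d", 1:n)
    base <- setNames(runif(n, 1, 3), ids)
    load1 <- setNames(rlnorm(n, 1, 0.5), ids)
    ## condition B: half the genes speed up 2x, loads shift coherently
    speed <- setNames(rep(c(2, 1), each = n / 2) * rlnorm(n, 0, 0.05), ids)
    scoresB <- base * speed
    loadB <- load1 * speed^1.5 * rlnorm(n, 0, 0.2)
    cmp <- conditionComparison(scoresB, base, loadB, load1)
    expect_gt(cmp$ratio_correlation$rho, 0.5)
    expect_lt(cmp$t_p, 0.01)
    expect_lt(cmp$wilcoxon_p, 0.01)

    ## identical conditions: degenerate correlation, tests report p = 1
    same <- conditionComparison(base, base, load1, load1)
    expect_false(same$ratio_correlation$ok)
    expect_equal(same$t_p, 1)
    expect_equal(same$wilcoxon_p, 1)

    ## q = 0.5 partitions every ranked gene exactly once
    half <- conditionComparison(scoresB, base, loadB, load1, q = 0.5)
    expect_length(intersect(half$top_ids, half$bottom_ids), 0)
    expect_equal(sort(c(half$top_ids, half$bottom_ids)), sort(ids))
    expect_error(conditionComparison(base[1:5], base[1:5], load1[1:5],
                                     load1[1:5]), "at least 10")
})
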