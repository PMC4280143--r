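test_that("Welch t handles symmetric and separated groups", {
    x <- makeTable(matrix(c(1, 2, 3, 1, 2, 3), 1, 6),
                   groups = rep(c("A", "B"), each = 3))
    dt <- differentialTest(x)
    expect_equal(dt$t, 0)
    expect_equal(dt$p, 1)

    set.seed(1)
    sep <- matrix(c(rnorm(4, 0, 1e-4), rnorm(4, 1, 1e-4)), 1, 8)
    dt2 <- differentialTest(makeTable(sep, groups = rep(c("A", "B"), each = 4)))
    expect_lt(dt2$p, 1e-8)
})

test_that("vectorized Welch matches stats::t.test to 1e-12", {
    set.seed(2)
    v <- randomMatrix(25, 14, missingRate = 0.15, seed = 2)
    g <- balancedGroups(14)
    dt <- differentialTest(makeTable(v), groups = g)
    for (i in seq_len(nrow(v))) {
        a <- v[i, g == "A"]; b <- v[i, g == "B"]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2 || length(b) < 2) {
            expect_true(is.na(dt$p[i]))
            next
        }
        ref <- t.test(a, b)
        expect_equal(dt$t[i], unname(ref$statistic), tolerance = 1e-12)
        expect_equal(dt$df[i], unname(ref$parameter), tolerance = 1e-12)
        expect_equal(dt$p[i], ref$p.value, tolerance = 1e-12)
    }
})

test_that("untestable features are marked, not dropped", {
    v <- randomMatrix(3, 6, seed = 3)
    v[1, 4:6] <- NA                       # group B unobserved
    v[2, c(5, 6)] <- NA                   # single obs left in group B
    dt <- differentialTest(makeTable(v), groups = rep(c("A", "B"), each = 3))
    expect_identical(nrow(dt), 3L)
    expect_true(all(is.na(dt$p[1:2])))
    expect_false(is.na(dt$p[3]))
})

test_that("BH adjustment matches its step-up definition", {
    expect_equal(bhAdjust(0.01), 0.01)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

    bruteBH <- function(p) {              # literal step-up definition
        m <- length(p)
        o <- order(p)
        adj <- p[o] * m / seq_len(m)
        adj <- rev(cummin(rev(adj)))
        pmin(adj, 1)[order(o)]
    }
    for (seed in 1:5) {
        set.seed(seed)
        p <- runif(50)^2
        expect_equal(bhAdjust(p), bruteBH(p), tolerance = 1e-12)
        expect_true(all(bhAdjust(p) >= p))
    }

    # NA passthrough: NA entries do not count toward m
    p <- c(0.01, NA, 0.02)
    adj <- bhAdjust(p)
    expect_true(is.na(adj[2]))
    expect_equal(adj[c(1, 3)], bruteBH(c(0.01, 0.02)))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH controls the simulated FDR under independence", {
    fdrs <- vapply(1:20, function(s) {
        set.seed(s)
        m <- 2000; n <- 20
        truthIdx <- seq_len(m / 10)       # 10% true effects
        v <- matrix(rnorm(m * n), m, n)
        v[truthIdx, 11:20] <- v[truthIdx, 11:20] + 2
        dt <- differentialTest(makeTable(v), groups = rep(c("A", "B"), each = 10))
        called <- which(dt$padj < 0.05)
        if (!length(called)) return(0)
        mean(!(called %in% truthIdx))
    }, numeric(1))
    expect_lte(mean(fdrs), 0.05 + 0.02)
})

test_that("Spearman rho has its closed forms and tie handling", {
    x <- makeTable(matrix(c(1, 2, 3, 4, 5,
                            10, 8, 6, 4, 2), 2, 5, byrow = TRUE))
    cov <- data.frame(z = c(2, 4, 6, 8, 10))
    rho <- spearmanToCovariates(x, cov)
    expect_equal(unname(rho[1, 1]), 1.0)
    expect_equal(unname(rho[2, 1]), -1.0)

    # ties: Pearson correlation of average ranks, by brute force
    xt <- c(1, 2, 2, 3, 4, 4, 4)
    zt <- c(5, 5, 7, 8, 8, 9, 10)
    avgRank <- function(u) vapply(u, function(ui)
        sum(u < ui) + (1 + sum(u == ui)) / 2, numeric(1))
    oracle <- {
        rx <- avgRank(xt); rz <- avgRank(zt)
        sum((rx - mean(rx)) * (rz - mean(rz))) /
            sqrt(sum((rx - mean(rx))^2) * sum((rz - mean(rz))^2))
    }
    rhoT <- spearmanToCovariates(makeTable(matrix(xt, 1)),
                                 data.frame(z = zt))
    expect_equal(unname(rhoT[1, 1]), oracle, tolerance = 1e-12)
})

test_that("Spearman rho is invariant to strictly monotone transforms", {
    set.seed(4)
    v <- matrix(rnorm(5 * 12, 15), 5, 12)
    cov <- data.frame(z = rnorm(12))
    r1 <- spearmanToCovariates(makeTable(v), cov)
    r2 <- spearmanToCovariates(makeTable(exp(v / 4)), cov)
    r3 <- spearmanToCovariates(makeTable(v), data.frame(z = cov$z^3))
    expect_equal(r1, r2, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unname(r1), unname(r3), tolerance = 1e-12)
})

test_that("constant vectors and short pairs are NA, with pairwise deletion", {
    v <- matrix(c(7, 7, 7, 7, 7,
                  1, 2, NA, 4, 5), 2, 5, byrow = TRUE)
    rho <- spearmanToCovariates(makeTable(v), data.frame(z = 1:5))
    expect_true(is.na(rho[1, 1]))
    expect_equal(unname(rho[2, 1]), 1.0)  # pairwise-complete on 4 points
    short <- matrix(c(1, 2, NA, NA, NA), 1, 5)
    expect_true(is.na(spearmanToCovariates(makeTable(short),
                                           data.frame(z = 1:5))[1, 1]))
})

test_that("comparing a table with itself is the identity report", {
    sim <- simulateIntensities(simulationConfig(m = 80, n = 16, seed = 5,
                                                trendSpecs = list()))
    x <- sim$table
    cmp <- compareRawVsNormalized(x, x, subsetAdjP = 0.5)
    expect_identical(cmp$nSignificantRaw, cmp$nSignificantNorm)
    expect_lte(cmp$nSignificantRaw, nrow(x))
    expect_equal(cmp$sampleMedians$raw, cmp$sampleMedians$normalized)
    if (!is.null(cmp$correlations))
        for (d in cmp$correlations)
            expect_equal(d$raw, d$normalized)
})
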