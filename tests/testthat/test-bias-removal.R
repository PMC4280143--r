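test_that("loadings are exact for representable residuals", {
    set.seed(1)
    V <- qr.Q(qr(matrix(rnorm(8 * 3), 8, 3)))
    expect_equal(estimateLoadings(2 * V[, 1], V), c(2, 0, 0),
                 tolerance = 1e-12)
    expect_equal(estimateLoadings(rep(0, 8), V), c(0, 0, 0))
})

test_that("masked loadings match the restricted normal-equations oracle", {
    for (seed in 1:5) {
        set.seed(seed)
        n <- 20; h <- 3
        V <- qr.Q(qr(matrix(rnorm(n * h), n, h)))
        r <- rnorm(n)
        r[sample(n, 6)] <- NA                        # 30% masked
        beta <- estimateLoadings(r, V)
        obs <- !is.na(r)
        Xo <- V[obs, , drop = FALSE]
        oracle <- solve(crossprod(Xo), crossprod(Xo, r[obs]))
        expect_equal(beta, as.numeric(oracle), tolerance = 1e-10)
    }
})

test_that("too few observations or rank deficiency is not-estimable", {
    V <- diag(6)[, 1:3]
    r <- c(1, 2, 3, NA, NA, NA)                      # observed count == h
    expect_null(estimateLoadings(r, V))
    # observed rows make the restricted design rank deficient
    r2 <- c(1, NA, NA, 2, 3, 4)
    V2 <- cbind(c(1, 0, 0, 0, 0, 0), c(2, 1, 1, 0, 0, 0))
    expect_null(estimateLoadings(r2, V2))
})

test_that("h = 0 is an identity map", {
    x <- makeTable(randomMatrix(20, 8, missingRate = 0.1, seed = 2),
                   groups = balancedGroups(8))
    fit <- fitANOVA(x)
    dec <- decomposeResiduals(fit, minCompleteRows = 5)
    res <- removeTrends(x, fit, dec, manualTrendSelection(0))
    expect_identical(intensityMatrix(normalizedTable(res)),
                     intensityMatrix(x))
    expect_true(all(featureStatus(res) == "unchanged"))
    expect_identical(ncol(trendLoadings(res)), 0L)
})

test_that("a noiseless injected trend is removed exactly", {
    # trend with zero within-group mean: reconstruction must recover the
    # pure group-effects table to numerical precision
    n <- 8; m <- 40
    g <- rep(c("A", "B"), each = 4)
    v <- c(-1, 1, -1, 1, 1, -1, 1, -1); v <- v / sqrt(sum(v^2))
    set.seed(3)
    mu <- rnorm(m, 16); gamma <- rnorm(m, 0, 0.5); beta <- rnorm(m, 0, 2)
    clean <- outer(mu, rep(1, n)) + outer(gamma, as.numeric(g == "B"))
    biased <- clean + beta %*% t(v)
    x <- makeTable(biased, groups = g)
    fit <- fitANOVA(x)
    dec <- decomposeResiduals(fit, minCompleteRows = 10)
    res <- removeTrends(x, fit, dec, manualTrendSelection(1))
    expect_equal(unname(intensityMatrix(normalizedTable(res))),
                 unname(clean), tolerance = 1e-8)
    expect_true(all(featureStatus(res) == "normalized"))
})

test_that("removal on complete data is an idempotent projection", {
    x <- makeTable(randomMatrix(60, 12, seed = 4),
                   groups = balancedGroups(12))
    fit <- fitANOVA(x)
    dec <- decomposeResiduals(fit)
    sel <- manualTrendSelection(2)
    res <- removeTrends(x, fit, dec, sel)
    xn <- normalizedTable(res)

    # cleaned residuals are orthogonal to each removed trend
    fit2 <- fitANOVA(xn)
    Vh <- trendMatrix(dec)[, 1:2]
    expect_lt(max(abs(fit2@residuals %*% Vh)), 1e-8)

    # second pass with the same trends changes nothing
    res2 <- removeTrends(xn, fit2, dec, sel)
    expect_equal(intensityMatrix(normalizedTable(res2)),
                 intensityMatrix(xn), tolerance = 1e-8)
    expect_lt(max(abs(trendLoadings(res2))), 1e-8)
})

test_that("with missing values the mask is kept and RSS never grows", {
    x <- makeTable(randomMatrix(60, 12, missingRate = 0.1, seed = 4),
                   groups = balancedGroups(12))
    fit <- fitANOVA(x)
    dec <- decomposeResiduals(fit, minCompleteRows = 12)
    res <- removeTrends(x, fit, dec, manualTrendSelection(2))
    xn <- normalizedTable(res)

    # mask is untouched, bitwise
    expect_identical(observedMask(xn), observedMask(x))

    # per-feature observed RSS never increases (least-squares projection)
    fit2 <- fitANOVA(xn)
    rss <- function(f) rowSums(f@residuals^2, na.rm = TRUE)
    expect_true(all(rss(fit2) <= rss(fit) + 1e-10))
})

test_that("features at the estimability boundary pass through flagged", {
    v <- randomMatrix(30, 10, seed = 6)
    v[1, 3:10] <- NA                      # 2 observations, h = 2 -> short
    v[2, c(1, 4, 8)] <- NA                # estimable from 7 positions
    x <- makeTable(v, groups = balancedGroups(10))
    fit <- fitANOVA(x)
    dec <- decomposeResiduals(fit, minCompleteRows = 10)
    res <- removeTrends(x, fit, dec, manualTrendSelection(2))
    st <- featureStatus(res)
    expect_identical(unname(st[1]), "unchanged")
    expect_identical(unname(st[2]), "partially_estimable")
    expect_equal(intensityMatrix(normalizedTable(res))[1, ],
                 intensityMatrix(x)[1, ])
    expect_true(all(st[-(1:2)] == "normalized"))
})

test_that("group effects survive normalization on simulated data", {
    deltas <- vapply(1:3, function(s) {
        sim <- simulateIntensities(simulationConfig(
            m = 200, n = 24, seed = s, trendSpecs = list(), noiseSd = 0.5))
        x <- sim$table
        res <- eigenNormalize(x, trends = 2)
        g <- designFactors(x)$group
        eff <- function(tab) {
            v <- intensityMatrix(tab)
            rowMeans(v[, g == "case", drop = FALSE]) -
                rowMeans(v[, g == "control", drop = FALSE])
        }
        sqrt(mean((eff(normalizedTable(res)) - eff(x))^2))
    }, numeric(1))
    # without injected bias, removal barely moves the estimated effects
    expect_lt(max(deltas), 0.05)
})

test_that("variance accounting reflects trend removal", {
    sim <- simulateIntensities(simulationConfig(
        m = 400, n = 40, seed = 9,
        trendSpecs = list(trendSpec("linear_drift", varianceFraction = 0.4))))
    x <- sim$table
    res <- eigenNormalize(x, trends = 1)
    rep <- summarizeVarianceShift(x, normalizedTable(res))
    expect_identical(rownames(rep), c("before", "after"))
    expect_equal(rep["before", "trendVar1"], 0.4, tolerance = 0.08)
    expect_lt(rep["after", "trendVar1"], 0.1)
    ok <- unlist(rep)
    expect_true(all(ok[!is.na(ok)] >= 0 & ok[!is.na(ok)] <= 1))
    # before == after gives identical rows
    rep2 <- summarizeVarianceShift(x, x)
    expect_equal(rep2["before", ], rep2["after", ], ignore_attr = TRUE)
})
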