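test_that("delimited parsing fills the mask from missing codes", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("feature\tS1\tS2",
                 "F1\t1.5\t2.5",
                 "F2\tNA\t4.0",
                 "F3\t5.0\t6.0"), path)
    x <- readFeatureTable(path)
    expect_s4_class(x, "IntensityExperiment")
    expect_identical(dim(x), c(3L, 2L))
    expect_identical(sum(!observedMask(x)), 1L)
    expect_false(observedMask(x)["F2", "S1"])
    expect_identical(intensityMatrix(x)["F3", "S2"], 6.0)
})

test_that("duplicate identifiers and bad files are rejected", {
    dupSample <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("feature\tS1\tS1", "F1\t1\t2"), dupSample)
    expect_error(readFeatureTable(dupSample), "duplicated sample id")

    dupFeature <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("feature\tS1\tS2", "F1\t1\t2", "F1\t3\t4"), dupFeature)
    expect_error(readFeatureTable(dupFeature), "duplicated feature id")

    allMissing <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("feature\tS1", "F1\tNA", "F2\tNA"), allMissing)
    expect_error(readFeatureTable(allMissing), "no observed values")

    ambiguous <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("feature\tS1,S2", "F1\t1,2"), ambiguous)
    expect_error(readFeatureTable(ambiguous), "ambiguous delimiter")
})

test_that("zeros are kept unless zero-as-missing is requested", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("feature,S1,S2", "F1,0,2", "F2,3,4"), path)
    x <- readFeatureTable(path)                       # comma auto-detected
    expect_identical(intensityMatrix(x)["F1", "S1"], 0)
    x0 <- readFeatureTable(path, zeroAsMissing = TRUE)
    expect_false(observedMask(x0)["F1", "S1"])
    expect_identical(sum(!observedMask(x0)), 1L)
})

test_that("write/read round-trip is lossless for values, mask and ids", {
    for (seed in 1:5) {
        v <- randomMatrix(m = 20, n = 7, missingRate = 0.2, seed = seed)
        x <- makeTable(v)
        path <- withr::local_tempfile(fileext = ".tsv")
        writeFeatureTable(x, path)
        y <- readFeatureTable(path, scale = "log")
        expect_identical(rownames(y), rownames(x))
        expect_identical(colnames(y), colnames(x))
        expect_identical(observedMask(y), observedMask(x))
        expect_identical(intensityMatrix(y), intensityMatrix(x))
    }
})

test_that("log transform has the closed form and an exact inverse", {
    x <- makeTable(matrix(c(100, 10, 1, 1000), 2, 2), scale = "raw")
    lx <- logTransform(x, base = 10)
    expect_equal(intensityMatrix(lx)[1, 1], 2.0)
    expect_identical(intensityScale(lx), "log")

    set.seed(4)
    v <- matrix(rexp(60, rate = 1 / 1000), 10, 6)
    r <- makeTable(v, scale = "raw")
    l2 <- logTransform(r, base = 2)
    expect_equal(2^intensityMatrix(l2), v, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_error(logTransform(r, base = 1), "base")
    expect_error(logTransform(l2), "already")
})

test_that("non-positive cells are masked and counted during log transform", {
    x <- makeTable(matrix(c(0, 4, 2, 8), 2, 2), scale = "raw")
    expect_warning(lx <- logTransform(x, base = 2), "masked")
    expect_false(observedMask(lx)[1, 1])
    expect_identical(S4Vectors::metadata(lx)$nNonPositiveMasked, 1L)
    expect_equal(intensityMatrix(lx)[2, 2], 3)
})

test_that("sample data alignment reorders, reports and errors by name", {
    x <- makeTable(randomMatrix(5, 4))
    design <- data.frame(group = c("b", "a", "b", "a"),
                         row.names = colnames(x))

    same <- attachSampleData(x, design)
    rep0 <- S4Vectors::metadata(same)$alignment
    expect_false(rep0$reordered)
    expect_identical(rep0$permutation, 1:4)

    perm <- c(3, 1, 4, 2)
    shuffled <- design[perm, , drop = FALSE]
    al <- attachSampleData(x, shuffled)
    repA <- S4Vectors::metadata(al)$alignment
    expect_true(repA$reordered)
    expect_identical(designFactors(al)$group,
                     factor(design$group))
    expect_identical(primaryFactor(al), "group")

    expect_error(attachSampleData(x, design[-2, , drop = FALSE]),
                 colnames(x)[2])
})

test_that("covariates are aligned with the table and kept numeric", {
    x <- makeTable(randomMatrix(4, 4))
    design <- data.frame(group = balancedGroups(4), row.names = colnames(x))
    cov <- data.frame(glucose = c(5.1, 9.8, 4.9, 10.2),
                      row.names = rev(colnames(x)))
    al <- attachSampleData(x, design, covariates = cov)
    expect_identical(sampleCovariates(al)$glucose, rev(cov$glucose))
    expect_error(attachSampleData(x, design, covariates = cov[-1, , drop = FALSE]),
                 "missing from covariates")
})

test_that("construction enforces the table invariants", {
    v <- randomMatrix(3, 3)
    rownames(v) <- c("F1", "F1", "F2")
    expect_error(IntensityExperiment(v), "unique")
    v2 <- randomMatrix(3, 3)
    v2[1, 1] <- Inf
    expect_error(IntensityExperiment(v2, scale = "log"), "finite")
    expect_silent(IntensityExperiment(v2, scale = "raw"))
})
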