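#' @import methods
#' @importFrom stats runif rnorm pt qlogis plogis sd complete.cases setNames
#' @importFrom utils read.table write.table packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors metadata `metadata<-` DataFrame
NULL

#' IntensityExperiment: a feature-by-sample intensity table
#'
#' An `IntensityExperiment` holds an LC-MS feature table as a
#' [SummarizedExperiment::SummarizedExperiment] with a single `intensity`
#' assay (features in rows, samples in columns), plus a `scale` flag that
#' records whether the stored values are raw or log intensities. Missing
#' (unobserved) cells are stored as `NA` and are excluded from all
#' arithmetic; no operation in this package ever fills a masked cell.
#'
#' Design factors (the treatment groups and any additional fixed-effect
#' factors) and numeric sample covariates live in `colData`; the names of
#' the factor columns, of the primary (treatment) factor, and of the
#' covariate columns are tracked in `metadata(x)$factors`,
#' `metadata(x)$primaryFactor` and `metadata(x)$covariates`.
#'
#' @slot scale character, `"raw"` or `"log"`. When `"log"`, all observed
#'   values must be finite.
#'
#' @seealso [IntensityExperiment()], [readFeatureTable()], [logTransform()],
#'   [attachSampleData()]
#' @export
setClass("IntensityExperiment",
    contains = "SummarizedExperiment",
    slots = c(scale = "character"),
    prototype = prototype(scale = "raw"))

setValidity("IntensityExperiment", function(object) {
    msg <- character()
    if (length(object@scale) != 1L || !object@scale %in% c("raw", "log"))
        msg <- c(msg, "'scale' must be one of \"raw\", \"log\"")
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "an assay named 'intensity' is required")
    fid <- rownames(object); sid <- colnames(object)
    if (is.null(fid) || anyDuplicated(fid) || any(is.na(fid)) || any(fid == ""))
        msg <- c(msg, "feature ids must be unique, non-empty and non-NA")
    if (is.null(sid) || anyDuplicated(sid) || any(is.na(sid)) || any(sid == ""))
        msg <- c(msg, "sample ids must be unique, non-empty and non-NA")
    v <- SummarizedExperiment::assay(object, "intensity")
    if (!is.numeric(v))
        msg <- c(msg, "'intensity' assay must be numeric")
    if (identical(object@scale, "log") && any(!is.finite(v[!is.na(v)])))
        msg <- c(msg, "log-scale values must be finite where observed")
    if (length(msg)) msg else TRUE
})

#' ResidualFit: per-feature fixed-effects ANOVA fits
#'
#' Result of [fitANOVA()]: the cell-means fit of every feature on the
#' design's factor combinations, with fitted values and residuals defined
#' only at observed positions. Features with residual degrees of freedom
#' below one are unusable for trend estimation and are listed in
#' `excluded` with a reason; features whose design has an entirely
#' unobserved cell are fit on the remaining cells and flagged.
#'
#' @slot fitted m x n matrix of fitted cell means (NA where unobserved).
#' @slot residuals m x n matrix of residuals, `observed - fitted`.
#' @slot cells factor of length n: the design cell of each sample.
#' @slot usable logical m: TRUE when `dfResidual >= 1`.
#' @slot dfResidual integer m: observed count minus estimated cell means.
#' @slot emptyCell logical m: TRUE when some design cell has no observation.
#' @slot excluded data.frame with columns `feature`, `reason` for features
#'   excluded from the residual matrix.
#'
#' @seealso [fitANOVA()], [residualMatrix()]
#' @export
setClass("ResidualFit",
    slots = c(fitted = "matrix", residuals = "matrix", cells = "factor",
              usable = "logical", dfResidual = "integer",
              emptyCell = "logical", excluded = "data.frame"))

setValidity("ResidualFit", function(object) {
    msg <- character()
    m <- nrow(object@fitted)
    if (!identical(dim(object@fitted), dim(object@residuals)))
        msg <- c(msg, "'fitted' and 'residuals' must have identical shape")
    if (length(object@cells) != ncol(object@fitted))
        msg <- c(msg, "'cells' length must equal the number of samples")
    for (s in c("usable", "dfResidual", "emptyCell"))
        if (length(slot(object, s)) != m)
            msg <- c(msg, sprintf("'%s' must have one entry per feature", s))
    if (length(msg)) msg else TRUE
})

#' ResidualDecomposition: SVD of the residual matrix
#'
#' Singular value decomposition `R = U D V'` of the complete-row submatrix
#' of the ANOVA residual matrix. Columns of `V` are the sample-indexed bias
#' trends; `varExplained[k] = d_k^2 / sum_j d_j^2` is the fraction of
#' residual variation carried by trend k. A deterministic sign convention
#' is applied: each column of `V` is flipped so its largest-magnitude entry
#' is positive (trends are otherwise only defined up to sign).
#'
#' Only residual rows without missing entries enter the decomposition;
#' `completeRows` records which rows of the input residual matrix were
#' used. Incomplete rows are still normalized downstream by regressing
#' their observed residuals on the trends.
#'
#' @slot U m' x r left singular vectors (feature loadspace).
#' @slot D length-r singular values, non-increasing.
#' @slot V n x r right singular vectors; columns are trends.
#' @slot varExplained length-r variance fractions, summing to 1.
#' @slot completeRows logical, one entry per row of the input matrix.
#' @slot note character; how masked cells were handled.
#'
#' @seealso [decomposeResiduals()], [permutationTrendTest()]
#' @export
setClass("ResidualDecomposition",
    slots = c(U = "matrix", D = "numeric", V = "matrix",
              varExplained = "numeric", completeRows = "logical",
              note = "character"))

setValidity("ResidualDecomposition", function(object) {
    msg <- character()
    r <- length(object@D)
    if (ncol(object@U) != r || ncol(object@V) != r)
        msg <- c(msg, "U, D and V must agree on the number of components")
    if (is.unsorted(rev(object@D)))
        msg <- c(msg, "singular values must be non-increasing")
    if (length(object@varExplained) != r)
        msg <- c(msg, "one variance fraction per component required")
    tot <- sum(object@varExplained)
    if (tot > 0 && abs(tot - 1) > 1e-8)
        msg <- c(msg, "variance fractions must sum to 1")
    if (length(msg)) msg else TRUE
})

#' TrendSelection: how many bias trends to remove
#'
#' The number of trends `h` to eliminate, together with the selection
#' method: `"permutation"` (step-down permutation test on the singular
#' value ratio statistic), `"heuristic"` (a fraction of the number of
#' samples, about 20\% for metabolomics data), or `"manual"`.
#'
#' @slot h integer, number of trends to remove.
#' @slot method one of `"permutation"`, `"heuristic"`, `"manual"`.
#' @slot pValues per-trend permutation p-values as computed (empty for
#'   heuristic/manual selection).
#' @slot alpha significance level used by the step-down rule.
#' @slot B number of permutation replicates.
#' @slot seed integer seed used for the permutation stream (NA if none).
#' @slot note character annotation (e.g. degenerate-input explanation).
#'
#' @seealso [permutationTrendTest()], [heuristicTrendCount()]
#' @export
setClass("TrendSelection",
    slots = c(h = "integer", method = "character", pValues = "numeric",
              alpha = "numeric", B = "integer", seed = "integer",
              note = "character"),
    prototype = prototype(pValues = numeric(), alpha = NA_real_,
                          B = NA_integer_, seed = NA_integer_,
                          note = character()))

setValidity("TrendSelection", function(object) {
    msg <- character()
    if (length(object@h) != 1L || is.na(object@h) || object@h < 0L)
        msg <- c(msg, "'h' must be a single non-negative integer")
    if (!object@method %in% c("permutation", "heuristic", "manual"))
        msg <- c(msg, "'method' must be permutation, heuristic or manual")
    if (length(object@pValues) &&
        any(object@pValues < 0 | object@pValues > 1, na.rm = TRUE))
        msg <- c(msg, "p-values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' NormalizationResult: a normalized table with its provenance
#'
#' Output of [removeTrends()] / [eigenNormalize()]: the normalized
#' intensity table (same shape and missing-value mask as the input),
#' per-feature trend loadings, a per-feature status flag, and the trend
#' selection and residual decomposition that produced it.
#'
#' Status levels: `"normalized"` (complete residual row, trends removed),
#' `"partially_estimable"` (missing values present but loadings estimable
#' from the observed positions), `"unchanged"` (feature passed through
#' untouched: unusable for ANOVA, too few observations to estimate the
#' loadings, or `h = 0`).
#'
#' @slot normalized an [IntensityExperiment].
#' @slot loadings m x h matrix of per-feature trend coefficients (NA rows
#'   where not estimable); 0 columns when h = 0.
#' @slot status character m, per-feature normalization status.
#' @slot selection the [TrendSelection] used.
#' @slot decomposition the [ResidualDecomposition] used.
#'
#' @seealso [removeTrends()], [eigenNormalize()]
#' @export
setClass("NormalizationResult",
    slots = c(normalized = "IntensityExperiment", loadings = "matrix",
              status = "character", selection = "TrendSelection",
              decomposition = "ResidualDecomposition"))

setValidity("NormalizationResult", function(object) {
    msg <- character()
    m <- nrow(object@normalized)
    if (nrow(object@loadings) != m)
        msg <- c(msg, "'loadings' must have one row per feature")
    if (length(object@status) != m)
        msg <- c(msg, "'status' must have one entry per feature")
    bad <- setdiff(unique(object@status),
                   c("normalized", "partially_estimable", "unchanged"))
    if (length(bad))
        msg <- c(msg, paste("invalid status:", paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
})
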