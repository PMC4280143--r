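#' Least-squares trend loadings for one feature
#'
#' Regresses the observed residual entries of a feature jointly on the
#' selected trend columns (ordinary least squares restricted to observed
#' positions). The joint projection over all h trends is the unique
#' variance-minimizing choice and remains well defined under missingness.
#' Returns `NULL` (not estimable) when fewer than `h + 1` entries are
#' observed or the restricted trend matrix is rank deficient.
#'
#' @param residuals length-n numeric vector, `NA` where unobserved.
#' @param V n x h matrix of trend columns.
#' @return length-h coefficient vector, or `NULL` when not estimable.
#' @export
estimateLoadings <- function(residuals, V) {
    V <- as.matrix(V)
    h <- ncol(V)
    if (h < 1L) stop("at least one trend column is required")
    obs <- which(!is.na(residuals))
    if (length(obs) < h + 1L) return(NULL)
    X <- V[obs, , drop = FALSE]
    qrX <- qr(X)
    if (qrX$rank < h) return(NULL)
    as.numeric(qr.coef(qrX, residuals[obs]))
}

#' Remove the selected bias trends from a feature table
#'
#' Reconstructs each feature as *fitted treatment value + cleaned
#' residual*, where the cleaned residual is the feature's residual minus
#' its least-squares projection onto the selected trends (evaluated at
#' observed positions only). Adding the cleaned residuals back to the
#' per-feature ANOVA fitted values — not to a grand mean — is what
#' preserves the treatment-group differences by construction.
#'
#' Features fall into three classes: complete residual rows are fully
#' `"normalized"`; features with missing values whose loadings are still
#' estimable from the observed positions are `"partially_estimable"`;
#' features unusable for ANOVA or with too few observations to estimate
#' loadings pass through `"unchanged"` (never dropped). With `h = 0` the
#' input is returned unchanged. The missing-value mask is never altered.
#' No residual-variance rescaling is applied after removal; use
#' [summarizeVarianceShift()] to see the variance reduction.
#'
#' @param x the [IntensityExperiment] that was fit.
#' @param fit the [ResidualFit] from [fitANOVA()].
#' @param decomposition the [ResidualDecomposition] of `fit`'s residuals.
#' @param selection a [TrendSelection] (h >= 0).
#' @return A [NormalizationResult].
#' @seealso [eigenNormalize()] for the one-call pipeline.
#' @export
removeTrends <- function(x, fit, decomposition, selection) {
    stopifnot(is(x, "IntensityExperiment"), is(fit, "ResidualFit"),
              is(decomposition, "ResidualDecomposition"),
              is(selection, "TrendSelection"))
    values <- intensityMatrix(x)
    m <- nrow(values); n <- ncol(values)
    if (!identical(dim(fit@fitted), dim(values)) ||
        nrow(decomposition@V) != n)
        stop("table, fit and decomposition shapes are inconsistent")
    h <- selection@h
    maxH <- length(decomposition@D)
    if (h > maxH)
        stop("selection requests ", h, " trends but only ", maxH,
             " components are available")
    status <- rep("unchanged", m)
    names(status) <- rownames(values)
    if (h == 0L) {
        loadings <- matrix(numeric(0), nrow = m, ncol = 0,
                           dimnames = list(rownames(values), NULL))
        return(new("NormalizationResult", normalized = x,
                   loadings = loadings, status = status,
                   selection = selection, decomposition = decomposition))
    }
    Vh <- decomposition@V[, seq_len(h), drop = FALSE]
    res <- fit@residuals
    loadings <- matrix(NA_real_, m, h,
                       dimnames = list(rownames(values),
                                       paste0("trend", seq_len(h))))
    usable <- which(fit@usable)
    completeRow <- rowSums(is.na(res)) == 0L
    # complete rows: V'V = I so the joint OLS is a plain cross-product
    ic <- usable[completeRow[usable]]
    if (length(ic)) {
        loadings[ic, ] <- res[ic, , drop = FALSE] %*% Vh
        status[ic] <- "normalized"
    }
    ip <- usable[!completeRow[usable]]
    for (i in ip) {
        beta <- estimateLoadings(res[i, ], Vh)
        if (!is.null(beta)) {
            loadings[i, ] <- beta
            status[i] <- "partially_estimable"
        }
    }
    est <- which(!is.na(loadings[, 1L]))
    cleaned <- res
    if (length(est)) {
        trendPart <- loadings[est, , drop = FALSE] %*% t(Vh)
        cleaned[est, ] <- res[est, , drop = FALSE] - trendPart
    }
    newValues <- values
    repl <- fit@fitted + cleaned
    take <- !is.na(repl) & status != "unchanged"
    newValues[take] <- repl[take]
    out <- x
    SummarizedExperiment::assay(out, "intensity") <- newValues
    validObject(out)
    new("NormalizationResult", normalized = out, loadings = loadings,
        status = status, selection = selection,
        decomposition = decomposition)
}

#' Accessors for normalization results
#'
#' `normalizedTable()` returns the normalized [IntensityExperiment],
#' `trendLoadings()` the m x h per-feature loadings matrix, and
#' `featureStatus()` the per-feature status
#' (`normalized` / `partially_estimable` / `unchanged`).
#'
#' @param object a [NormalizationResult].
#' @return IntensityExperiment / matrix / named character vector.
#' @name normAccessors
NULL

#' @rdname normAccessors
#' @export
setMethod("normalizedTable", "NormalizationResult",
    function(object) object@normalized)

#' @rdname normAccessors
#' @export
setMethod("trendLoadings", "NormalizationResult",
    function(object) object@loadings)

#' @rdname normAccessors
#' @export
setMethod("featureStatus", "NormalizationResult",
    function(object) object@status)

setMethod("show", "NormalizationResult", function(object) {
    tab <- table(factor(object@status,
                        c("normalized", "partially_estimable", "unchanged")))
    cat("NormalizationResult: h =", object@selection@h,
        "trends removed (", object@selection@method, ")\n")
    cat(sprintf("  features: %d normalized, %d partially estimable, %d unchanged\n",
                tab[1L], tab[2L], tab[3L]))
})
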