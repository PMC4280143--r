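#' Per-feature fixed-effects ANOVA and the residual matrix
#'
#' Fits every feature with a cell-means model over all combinations of the
#' design factors: the fitted value of an observed cell is the mean of the
#' observed values in its design cell, so residuals sum to zero within
#' every cell. This captures (and later preserves) the variation
#' attributable to the treatment effects; the residual matrix is the
#' substrate for bias-trend discovery.
#'
#' The cell-means parameterization gives residuals identical to any
#' full-rank contrast coding of the crossed fixed-effects model, with no
#' contrast ambiguity and graceful behaviour when cells are missing.
#' A feature is *usable* when its residual degrees of freedom are at least
#' one (observed count >= number of occupied cells + 1); zero-df residual
#' rows are identically zero and would dilute trend estimation, so they
#' are excluded and reported. Features with an entirely unobserved design
#' cell are fit on their remaining cells and flagged (`emptyCell`); their
#' residual rows are incomplete and therefore never enter trend
#' estimation, but they are still normalized by loadings regression.
#'
#' @param x an [IntensityExperiment] with an attached design, or a numeric
#'   matrix (then `design` must be given).
#' @param design optional data.frame of factors, one row per sample; taken
#'   from `designFactors(x)` when `x` is an IntensityExperiment.
#' @param requireLog when TRUE (default) a raw-scale IntensityExperiment
#'   is refused; set FALSE to override deliberately.
#' @return A [ResidualFit].
#' @examples
#' ie <- IntensityExperiment(
#'   matrix(c(1, 3, 2, 6), 1, 4,
#'          dimnames = list("F1", paste0("S", 1:4))),
#'   scale = "log", design = data.frame(group = c("A", "A", "B", "B")))
#' fit <- fitANOVA(ie)
#' residualMatrix(fit)  # -1 1 -2 2
#' @export
fitANOVA <- function(x, design = NULL, requireLog = TRUE) {
    if (is(x, "IntensityExperiment")) {
        if (requireLog && intensityScale(x) != "log")
            stop("table is on the raw scale; logTransform() it first ",
                 "(or set requireLog = FALSE)")
        values <- intensityMatrix(x)
        if (is.null(design)) design <- designFactors(x)
    } else {
        values <- as.matrix(x)
        if (is.null(design)) stop("'design' is required for matrix input")
    }
    design <- as.data.frame(design)
    if (!length(design)) stop("at least one design factor is required")
    if (nrow(design) != ncol(values))
        stop("design rows must match table samples")
    if (ncol(values) < 2L) stop("need at least two samples")
    cells <- interaction(lapply(design, factor), drop = TRUE, lex.order = TRUE)

    m <- nrow(values); n <- ncol(values)
    fitted <- matrix(NA_real_, m, n, dimnames = dimnames(values))
    lev <- levels(cells)
    cellCounts <- matrix(0L, m, length(lev))
    for (k in seq_along(lev)) {
        idx <- which(cells == lev[k])
        sub <- values[, idx, drop = FALSE]
        cnt <- rowSums(!is.na(sub))
        mu <- rowSums(sub, na.rm = TRUE) / cnt      # NaN when cnt == 0
        fitted[, idx] <- mu
        cellCounts[, k] <- cnt
    }
    fitted[is.na(values)] <- NA_real_               # defined only where observed
    fitted[is.nan(fitted)] <- NA_real_
    residuals <- values - fitted

    nParams <- rowSums(cellCounts > 0L)
    nObs <- rowSums(cellCounts)
    dfResidual <- as.integer(nObs - nParams)
    usable <- dfResidual >= 1L
    emptyCell <- rowSums(cellCounts == 0L) > 0L

    reason <- rep(NA_character_, m)
    reason[!usable & nObs <= 1L] <- "insufficient observations"
    reason[!usable & nObs > 1L] <- "zero residual degrees of freedom"
    excluded <- data.frame(feature = rownames(values)[!usable],
                           reason = reason[!usable],
                           stringsAsFactors = FALSE)
    fit <- new("ResidualFit", fitted = fitted, residuals = residuals,
               cells = cells, usable = usable, dfResidual = dfResidual,
               emptyCell = emptyCell, excluded = excluded)
    if (!any(usable))
        stop("no feature has residual degrees of freedom; ",
             "cannot build a residual matrix")
    fit
}

#' Extract the residual matrix of usable features
#'
#' Returns the m' x n matrix stacking the residual rows of the features
#' usable for trend analysis (residual df >= 1), in input order. Rows may
#' contain `NA` at unobserved positions; trend estimation further
#' restricts to complete rows (see [decomposeResiduals()]).
#'
#' @param object a [ResidualFit].
#' @param ... unused.
#' @return numeric matrix.
#' @name residualMatrix
#' @export
setMethod("residualMatrix", "ResidualFit", function(object, ...) {
    object@residuals[object@usable, , drop = FALSE]
})

#' @rdname residualMatrix
#' @param fit a [ResidualFit].
#' @export
fittedValues <- function(fit) {
    stopifnot(is(fit, "ResidualFit"))
    fit@fitted
}

#' @rdname residualMatrix
#' @export
excludedFeatures <- function(fit) {
    stopifnot(is(fit, "ResidualFit"))
    fit@excluded
}

setMethod("show", "ResidualFit", function(object) {
    cat("ResidualFit:", nrow(object@fitted), "features x",
        ncol(object@fitted), "samples\n")
    cat("  design cells:", nlevels(object@cells),
        "| usable features:", sum(object@usable),
        "| excluded:", sum(!object@usable),
        "| empty-cell flagged:", sum(object@emptyCell), "\n")
})
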