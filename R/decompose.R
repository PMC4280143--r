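#' Singular value decomposition of the residual matrix
#'
#' Computes `R = U D V'` on the complete rows of the residual matrix (rows
#' with no missing entries). Columns of `V` are the sample-indexed bias
#' trends, ordered by decreasing singular value; `varExplained[k] =
#' d_k^2 / sum(d^2)`. Restricting to complete rows avoids any imputation
#' bias in the trend estimates; features with missing entries are
#' normalized later by regressing their observed residuals on the trends.
#'
#' Because singular vectors are only defined up to sign, a deterministic
#' convention is applied: each column of `V` is flipped (together with the
#' matching column of `U`) so that its largest-magnitude entry is
#' positive.
#'
#' @param object a [ResidualFit] or a numeric residual matrix (possibly
#'   containing `NA`).
#' @param minCompleteRows minimum number of complete rows required;
#'   default `max(10, n)`. Fewer is an error suggesting stricter feature
#'   filtering.
#' @param ... unused.
#' @return A [ResidualDecomposition].
#' @name decomposeResiduals
#' @examples
#' R <- diag(c(2, 1))
#' varianceExplained(decomposeResiduals(R, minCompleteRows = 2))  # 0.8 0.2
NULL

.decomposeMatrix <- function(R, minCompleteRows = NULL) {
    R <- as.matrix(R)
    if (nrow(R) < 2L || ncol(R) < 3L) {
        if (is.null(minCompleteRows) || nrow(R) < 2L || ncol(R) < 2L)
            stop("residual matrix must have >= 2 rows and >= 3 columns")
    }
    n <- ncol(R)
    complete <- rowSums(is.na(R)) == 0L
    need <- if (is.null(minCompleteRows)) max(10L, n) else minCompleteRows
    if (sum(complete) < need)
        stop("only ", sum(complete), " complete residual rows (need >= ",
             need, "); filter features with many missing values ",
             "before trend estimation")
    Rc <- R[complete, , drop = FALSE]
    sv <- svd(Rc)
    r <- length(sv$d)
    # deterministic sign: largest-|.| entry of each trend positive
    for (k in seq_len(r)) {
        j <- which.max(abs(sv$v[, k]))
        if (sv$v[j, k] < 0) {
            sv$v[, k] <- -sv$v[, k]
            sv$u[, k] <- -sv$u[, k]
        }
    }
    d2 <- sv$d^2
    tot <- sum(d2)
    ve <- if (tot > 0) d2 / tot else rep(0, r)
    rownames(sv$u) <- rownames(Rc)
    rownames(sv$v) <- colnames(Rc)
    new("ResidualDecomposition", U = sv$u, D = sv$d, V = sv$v,
        varExplained = ve, completeRows = complete,
        note = paste0("SVD on ", sum(complete), "/", nrow(R),
                      " complete residual rows; incomplete rows excluded ",
                      "from trend estimation (no imputation)"))
}

#' @rdname decomposeResiduals
#' @export
setMethod("decomposeResiduals", "matrix",
    function(object, minCompleteRows = NULL, ...)
        .decomposeMatrix(object, minCompleteRows))

#' @rdname decomposeResiduals
#' @export
setMethod("decomposeResiduals", "ResidualFit",
    function(object, minCompleteRows = NULL, ...)
        .decomposeMatrix(residualMatrix(object), minCompleteRows))

#' Accessors for trend decompositions and selections
#'
#' `trendMatrix()` returns the n x r matrix whose columns are the bias
#' trends (right singular vectors); `varianceExplained()` the per-trend
#' fractions d_k^2 / sum(d^2); `nTrends()` the selected number of trends
#' of a [TrendSelection]; `trendPValues()` its per-trend permutation
#' p-values.
#'
#' @param object a [ResidualDecomposition] or [TrendSelection].
#' @return matrix / numeric / integer / numeric respectively.
#' @name trendAccessors
NULL

#' @rdname trendAccessors
#' @export
setMethod("trendMatrix", "ResidualDecomposition", function(object) object@V)

#' @rdname trendAccessors
#' @export
setMethod("varianceExplained", "ResidualDecomposition",
    function(object) object@varExplained)

#' @rdname trendAccessors
#' @export
setMethod("nTrends", "TrendSelection", function(object) object@h)

#' @rdname trendAccessors
#' @export
setMethod("trendPValues", "TrendSelection", function(object) object@pValues)

setMethod("show", "ResidualDecomposition", function(object) {
    cat("ResidualDecomposition:", nrow(object@U), "features x",
        nrow(object@V), "samples,", length(object@D), "components\n")
    k <- min(5L, length(object@D))
    cat("  top variance fractions:",
        paste(sprintf("%.3f", object@varExplained[seq_len(k)]),
              collapse = " "), "\n")
})

setMethod("show", "TrendSelection", function(object) {
    cat("TrendSelection: h =", object@h, "(", object@method, ")\n")
    if (length(object@pValues))
        cat("  p-values:",
            paste(sprintf("%.4g", object@pValues), collapse = " "),
            sprintf(" [alpha = %g, B = %d]\n", object@alpha, object@B))
    if (length(object@note)) cat("  note:", object@note, "\n")
})
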