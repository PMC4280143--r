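#' Step-down permutation test for the number of bias trends
#'
#' Decides how many leading singular trends of the residual matrix are
#' systematic rather than noise. For trend k the statistic is the
#' tail-conditioned eigenvalue ratio
#' \deqn{f_k = d_k^2 / \sum_{j \ge k} d_j^2,}
#' the fraction of the *remaining* residual variation carried by trend k.
#' The test is step-down and sequential: trend k is tested on the residual
#' matrix re-orthogonalized against the previously accepted trends
#' (their right-singular directions projected out), on which f_k is the
#' leading eigenvalue fraction. Its null distribution is built by
#' permuting the entries within each row of that reduced matrix
#' (destroying all across-sample structure while preserving each
#' feature's residual distribution) and re-decomposing, B times;
#' `p_k = (1 + #\{f*_k >= f_k\}) / (B + 1)`. Trends 1, 2, ... are
#' accepted while `p_k <= alpha`, stopping at the first failure: trends
#' are variance-ordered, so accepting a later trend after rejecting an
#' earlier one would be uninterpretable. Projecting out accepted trends
#' before permuting keeps the null honest for the later tests — otherwise
#' the accepted trends' variance would inflate the permuted spectrum and
#' later p-values would be anticonservative.
#'
#' Only complete residual rows are used (as in [decomposeResiduals()]).
#' A degenerate all-zero residual matrix yields `h = 0` with a note.
#'
#' @param object a [ResidualFit] or numeric residual matrix.
#' @param B number of permutation replicates (>= 50; default 500).
#' @param alpha significance level of the step-down rule (default 0.05).
#' @param seed integer seed for the permutation stream; recorded in the
#'   result. `NULL` leaves the RNG state untouched (seed recorded as NA).
#' @param hMax largest number of trends to test (default n - 2).
#' @param ... unused.
#' @return A [TrendSelection] with `method = "permutation"`.
#' @name permutationTrendTest
NULL

.permutationTest <- function(R, B = 500L, alpha = 0.05, seed = NULL,
                             hMax = NULL, cells = NULL) {
    R <- as.matrix(R)
    n <- ncol(R)
    complete <- rowSums(is.na(R)) == 0L
    Rc <- R[complete, , drop = FALSE]
    if (nrow(Rc) < max(10L, n))
        stop("too few complete residual rows for the permutation test")
    if (is.null(hMax)) hMax <- n - 2L
    hMax <- as.integer(hMax)
    B <- as.integer(B)
    if (B < 50L) stop("'B' must be at least 50")
    if (!(alpha > 0 && alpha < 1)) stop("'alpha' must be in (0, 1)")
    if (hMax < 1L || hMax > n - 1L) stop("'hMax' must be in [1, n - 1]")
    if (!is.null(seed)) set.seed(as.integer(seed))

    tot <- sum(Rc^2)
    if (tot <= 1e-12 * length(Rc))
        return(new("TrendSelection", h = 0L, method = "permutation",
                   pValues = numeric(), alpha = alpha, B = B,
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                   note = "degenerate residual matrix (no variation); h = 0"))

    m <- nrow(Rc)
    colKey <- rep(seq_len(m), each = n)
    # projection onto the orthocomplement of the design-cell space: observed
    # residual rows live there, so permuted null rows are re-residualized
    # into the same space to keep ranks comparable
    P <- diag(n)
    if (!is.null(cells)) {
        cells <- factor(cells)
        for (lev in levels(cells)) {
            idx <- which(cells == lev)
            P[idx, idx] <- P[idx, idx] - 1 / length(idx)
        }
    }
    p <- numeric(0)
    h <- 0L
    Rcur <- Rc
    for (k in seq_len(hMax)) {
        sv <- svd(Rcur, nu = 0, nv = min(1L, n))
        d2 <- sv$d^2
        denom <- sum(d2)
        if (denom <= 1e-12 * length(Rcur)) break
        fObs <- d2[1L] / denom       # = d_k^2 / sum_{j >= k} d_j^2 of R
        X <- t(Rcur)                 # n x m; each column = one feature's row
        exceed <- 0L
        for (b in seq_len(B)) {
            o <- order(colKey, stats::runif(length(X)))  # permute within row
            Xp <- matrix(X[o], nrow = n, ncol = m)
            M <- P %*% tcrossprod(Xp) %*% P   # re-residualized null spectrum
            ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
            if (ev[1L] / sum(pmax(ev, 0)) >= fObs) exceed <- exceed + 1L
        }
        p[k] <- (1 + exceed) / (B + 1)
        if (p[k] > alpha) break
        h <- k
        v <- sv$v[, 1L]              # re-orthogonalize against accepted trend
        Rcur <- Rcur - (Rcur %*% v) %*% t(v)
        P <- P - tcrossprod(v)
    }
    new("TrendSelection", h = h, method = "permutation", pValues = p,
        alpha = alpha, B = B,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        note = character())
}

#' @rdname permutationTrendTest
#' @param cells optional factor of design cells (length n); when given,
#'   permuted null replicates are re-residualized onto the orthocomplement
#'   of the cell-means space, matching the observed residuals. Filled in
#'   automatically for [ResidualFit] input.
#' @export
setMethod("permutationTrendTest", "matrix",
    function(object, B = 500L, alpha = 0.05, seed = NULL, hMax = NULL,
             cells = NULL, ...)
        .permutationTest(object, B, alpha, seed, hMax, cells))

#' @rdname permutationTrendTest
#' @export
setMethod("permutationTrendTest", "ResidualFit",
    function(object, B = 500L, alpha = 0.05, seed = NULL, hMax = NULL, ...)
        .permutationTest(residualMatrix(object), B, alpha, seed, hMax,
                         cells = object@cells))

#' Samples-fraction heuristic for the number of trends
#'
#' For metabolomics data, removing about 20\% of the number of samples as
#' bias trends tends to normalize better than the automatically selected
#' number (which works well for proteomics). `heuristicTrendCount()`
#' returns `round-half-up(fraction * n)`, at least 1 and capped at
#' `n - 2`; `heuristicTrendSelection()` wraps it in a [TrendSelection].
#'
#' @param n number of samples (>= 3).
#' @param fraction fraction of samples, in (0, 1); default 0.2.
#' @return integer trend count / a [TrendSelection].
#' @examples
#' heuristicTrendCount(10)  # 2
#' heuristicTrendCount(79)  # 16
#' @export
heuristicTrendCount <- function(n, fraction = 0.2) {
    if (!is.numeric(n) || length(n) != 1L || n < 3)
        stop("'n' must be a single integer >= 3")
    if (!(fraction > 0 && fraction < 1))
        stop("'fraction' must be in (0, 1)")
    h <- floor(fraction * n + 0.5)          # round half up
    as.integer(min(max(h, 1L), n - 2L))
}

#' @rdname heuristicTrendCount
#' @export
heuristicTrendSelection <- function(n, fraction = 0.2) {
    new("TrendSelection", h = heuristicTrendCount(n, fraction),
        method = "heuristic", pValues = numeric(), alpha = NA_real_,
        B = NA_integer_, seed = NA_integer_,
        note = sprintf("%.0f%% of %d samples", 100 * fraction, n))
}

#' @rdname heuristicTrendCount
#' @param h number of trends to remove, chosen by the analyst.
#' @export
manualTrendSelection <- function(h) {
    new("TrendSelection", h = as.integer(h), method = "manual",
        pValues = numeric(), alpha = NA_real_, B = NA_integer_,
        seed = NA_integer_, note = character())
}
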