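#' Per-feature Welch t-tests with Benjamini-Hochberg adjustment
#'
#' Compares the two levels of the primary factor feature by feature with
#' an unpaired Welch (unequal-variance) two-sample t-test on the observed
#' values, and adjusts the two-sided p-values across features with the
#' Benjamini-Hochberg step-up procedure. Features with fewer than two
#' observations in either group — or with zero variance in both groups
#' and unequal means — are marked untestable (`NA` p-value) rather than
#' dropped.
#'
#' @param x an [IntensityExperiment] with an attached design whose
#'   primary factor has exactly two levels (or supply `groups`).
#' @param groups optional two-level label vector overriding the design.
#' @return A data.frame with one row per feature: group means and
#'   observed counts, `t`, Welch `df`, raw `p`, and BH-adjusted `padj`.
#' @export
differentialTest <- function(x, groups = NULL) {
    stopifnot(is(x, "IntensityExperiment"))
    v <- intensityMatrix(x)
    if (is.null(groups)) groups <- designFactors(x)[[primaryFactor(x)]]
    groups <- factor(groups)
    if (nlevels(groups) != 2L)
        stop("the unpaired t-test needs exactly two group levels")
    i1 <- groups == levels(groups)[1L]
    i2 <- groups == levels(groups)[2L]
    s1 <- .groupStats(v[, i1, drop = FALSE])
    s2 <- .groupStats(v[, i2, drop = FALSE])
    se2 <- s1$var / s1$n + s2$var / s2$n
    t <- (s1$mean - s2$mean) / sqrt(se2)
    df <- se2^2 / (s1$var^2 / (s1$n^2 * (s1$n - 1)) +
                   s2$var^2 / (s2$n^2 * (s2$n - 1)))
    p <- 2 * stats::pt(-abs(t), df)
    # zero pooled standard error: equal means -> t = 0, p = 1; else untestable
    degen <- is.finite(s1$mean) & is.finite(s2$mean) & se2 == 0
    t[degen & s1$mean == s2$mean] <- 0
    p[degen & s1$mean == s2$mean] <- 1
    untestable <- s1$n < 2L | s2$n < 2L | (degen & s1$mean != s2$mean)
    t[untestable] <- NA_real_
    p[untestable] <- NA_real_
    df[untestable] <- NA_real_
    data.frame(feature = rownames(v),
               mean1 = s1$mean, mean2 = s2$mean,
               n1 = s1$n, n2 = s2$n,
               t = t, df = df, p = p, padj = bhAdjust(p),
               row.names = NULL, stringsAsFactors = FALSE)
}

.groupStats <- function(sub) {
    n <- rowSums(!is.na(sub))
    mean <- rowSums(sub, na.rm = TRUE) / n
    var <- rowSums((sub - mean)^2, na.rm = TRUE) / (n - 1L)
    mean[n == 0L] <- NA_real_
    var[n < 2L] <- NA_real_
    list(n = n, mean = mean, var = var)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts raw p-values for multiple testing controlling the false
#' discovery rate. `NA` entries pass through as `NA` and do not count
#' toward the number of tests.
#'
#' @param p numeric vector of raw p-values in [0, 1] (NA allowed).
#' @return vector of adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
    if (!is.numeric(p)) stop("'p' must be numeric")
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1))
        stop("p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(p))
    out[ok] <- stats::p.adjust(p[ok], method = "BH")
    out
}

#' Spearman correlation of features to sample covariates
#'
#' Correlates each feature's intensities with each numeric covariate
#' using Spearman's rank correlation on pairwise-complete observations
#' (ranks recomputed per pair, average-rank ties). Pairs with fewer than
#' `minPairs` complete observations, or with a constant vector after
#' deletion, are `NA`.
#'
#' @param x an [IntensityExperiment].
#' @param covariates data.frame of numeric covariates (default: the
#'   covariates attached to `x`).
#' @param features optional character vector restricting the features.
#' @param minPairs minimum complete pairs per correlation (default 3).
#' @return matrix of Spearman rho, features x covariates.
#' @export
spearmanToCovariates <- function(x, covariates = NULL, features = NULL,
                                 minPairs = 3L) {
    stopifnot(is(x, "IntensityExperiment"))
    if (is.null(covariates)) covariates <- sampleCovariates(x)
    covariates <- as.data.frame(covariates)
    if (!ncol(covariates)) stop("no covariates available")
    if (nrow(covariates) != ncol(x))
        stop("covariates must have one row per sample")
    v <- intensityMatrix(x)
    if (!is.null(features)) v <- v[features, , drop = FALSE]
    out <- matrix(NA_real_, nrow(v), ncol(covariates),
                  dimnames = list(rownames(v), colnames(covariates)))
    for (j in seq_len(ncol(covariates))) {
        z <- as.numeric(covariates[[j]])
        for (i in seq_len(nrow(v))) {
            ok <- !is.na(v[i, ]) & !is.na(z)
            if (sum(ok) < minPairs) next
            xi <- rank(v[i, ok]); zi <- rank(z[ok])
            if (stats::sd(xi) == 0 || stats::sd(zi) == 0) next
            out[i, j] <- stats::cor(xi, zi)
        }
    }
    out
}

#' Compare a raw and a normalized table
#'
#' The before/after report used to judge a normalization: per-feature
#' Welch tests with BH adjustment on both tables and the counts of
#' significant features at `alpha`; Spearman correlations of a feature
#' subset to each covariate in both tables (the paired lists behind a
#' raw-versus-normalized correlation scatter); and per-sample median
#' profiles in column (run) order (the data behind run-order boxplots).
#' The subset defaults to features with BH-adjusted p below
#' `subsetAdjP` in the *normalized* table.
#'
#' @param raw,norm [IntensityExperiment]s of matched shape with the same
#'   design.
#' @param alpha significance cutoff on the BH-adjusted p (default 0.05).
#' @param subsetAdjP adjusted-p threshold defining the correlation subset
#'   (default 0.001).
#' @param covariates optional covariate data.frame (default: those
#'   attached to `norm`).
#' @return list with `nSignificantRaw`, `nSignificantNorm`, the two
#'   differential tables, `correlations` (per covariate, a data.frame of
#'   paired raw/normalized rho), `subsetFeatures`, and `sampleMedians`.
#' @export
compareRawVsNormalized <- function(raw, norm, alpha = 0.05,
                                   subsetAdjP = 0.001, covariates = NULL) {
    stopifnot(is(raw, "IntensityExperiment"), is(norm, "IntensityExperiment"))
    if (!identical(dim(raw), dim(norm)))
        stop("'raw' and 'norm' must have matched shapes")
    dtRaw <- differentialTest(raw)
    dtNorm <- differentialTest(norm)
    if (is.null(covariates)) {
        covariates <- sampleCovariates(norm)
        if (!ncol(covariates)) covariates <- NULL
    }
    subset <- dtNorm$feature[!is.na(dtNorm$padj) & dtNorm$padj < subsetAdjP]
    correlations <- NULL
    if (!is.null(covariates) && length(subset)) {
        rhoRaw <- spearmanToCovariates(raw, covariates, features = subset)
        rhoNorm <- spearmanToCovariates(norm, covariates, features = subset)
        correlations <- lapply(colnames(rhoRaw), function(cv)
            data.frame(feature = subset, raw = rhoRaw[, cv],
                       normalized = rhoNorm[, cv], row.names = NULL))
        names(correlations) <- colnames(rhoRaw)
    }
    vRaw <- intensityMatrix(raw); vNorm <- intensityMatrix(norm)
    sampleMedians <- data.frame(
        sample = colnames(vRaw),
        raw = apply(vRaw, 2, stats::median, na.rm = TRUE),
        normalized = apply(vNorm, 2, stats::median, na.rm = TRUE),
        row.names = NULL)
    list(nSignificantRaw = sum(dtRaw$padj < alpha, na.rm = TRUE),
         nSignificantNorm = sum(dtNorm$padj < alpha, na.rm = TRUE),
         alpha = alpha,
         test = "Welch unpaired t, BH-adjusted",
         differentialRaw = dtRaw, differentialNorm = dtNorm,
         subsetFeatures = subset, subsetAdjP = subsetAdjP,
         correlations = correlations, sampleMedians = sampleMedians)
}
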