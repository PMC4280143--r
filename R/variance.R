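#' Variance accounting before and after normalization
#'
#' Reproduces the variance bookkeeping used to judge a normalization: for
#' each table the design ANOVA is (re-)fit, the residual matrix is
#' decomposed, and the report gives the variance fractions of the leading
#' residual trends together with the fraction of total (feature-centred)
#' variation attributable to the primary treatment factor. On raw data a
#' large top-trend fraction signals systematic bias (e.g. run-order signal
#' loss); after successful normalization the top trends drop toward the
#' noise floor while the treatment fraction is preserved.
#'
#' The treatment fraction is `SS_between / SS_total`, where `SS_between`
#' sums, over observed cells, the squared deviation of the feature's
#' primary-factor group mean from its overall mean, and `SS_total` the
#' squared deviation of the observed value from the feature's overall
#' mean.
#'
#' @param before,after [IntensityExperiment]s of matched shape, with the
#'   same attached design.
#' @param nTop number of leading trend fractions to report (default 3).
#' @return data.frame with one row per table (`before`, `after`) and
#'   columns `trendVar1..nTop`, `primaryFactorFraction`.
#' @export
summarizeVarianceShift <- function(before, after, nTop = 3L) {
    stopifnot(is(before, "IntensityExperiment"),
              is(after, "IntensityExperiment"))
    if (!identical(dim(before), dim(after)))
        stop("'before' and 'after' must have matched shapes")
    one <- function(x) {
        fit <- fitANOVA(x, requireLog = FALSE)
        dec <- decomposeResiduals(fit)
        ve <- varianceExplained(dec)
        top <- ve[seq_len(min(nTop, length(ve)))]
        length(top) <- nTop                      # pad with NA
        c(top, primary = .primaryFactorFraction(x))
    }
    out <- rbind(before = one(before), after = one(after))
    colnames(out) <- c(paste0("trendVar", seq_len(nTop)),
                       "primaryFactorFraction")
    as.data.frame(out)
}

.primaryFactorFraction <- function(x) {
    v <- intensityMatrix(x)
    g <- factor(designFactors(x)[[primaryFactor(x)]])
    rowMean <- rowMeans(v, na.rm = TRUE)
    centred <- v - rowMean
    ssTotal <- sum(centred^2, na.rm = TRUE)
    if (ssTotal == 0) return(0)
    ssBetween <- 0
    for (lev in levels(g)) {
        idx <- which(g == lev)
        sub <- v[, idx, drop = FALSE]
        cnt <- rowSums(!is.na(sub))
        mu <- rowSums(sub, na.rm = TRUE) / cnt
        dev <- (mu - rowMean)^2 * cnt
        ssBetween <- ssBetween + sum(dev[cnt > 0])
    }
    ssBetween / ssTotal
}
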