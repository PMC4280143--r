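#' Treatment-preserving SVD normalization in one call
#'
#' Runs the full normalization pipeline on a log-scale feature table with
#' an attached design: per-feature cell-means ANOVA, SVD of the residual
#' matrix, selection of the number of bias trends, and trend removal.
#'
#' Trend-count selection: `trends = "heuristic"` (default) uses
#' `fraction` of the number of samples (about 20\%, the choice that tends
#' to normalize metabolomics data better); `"permutation"` runs the
#' step-down permutation test; an integer removes exactly that many
#' trends (`0` returns the input unchanged).
#'
#' @param x an [IntensityExperiment] (log scale) with attached design.
#' @param trends `"heuristic"`, `"permutation"`, or a non-negative
#'   integer.
#' @param fraction samples fraction for the heuristic (default 0.2).
#' @param B,alpha,hMax permutation-test parameters, see
#'   [permutationTrendTest()].
#' @param seed integer seed for the permutation stream.
#' @return A [NormalizationResult]; the [TrendSelection] actually used is
#'   available as `result@selection`.
#' @examples
#' sim <- simulateIntensities(simulationConfig(m = 60, n = 12, seed = 1,
#'     trendSpecs = list(trendSpec("linear_drift", varianceFraction = 0.3))))
#' res <- eigenNormalize(sim$table, trends = 1)
#' res
#' @export
eigenNormalize <- function(x, trends = c("heuristic", "permutation"),
                           fraction = 0.2, B = 500L, alpha = 0.05,
                           seed = NULL, hMax = NULL) {
    stopifnot(is(x, "IntensityExperiment"))
    fit <- fitANOVA(x)
    dec <- decomposeResiduals(fit)
    sel <- if (is.numeric(trends)) {
        manualTrendSelection(trends)
    } else {
        switch(match.arg(trends),
            heuristic = heuristicTrendSelection(ncol(x), fraction),
            permutation = permutationTrendTest(fit, B = B, alpha = alpha,
                                               seed = seed, hMax = hMax))
    }
    removeTrends(x, fit, dec, sel)
}

#' Write a JSON trend report
#'
#' Serializes a trend selection and decomposition (number of trends,
#' method, per-trend variance fractions, permutation p-values, seed, B)
#' to JSON, and optionally the trend matrix `V` as delimited text for
#' plotting sample-indexed trend panels.
#'
#' @param selection a [TrendSelection].
#' @param decomposition a [ResidualDecomposition].
#' @param path output JSON path.
#' @param trendsPath optional path for the V matrix as TSV.
#' @return `path`, invisibly.
#' @export
writeTrendReport <- function(selection, decomposition, path,
                             trendsPath = NULL) {
    rep <- list(
        h = selection@h,
        method = selection@method,
        alpha = selection@alpha,
        B = selection@B,
        seed = selection@seed,
        pValues = selection@pValues,
        varExplained = decomposition@varExplained,
        note = c(selection@note, decomposition@note))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    if (!is.null(trendsPath)) {
        V <- trendMatrix(decomposition)
        df <- data.frame(sample = rownames(V) %||% seq_len(nrow(V)), V,
                         check.names = FALSE)
        utils::write.table(df, trendsPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records everything needed to re-run a normalization: resolved
#' parameters, seeds, package version, md5 digests of the input files,
#' stage timings and warnings.
#'
#' @param path output JSON path.
#' @param parameters named list of resolved parameters.
#' @param inputs character vector of input file paths (digested).
#' @param timings named numeric vector of stage timings in seconds.
#' @param warnings character vector of warnings raised.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(path, parameters = list(), inputs = character(),
                             timings = numeric(), warnings = character()) {
    digests <- if (length(inputs)) {
        as.list(tools::md5sum(inputs))
    } else list()
    manifest <- list(
        package = "eigenTrend",
        version = as.character(utils::packageVersion("eigenTrend")),
        parameters = parameters,
        inputDigests = digests,
        timingsSec = as.list(timings),
        warnings = warnings)
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    invisible(path)
}
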