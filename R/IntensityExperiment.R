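#' Construct an IntensityExperiment
#'
#' Wraps a feature-by-sample numeric matrix (features in rows) into an
#' [IntensityExperiment]. Unobserved cells are `NA`. Optionally attaches a
#' sample design (treatment groups and further fixed-effect factors) and
#' numeric covariates; see [attachSampleData()] for attaching them to an
#' existing object with order checking.
#'
#' @param values numeric matrix, m features x n samples, with rownames
#'   (feature ids) and colnames (sample ids).
#' @param scale `"raw"` or `"log"`; whether values are raw or log intensities.
#' @param design optional data.frame of categorical factors, one row per
#'   sample in column order of `values`.
#' @param primaryFactor name of the treatment factor within `design`
#'   (default: its first column).
#' @param covariates optional data.frame of numeric sample covariates.
#' @return An [IntensityExperiment].
#' @examples
#' m <- matrix(rnorm(12, 15), 3, 4,
#'             dimnames = list(paste0("F", 1:3), paste0("S", 1:4)))
#' ie <- IntensityExperiment(m, scale = "log",
#'                           design = data.frame(group = c("a","a","b","b")))
#' primaryFactor(ie)
#' @export
IntensityExperiment <- function(values, scale = c("raw", "log"),
                                design = NULL, primaryFactor = NULL,
                                covariates = NULL) {
    scale <- match.arg(scale)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    cd <- S4Vectors::DataFrame(row.names = colnames(values))
    md <- list(factors = character(), primaryFactor = NA_character_,
               covariates = character())
    if (!is.null(design)) {
        design <- as.data.frame(design)
        if (nrow(design) != ncol(values))
            stop("design must have one row per sample")
        design[] <- lapply(design, function(f) {
            f <- factor(f)
            if (nlevels(droplevels(f)) < 1L)
                stop("every design factor needs at least one level")
            droplevels(f)
        })
        if (is.null(primaryFactor)) primaryFactor <- names(design)[1L]
        if (!primaryFactor %in% names(design))
            stop("primaryFactor '", primaryFactor, "' is not a design column")
        for (nm in names(design)) cd[[nm]] <- design[[nm]]
        md$factors <- names(design)
        md$primaryFactor <- primaryFactor
    }
    if (!is.null(covariates)) {
        covariates <- as.data.frame(covariates)
        if (nrow(covariates) != ncol(values))
            stop("covariates must have one row per sample")
        for (nm in names(covariates)) cd[[nm]] <- as.numeric(covariates[[nm]])
        md$covariates <- names(covariates)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = values), colData = cd)
    S4Vectors::metadata(se) <- md
    new("IntensityExperiment", se, scale = scale)
}

#' Access the intensity matrix, mask and scale
#'
#' `intensityMatrix()` returns the m x n matrix of intensities (`NA` where
#' unobserved); `observedMask()` the logical matrix that is `TRUE` where a
#' value was observed; `intensityScale()` the `"raw"`/`"log"` flag.
#'
#' @param x an [IntensityExperiment].
#' @param ... unused.
#' @return A matrix, logical matrix, or character scalar respectively.
#' @name intensityMatrix
#' @aliases observedMask intensityScale
NULL

#' @rdname intensityMatrix
#' @export
setMethod("intensityMatrix", "IntensityExperiment",
    function(x, ...) SummarizedExperiment::assay(x, "intensity"))

#' @rdname intensityMatrix
#' @export
setMethod("observedMask", "IntensityExperiment",
    function(x, ...) !is.na(SummarizedExperiment::assay(x, "intensity")))

#' @rdname intensityMatrix
#' @export
setMethod("intensityScale", "IntensityExperiment", function(x) x@scale)

#' Access the sample design and covariates
#'
#' `designFactors()` returns the data.frame of fixed-effect factors (one
#' row per sample), `primaryFactor()` the name of the treatment factor,
#' and `sampleCovariates()` the data.frame of numeric covariates (possibly
#' zero columns).
#'
#' @param x an [IntensityExperiment].
#' @return data.frame / character scalar / data.frame.
#' @name designAccessors
#' @aliases primaryFactor sampleCovariates
NULL

#' @rdname designAccessors
#' @export
setMethod("designFactors", "IntensityExperiment", function(x) {
    nms <- S4Vectors::metadata(x)$factors
    if (is.null(nms) || !length(nms))
        stop("no design attached; use attachSampleData()")
    as.data.frame(SummarizedExperiment::colData(x)[, nms, drop = FALSE])
})

#' @rdname designAccessors
#' @export
setMethod("primaryFactor", "IntensityExperiment", function(x) {
    pf <- S4Vectors::metadata(x)$primaryFactor
    if (is.null(pf) || is.na(pf)) stop("no primary factor recorded")
    pf
})

#' @rdname designAccessors
#' @export
setMethod("sampleCovariates", "IntensityExperiment", function(x) {
    nms <- S4Vectors::metadata(x)$covariates
    if (is.null(nms)) nms <- character()
    as.data.frame(SummarizedExperiment::colData(x)[, nms, drop = FALSE])
})

setMethod("show", "IntensityExperiment", function(object) {
    v <- intensityMatrix(object)
    cat("IntensityExperiment:", nrow(v), "features x", ncol(v), "samples\n")
    cat("  scale:", object@scale,
        sprintf(" | missing: %.1f%%\n", 100 * mean(is.na(v))))
    md <- S4Vectors::metadata(object)
    if (length(md$factors))
        cat("  factors:", paste(md$factors, collapse = ", "),
            sprintf("(primary: %s)\n", md$primaryFactor))
    if (length(md$covariates))
        cat("  covariates:", paste(md$covariates, collapse = ", "), "\n")
})

#' Log-transform a raw-scale intensity table
#'
#' Applies `log_base(value + offset)` to every observed cell of a
#' raw-scale table. Observed cells with `value + offset <= 0` cannot be
#' transformed: they become unobserved, and the number of such newly
#' masked cells is recorded in `metadata(x)$nNonPositiveMasked` and
#' reported via a warning.
#'
#' @param x an [IntensityExperiment] with `intensityScale(x) == "raw"`.
#' @param base logarithm base, > 1 (default 2, the usual scale for
#'   fold-change interpretation of LC-MS intensities).
#' @param offset value added before taking logs (default 0).
#' @return An [IntensityExperiment] with `scale == "log"`.
#' @export
logTransform <- function(x, base = 2, offset = 0) {
    stopifnot(is(x, "IntensityExperiment"))
    if (intensityScale(x) != "raw")
        stop("table is already on the log scale")
    if (!is.numeric(base) || length(base) != 1L || base <= 1)
        stop("'base' must be a single number > 1")
    v <- intensityMatrix(x)
    bad <- !is.na(v) & (v + offset) <= 0
    nBad <- sum(bad)
    v[bad] <- NA_real_
    v[!is.na(v)] <- log(v[!is.na(v)] + offset, base = base)
    SummarizedExperiment::assay(x, "intensity") <- v
    x@scale <- "log"
    S4Vectors::metadata(x)$nNonPositiveMasked <- nBad
    S4Vectors::metadata(x)$logBase <- base
    S4Vectors::metadata(x)$logOffset <- offset
    if (nBad > 0L)
        warning(nBad, " non-positive cell(s) masked during log transform")
    validObject(x)
    x
}

#' Attach and align sample design and covariates
#'
#' Matches a design table (and optionally a covariate table) to the sample
#' order of an intensity table by sample id, reordering the metadata rows
#' if needed. Samples present in the table but absent from the design are
#' an error; extra design rows are dropped with a note. The alignment
#' report (reordering applied, dropped rows) is stored in
#' `metadata(x)$alignment` and returned invisibly alongside the object.
#'
#' @param x an [IntensityExperiment].
#' @param design data.frame of factors; sample ids in `rownames` or in a
#'   column named `sample`.
#' @param covariates optional data.frame of numeric covariates, keyed the
#'   same way.
#' @param primaryFactor name of the treatment factor (default: first
#'   design column).
#' @return The [IntensityExperiment] with design/covariates in `colData`
#'   and the alignment report in `metadata(x)$alignment`.
#' @export
attachSampleData <- function(x, design, covariates = NULL,
                             primaryFactor = NULL) {
    stopifnot(is(x, "IntensityExperiment"))
    sid <- colnames(x)
    design <- .keyedFrame(design, "design")
    missing <- setdiff(sid, rownames(design))
    if (length(missing))
        stop("sample(s) missing from design: ", paste(missing, collapse = ", "))
    extra <- setdiff(rownames(design), sid)
    perm <- match(sid, rownames(design))
    report <- list(
        reordered = !identical(perm, seq_along(sid)),
        permutation = perm,
        droppedFromDesign = extra)
    design <- design[perm, , drop = FALSE]
    covFrame <- NULL
    if (!is.null(covariates)) {
        covariates <- .keyedFrame(covariates, "covariates")
        cmissing <- setdiff(sid, rownames(covariates))
        if (length(cmissing))
            stop("sample(s) missing from covariates: ",
                 paste(cmissing, collapse = ", "))
        covFrame <- covariates[match(sid, rownames(covariates)), , drop = FALSE]
    }
    out <- IntensityExperiment(intensityMatrix(x), scale = intensityScale(x),
                               design = design, primaryFactor = primaryFactor,
                               covariates = covFrame)
    md <- S4Vectors::metadata(x)
    keep <- setdiff(names(md), c("factors", "primaryFactor", "covariates"))
    for (nm in keep) S4Vectors::metadata(out)[[nm]] <- md[[nm]]
    S4Vectors::metadata(out)$alignment <- report
    out
}

# a data.frame keyed by sample id: rownames, or a 'sample' id column
.keyedFrame <- function(df, what) {
    df <- as.data.frame(df)
    if ("sample" %in% names(df)) {
        rn <- as.character(df$sample)
        df$sample <- NULL
        rownames(df) <- rn
    }
    if (is.null(rownames(df)) ||
        identical(rownames(df), as.character(seq_len(nrow(df)))))
        stop(what, " must be keyed by sample id ",
             "(rownames or a 'sample' column)")
    if (anyDuplicated(rownames(df)))
        stop("duplicated sample ids in ", what)
    df
}
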