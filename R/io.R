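#' Read a delimited feature table
#'
#' Reads a feature-by-sample intensity table from delimited text: first
#' column holds the feature ids, the header row the sample ids. The
#' delimiter is auto-detected between tab and comma unless given;
#' ambiguous files (both delimiters present in the header) are rejected
#' rather than guessed. Cells matching one of `missingCodes` become
#' unobserved (`NA`); zeros are treated as true low intensities unless
#' `zeroAsMissing = TRUE` (XCMS-style tables may contain genuine zeros).
#'
#' @param path path to a TSV/CSV file.
#' @param missingCodes character cell values treated as missing.
#' @param zeroAsMissing logical; additionally treat `0` as missing.
#' @param delim `"\t"`, `","`, or `NULL` to auto-detect.
#' @param scale `"raw"` (default) or `"log"`, recorded on the table.
#' @return An [IntensityExperiment].
#' @seealso [writeFeatureTable()], [readSampleData()]
#' @export
readFeatureTable <- function(path, missingCodes = c("", "NA", "NaN"),
                             zeroAsMissing = FALSE, delim = NULL,
                             scale = c("raw", "log")) {
    scale <- match.arg(scale)
    if (!file.exists(path)) stop("file not found: ", path)
    delim <- delim %||% .detectDelim(path)
    df <- utils::read.table(path, sep = delim, header = TRUE,
                            check.names = FALSE, colClasses = "character",
                            na.strings = NULL, quote = "\"",
                            comment.char = "", fill = FALSE)
    if (ncol(df) < 2L) stop("feature table needs an id column and >= 1 sample")
    fid <- df[[1L]]
    sid <- colnames(df)[-1L]
    if (anyDuplicated(fid))
        stop("duplicated feature id(s): ",
             paste(unique(fid[duplicated(fid)]), collapse = ", "))
    if (anyDuplicated(sid))
        stop("duplicated sample id(s) in header: ",
             paste(unique(sid[duplicated(sid)]), collapse = ", "))
    vals <- as.matrix(df[, -1L, drop = FALSE])
    vals[vals %in% missingCodes] <- NA
    num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
    badCells <- !is.na(vals) & is.na(num)
    if (any(badCells))
        stop("non-numeric cell(s) not covered by missingCodes, e.g. '",
             vals[which(badCells)[1L]], "'")
    if (zeroAsMissing) num[!is.na(num) & num == 0] <- NA_real_
    dimnames(num) <- list(fid, sid)
    if (all(is.na(num))) stop("table contains no observed values")
    IntensityExperiment(num, scale = scale)
}

#' Write a feature table as delimited text
#'
#' Inverse of [readFeatureTable()]: writes the intensity matrix with the
#' feature-id column first and sample ids as header, preserving column
#' order. Unobserved cells are written as `NA`. Values are written with
#' full precision (`format = "%.17g"` equivalent) so a read/write
#' round-trip is lossless.
#'
#' @param x an [IntensityExperiment].
#' @param path output path.
#' @param delim field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(x, path, delim = "\t") {
    stopifnot(is(x, "IntensityExperiment"))
    v <- intensityMatrix(x)
    chr <- array(NA_character_, dim = dim(v))
    obs <- !is.na(v)
    chr[obs] <- sprintf("%.17g", v[obs])
    df <- data.frame(feature = rownames(v), chr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("feature", colnames(v))
    utils::write.table(df, path, sep = delim, quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Read a sample-metadata table
#'
#' Reads a delimited table keyed by sample id (first column, or a column
#' named `sample`). Used for both the design (factor columns) and the
#' covariate table (numeric columns). The delimiter is auto-detected
#' unless given.
#'
#' @param path path to a delimited text file.
#' @param delim `"\t"`, `","`, or `NULL` to auto-detect.
#' @return data.frame with sample ids as rownames.
#' @export
readSampleData <- function(path, delim = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    delim <- delim %||% .detectDelim(path)
    df <- utils::read.table(path, sep = delim, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "\"", comment.char = "")
    if (ncol(df) < 2L) stop("sample table needs an id column and >= 1 column")
    key <- if ("sample" %in% names(df)) "sample" else names(df)[1L]
    ids <- as.character(df[[key]])
    if (anyDuplicated(ids))
        stop("duplicated sample id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    df[[key]] <- NULL
    rownames(df) <- ids
    df
}

.detectDelim <- function(path) {
    header <- readLines(path, n = 1L)
    nTab <- lengths(regmatches(header, gregexpr("\t", header)))
    nCom <- lengths(regmatches(header, gregexpr(",", header)))
    if (nTab > 0L && nCom > 0L)
        stop("ambiguous delimiter (header contains both tab and comma); ",
             "pass 'delim' explicitly")
    if (nTab > 0L) return("\t")
    if (nCom > 0L) return(",")
    stop("could not detect delimiter in ", path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
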