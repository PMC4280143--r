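# shared builders for small in-code fixtures

makeTable <- function(values, groups = NULL, scale = "log", ...) {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("F%02d", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
    design <- if (is.null(groups)) NULL else data.frame(group = groups)
    IntensityExperiment(values, scale = scale, design = design, ...)
}

randomMatrix <- function(m, n, missingRate = 0, seed = 1) {
    set.seed(seed)
    v <- matrix(rnorm(m * n, mean = 15, sd = 2), m, n,
                dimnames = list(sprintf("F%03d", seq_len(m)),
                                sprintf("S%03d", seq_len(n))))
    if (missingRate > 0)
        v[matrix(runif(m * n) < missingRate, m, n)] <- NA_real_
    v
}

balancedGroups <- function(n) rep(c("A", "B"), length.out = n)
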