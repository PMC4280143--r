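#' Specify one injected bias trend
#'
#' Describes a systematic trend for the synthetic-data generator. Shapes
#' mirror the biases seen in multi-day LC-MS runs: `"linear_drift"` is a
#' within-day sawtooth (signal intensity declining over each day's run
#' order), `"day_step"` a between-day batch step, `"sine"` a smooth
#' low-frequency unknown bias, `"custom"` any user-supplied sample
#' vector. Amplitude is set either directly through `loadingSd` (the SD
#' of per-feature loadings on the unit-norm trend) or through
#' `varianceFraction`, the target fraction of residual-matrix variance
#' the trend should carry (calibrated against the noise level; requires
#' `noiseSd > 0`).
#'
#' @param shape one of `"linear_drift"`, `"day_step"`, `"sine"`,
#'   `"custom"`.
#' @param varianceFraction target residual-variance fraction in (0, 1),
#'   or `NULL` when `loadingSd` is given.
#' @param loadingSd SD of per-feature loadings, or `NULL` to derive it
#'   from `varianceFraction`.
#' @param vector length-n sample vector for `shape = "custom"`.
#' @param zeroFraction fraction of features with exactly zero loading on
#'   this trend (drift affects features heterogeneously).
#' @return A `trendSpec` list.
#' @export
trendSpec <- function(shape = c("linear_drift", "day_step", "sine", "custom"),
                      varianceFraction = NULL, loadingSd = NULL,
                      vector = NULL, zeroFraction = 0) {
    shape <- match.arg(shape)
    if (is.null(varianceFraction) && is.null(loadingSd))
        stop("give either 'varianceFraction' or 'loadingSd'")
    if (!is.null(varianceFraction) &&
        !(varianceFraction > 0 && varianceFraction < 1))
        stop("'varianceFraction' must be in (0, 1)")
    if (shape == "custom" && is.null(vector))
        stop("'custom' shape needs a 'vector'")
    if (!(zeroFraction >= 0 && zeroFraction < 1))
        stop("'zeroFraction' must be in [0, 1)")
    structure(list(shape = shape, varianceFraction = varianceFraction,
                   loadingSd = loadingSd, vector = vector,
                   zeroFraction = zeroFraction), class = "trendSpec")
}

#' Configure the synthetic LC-MS feature-table generator
#'
#' Defaults describe a desk-scale two-group serum metabolomics study run
#' over five instrument days: m = 1000 peaks, n = 80 samples in two
#' balanced groups with run order randomized, true group log2-fold-changes
#' of SD 0.5 on 10\% of features, unit log2 residual noise, and three
#' orthogonalized bias trends — within-day signal-loss drift, a
#' between-day batch step, and a smooth sine — carrying 20\%, 10\% and
#' 5\% of the residual variance. A clinical covariate correlated with
#' group (rho 0.6) is generated alongside. Missingness is off by default
#' and can be switched on with `missingRate` (> 0), optionally
#' intensity-dependent via `mnarStrength`.
#'
#' @param m number of features (>= 10).
#' @param n number of samples (>= 6).
#' @param groups optional explicit group label vector of length n;
#'   default balanced two groups in randomized order.
#' @param effectSd SD of true group log2-fold-changes.
#' @param effectFraction fraction of features with a true group effect.
#' @param baselineMean,baselineSd distribution of per-feature baseline
#'   log2 intensities.
#' @param trendSpecs list of [trendSpec()]s (possibly empty).
#' @param days number of instrument days for drift/step shapes.
#' @param noiseSd SD of the residual noise (log2 scale).
#' @param missingRate overall missingness probability in [0, 1).
#' @param mnarStrength intensity dependence of missingness: logit-scale
#'   slope on the (descending) value rank; 0 = missing completely at
#'   random.
#' @param covariateCor correlation of the simulated clinical covariate
#'   with group membership (`NULL` or 0 for none).
#' @param seed integer seed; fully determines the output.
#' @return A validated `SimulationConfig` list.
#' @seealso [simulateIntensities()]
#' @export
simulationConfig <- function(m = 1000L, n = 80L, groups = NULL,
                             effectSd = 0.5, effectFraction = 0.1,
                             baselineMean = 18, baselineSd = 1.5,
                             trendSpecs = list(
                                 trendSpec("linear_drift", varianceFraction = 0.20),
                                 trendSpec("day_step", varianceFraction = 0.10),
                                 trendSpec("sine", varianceFraction = 0.05)),
                             days = 5L, noiseSd = 1,
                             missingRate = 0, mnarStrength = 0,
                             covariateCor = 0.6, seed = 1L) {
    m <- as.integer(m); n <- as.integer(n)
    if (m < 10L) stop("'m' must be >= 10")
    if (n < 6L) stop("'n' must be >= 6")
    if (!is.null(groups) && length(groups) != n)
        stop("'groups' must have length n")
    if (length(trendSpecs) >= n)
        stop("requested trend count must be smaller than n")
    if (!all(vapply(trendSpecs, inherits, logical(1), "trendSpec")))
        stop("'trendSpecs' must be a list of trendSpec() objects")
    if (!(missingRate >= 0 && missingRate < 1))
        stop("'missingRate' must be in [0, 1)")
    if (effectFraction < 0 || effectFraction > 1)
        stop("'effectFraction' must be in [0, 1]")
    if (noiseSd < 0) stop("'noiseSd' must be >= 0")
    fr <- unlist(lapply(trendSpecs, `[[`, "varianceFraction"))
    if (length(fr) && sum(fr) >= 1)
        stop("trend variance fractions must sum to < 1")
    needCalib <- vapply(trendSpecs,
                        function(s) is.null(s$loadingSd), logical(1))
    if (any(needCalib) && noiseSd == 0)
        stop("varianceFraction calibration needs noiseSd > 0; ",
             "give loadingSd directly instead")
    structure(list(m = m, n = n, groups = groups, effectSd = effectSd,
                   effectFraction = effectFraction,
                   baselineMean = baselineMean, baselineSd = baselineSd,
                   trendSpecs = trendSpecs, days = as.integer(days),
                   noiseSd = noiseSd, missingRate = missingRate,
                   mnarStrength = mnarStrength,
                   covariateCor = covariateCor,
                   seed = as.integer(seed)),
              class = "SimulationConfig")
}

#' Run-order trend shapes
#'
#' Builds the two canonical run-order bias vectors for an experiment of
#' `n` samples over `days` instrument days: a within-day sawtooth drift
#' (linear signal loss over each day's injections) and a between-day step
#' vector. Both are centred and unit-norm; the step vector is omitted for
#' a single day (it would be constant).
#'
#' @param n number of samples (>= days).
#' @param days number of days (>= 1).
#' @return named list with elements `drift` and (if `days > 1`) `dayStep`.
#' @export
makeRunOrderTrends <- function(n, days = 1L) {
    n <- as.integer(n); days <- as.integer(days)
    if (days < 1L || n < days) stop("need days >= 1 and n >= days")
    day <- rep(seq_len(days), each = ceiling(n / days), length.out = n)
    withinIdx <- stats::ave(seq_len(n), day, FUN = seq_along)
    daySize <- stats::ave(seq_len(n), day, FUN = length)
    drift <- -(withinIdx - (daySize + 1) / 2)     # declining within each day
    out <- list(drift = .centerUnit(drift))
    if (days > 1L) out$dayStep <- .centerUnit(as.numeric(day))
    out
}

.centerUnit <- function(v) {
    v <- v - mean(v)
    nrm <- sqrt(sum(v^2))
    if (nrm == 0) stop("degenerate (constant) trend vector")
    v / nrm
}

#' Orthonormalize trend columns
#'
#' Gram-Schmidt in column order: each column is centred, projected out of
#' the span of its predecessors, and scaled to unit norm.
#'
#' @param V n x K matrix of trend columns.
#' @return n x K matrix with orthonormal, centred columns.
#' @export
orthonormalizeTrends <- function(V) {
    V <- as.matrix(V)
    for (k in seq_len(ncol(V))) {
        v <- V[, k] - mean(V[, k])
        if (k > 1L) {
            prev <- V[, seq_len(k - 1L), drop = FALSE]
            v <- v - prev %*% crossprod(prev, v)
        }
        nrm <- sqrt(sum(v^2))
        if (nrm < 1e-10)
            stop("trend column ", k, " is linearly dependent on its ",
                 "predecessors")
        V[, k] <- as.numeric(v) / nrm
    }
    V
}

#' Generate a synthetic feature table with known truth
#'
#' Draws a log-scale feature table from the additive model
#' `x_ij = mu_i + gamma_i * group_j + sum_k beta_ik v_kj + eps_ij`:
#' per-feature baselines, group log2-fold-changes on a subset of
#' features, heterogeneous per-feature loadings on orthonormalized bias
#' trends (injected on the log scale, i.e. multiplicative signal loss on
#' the raw scale), and Gaussian noise. Missingness, when enabled, is
#' applied after signal generation; with `mnarStrength > 0` lower values
#' are more likely to be masked (logistic model on the value rank),
#' emulating intensity-dependent LC-MS missingness. The seed fully
#' determines the output.
#'
#' Trend amplitudes requested as `varianceFraction` f are calibrated so
#' that the trend carries about f of the ANOVA-residual variance:
#' `loadingSd^2 = f / (1 - sum(f)) * n * noiseSd^2 / (1 - zeroFraction)`.
#'
#' @param config a [simulationConfig()].
#' @return list with elements `table` (an [IntensityExperiment], log
#'   scale, design and covariate attached), `truth` (baselines, true
#'   effects, trends, loadings, noise, mask, and the complete pre-masking
#'   matrix), and `config`.
#' @examples
#' sim <- simulateIntensities(simulationConfig(m = 50, n = 12, seed = 7,
#'     trendSpecs = list(), noiseSd = 0.5))
#' sim$table
#' @export
simulateIntensities <- function(config = simulationConfig()) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    m <- config$m; n <- config$n
    if (is.null(config$groups)) {
        groups <- factor(sample(rep(c("control", "case"), length.out = n)),
                         levels = c("control", "case"))
    } else {
        groups <- factor(config$groups)
    }
    if (nlevels(groups) < 2L)
        stop("the design needs at least two group levels")
    lev2 <- levels(groups)[2L]
    gInd <- as.numeric(groups == lev2)

    baseline <- stats::rnorm(m, config$baselineMean, config$baselineSd)
    effects <- numeric(m)
    nEff <- round(config$effectFraction * m)
    effIdx <- if (nEff > 0) sample.int(m, nEff) else integer()
    if (nEff > 0) effects[effIdx] <- stats::rnorm(nEff, 0, config$effectSd)

    K <- length(config$trendSpecs)
    V <- matrix(numeric(0), nrow = n, ncol = 0)
    loadings <- matrix(numeric(0), nrow = m, ncol = 0)
    if (K > 0L) {
        shapes <- makeRunOrderTrends(n, config$days)
        raw <- vapply(config$trendSpecs, function(s) {
            switch(s$shape,
                linear_drift = shapes$drift,
                day_step = {
                    if (is.null(shapes$dayStep))
                        stop("'day_step' needs days > 1")
                    shapes$dayStep
                },
                sine = sin(2 * pi * 2 * seq_len(n) / n),
                custom = as.numeric(s$vector))
        }, numeric(n))
        # matched-block design: run-order biases are balanced across the
        # treatment groups, so injected trends are centred within each group
        # (no confounding of bias with the treatment effect)
        for (lev in levels(groups)) {
            idx <- groups == lev
            raw[idx, ] <- sweep(raw[idx, , drop = FALSE], 2,
                                colMeans(raw[idx, , drop = FALSE]))
        }
        V <- orthonormalizeTrends(raw)
        fr <- vapply(config$trendSpecs, function(s)
            s$varianceFraction %||% NA_real_, numeric(1))
        sumFr <- sum(fr, na.rm = TRUE)
        loadings <- matrix(0, m, K)
        for (k in seq_len(K)) {
            s <- config$trendSpecs[[k]]
            ls <- s$loadingSd %||%
                sqrt(fr[k] / (1 - sumFr) * n * config$noiseSd^2 /
                     (1 - s$zeroFraction))
            beta <- stats::rnorm(m, 0, ls)
            if (s$zeroFraction > 0)
                beta[sample.int(m, round(s$zeroFraction * m))] <- 0
            loadings[, k] <- beta
        }
    }
    noise <- matrix(stats::rnorm(m * n, 0, config$noiseSd), m, n)
    values <- baseline + outer(effects, gInd) + noise
    if (K > 0L) values <- values + loadings %*% t(V)
    dimnames(values) <- list(sprintf("F%04d", seq_len(m)),
                             sprintf("S%03d", seq_len(n)))

    covariates <- NULL
    rho <- config$covariateCor %||% 0
    if (!is.na(rho) && rho != 0) {
        gStd <- (gInd - mean(gInd)) / stats::sd(gInd)
        z <- rho * gStd + sqrt(1 - rho^2) * stats::rnorm(n)
        covariates <- data.frame(covariate = z)
    }

    observed <- matrix(TRUE, m, n)
    masked <- values
    if (config$missingRate > 0) {
        rk <- rank(values, ties.method = "first") / (m * n + 1)
        pMiss <- stats::plogis(stats::qlogis(config$missingRate) +
                               config$mnarStrength * (0.5 - rk))
        observed <- matrix(stats::runif(m * n) >= pMiss, m, n)
        masked[!observed] <- NA_real_
        if (all(!observed)) stop("missingness masked every value")
    }
    table <- IntensityExperiment(masked, scale = "log",
                                 design = data.frame(group = groups),
                                 primaryFactor = "group",
                                 covariates = covariates)
    truth <- list(baseline = baseline, trueEffects = effects,
                  effectIdx = sort(effIdx), groupLevels = levels(groups),
                  trueTrends = V, trueLoadings = loadings, noise = noise,
                  observed = observed, complete = values,
                  covariate = if (is.null(covariates)) NULL else
                      covariates$covariate)
    list(table = table, truth = truth, config = config)
}
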