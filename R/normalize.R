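#' @importFrom stats loess loess.control quantile
NULL

.geomean1 <- function(x) x / exp(mean(log(x)))

.getCounts <- function(counts) {
    if (is(counts, "AtacCountExperiment"))
        SummarizedExperiment::assay(counts, "counts")
    else as.matrix(counts)
}

.getLibSizes <- function(counts, libSizes = NULL) {
    if (!is.null(libSizes))
        return(libSizes)
    if (is(counts, "AtacCountExperiment"))
        libSizes(counts)
    else colSums(.getCounts(counts))
}

#' Full-library-size scale factors
#'
#' Linear scaling by total library size: s_i proportional to L_i,
#' renormalized to unit geometric mean.  This method assumes any global
#' accessibility difference between conditions may be real and technical
#' bias is small, so global shifts are preserved in the DA output.
#'
#' @param counts An \linkS4class{AtacCountExperiment} or count matrix.
#' @param libSizes Full-library fragment totals; defaults to the object's
#'   library sizes.
#' @return A \linkS4class{NormalizationResult} with factors and effective
#'   library sizes equal to \code{libSizes}.
#' @export
normLibsize <- function(counts, libSizes = NULL) {
    L <- .getLibSizes(counts, libSizes)
    stopifnot(all(L > 0))
    s <- .geomean1(L)
    new("NormalizationResult", method = "libsize", factors = unname(s),
        offsets = NULL, transformed = NULL, effLibSizes = unname(L),
        details = list(libSizes = unname(L)))
}

#' Reads-in-peaks scale factors
#'
#' As \code{\link{normLibsize}} with the library size replaced by the
#' in-peak column sum, normalizing away differences in enrichment
#' efficiency (FRiP) rather than raw depth: adding out-of-peak background
#' fragments leaves these factors unchanged.
#'
#' @param counts An \linkS4class{AtacCountExperiment} over PEAK rows (or a
#'   peak count matrix).
#' @return A \linkS4class{NormalizationResult}; effective library sizes are
#'   the in-peak sums rescaled to the mean full library size.
#' @export
normReadsInPeaks <- function(counts) {
    cnt <- .getCounts(counts)
    rip <- colSums(cnt)
    if (any(rip == 0))
        stop("a sample has zero in-peak reads; cannot normalize")
    s <- .geomean1(rip)
    L <- .getLibSizes(counts)
    new("NormalizationResult", method = "reads_in_peaks",
        factors = unname(s), offsets = NULL, transformed = NULL,
        effLibSizes = unname(s * exp(mean(log(L)))),
        details = list(readsInPeaks = unname(rip)))
}

#' Trimmed mean of M-values (TMM) scale factors
#'
#' Computes edgeR-style TMM factors, typically from counts in large (10 kb)
#' genomic bins so that genome-scale background drives the factors.  TMM
#' assumes most bins are NOT differential: for each sample against a
#' reference (the sample whose upper-quartile CPM is closest to the mean),
#' per-bin log ratios M and abundances A are formed from depth-scaled
#' counts, the extreme M and A quantiles are discarded, and the factor is
#' two to the power of the precision-weighted mean of the surviving M
#' values (delta-method binomial weights).  Factors are renormalized to
#' unit geometric mean; effective library sizes are \code{L_i * s_i}.
#'
#' @param binCounts An \linkS4class{AtacCountExperiment} or matrix of bin
#'   counts (>= 2 samples).
#' @param logratioTrim Total fraction of bins trimmed on M, split equally
#'   over both tails (default 0.30, i.e. 15\% per tail).
#' @param abundanceTrim Total fraction trimmed on A (default 0.05, i.e.
#'   2.5\% per tail).
#' @param libSizes Library sizes; defaults to bin-count column sums.
#' @return A \linkS4class{NormalizationResult}.
#' @export
normTMM <- function(binCounts, logratioTrim = 0.30, abundanceTrim = 0.05,
                    libSizes = NULL) {
    cnt <- .getCounts(binCounts)
    if (ncol(cnt) < 2L)
        stop("TMM needs at least 2 samples")
    L <- if (!is.null(libSizes)) libSizes else colSums(cnt)
    stopifnot(all(L > 0))
    uq <- apply(cnt, 2L, function(y) quantile(y / sum(y) * 1e6, 0.75))
    ref <- which.min(abs(uq - mean(uq)))
    f <- vapply(seq_len(ncol(cnt)), function(i) {
        if (i == ref)
            return(1)
        .tmmPair(cnt[, i], cnt[, ref], L[i], L[ref],
                 mTrim = logratioTrim / 2, aTrim = abundanceTrim / 2)
    }, numeric(1))
    s <- .geomean1(f)
    new("NormalizationResult", method = "tmm", factors = unname(s),
        offsets = NULL, transformed = NULL,
        effLibSizes = unname(L * s),
        details = list(reference = unname(ref), rawFactors = unname(f),
                       libSizes = unname(L)))
}

# One TMM factor: sample (y, L) against reference (yr, Lr).  Bins with a
# zero in either sample are excluded pairwise; ranks use ties.method =
# "first" so the trim is deterministic and reproducible by a sort-based
# check.
.tmmPair <- function(y, yr, L, Lr, mTrim, aTrim) {
    keep <- y > 0 & yr > 0
    y <- y[keep]; yr <- yr[keep]
    if (!length(y))
        return(1)
    p <- y / L; pr <- yr / Lr
    M <- log2(p / pr)
    A <- 0.5 * log2(p * pr)
    w <- 1 / ((L - y) / (L * y) + (Lr - yr) / (Lr * yr))
    n <- length(M)
    loM <- floor(n * mTrim) + 1L; hiM <- n - floor(n * mTrim)
    loA <- floor(n * aTrim) + 1L; hiA <- n - floor(n * aTrim)
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (sum(sel) < 10L) {
        warning("fewer than 10 bins survive TMM trimming; ",
                "falling back to the untrimmed weighted mean")
        sel <- rep(TRUE, n)
    }
    2^(sum(w[sel] * M[sel]) / sum(w[sel]))
}

#' Loess (abundance-dependent) normalization offsets
#'
#' Fits, for every sample, a robust local linear regression of that
#' sample's deviation M = log2(count + 0.5) - rowMean on the average
#' abundance A, and returns the fitted values as log2-scale offsets
#' (row-centred so each region's offsets sum to zero over samples).
#' Subtracting the offsets from log2-CPM removes both global shifts and
#' abundance-dependent (trended) biases; the method therefore assumes the
#' true signal distribution is symmetric, with no genuine global
#' accessibility change between conditions.
#'
#' @param counts An \linkS4class{AtacCountExperiment} or count matrix
#'   (>= 50 regions recommended for a stable fit).
#' @param span Loess span (default 0.5).
#' @param iterations Robustifying (bisquare) iterations (default 3).
#' @param prior Prior count for the log transform.
#' @return A \linkS4class{NormalizationResult} carrying the offset matrix;
#'   effective library sizes stay at the full library sizes.
#' @export
normLoess <- function(counts, span = 0.5, iterations = 3L, prior = 0.5) {
    cnt <- .getCounts(counts)
    L <- .getLibSizes(counts)
    V <- log2(cnt + prior)
    A <- rowMeans(V)
    n <- ncol(V)
    o <- matrix(0, nrow(V), n, dimnames = dimnames(V))
    if (stats::sd(A) > 0) {
        ctl <- loess.control(iterations = as.integer(iterations) + 1L,
                             surface = "interpolate")
        for (i in seq_len(n)) {
            M <- V[, i] - A
            if (diff(range(M)) < 1e-12) {
                # constant deviation (e.g. identical samples): the robust
                # fit is degenerate, the answer is the constant itself
                o[, i] <- M
            } else {
                fit <- loess(M ~ A, span = span, degree = 1,
                             family = "symmetric", control = ctl)
                o[, i] <- stats::fitted(fit)
            }
        }
        o <- o - rowMeans(o)
    }
    new("NormalizationResult", method = "loess", factors = NULL,
        offsets = o, transformed = NULL, effLibSizes = unname(L),
        details = list(span = span, iterations = iterations))
}

#' Classic quantile normalization
#'
#' Forces every column to share one distribution: the value of rank r in a
#' column is replaced by the across-column mean of the r-th order
#' statistics; ties within a column receive the mean of their target
#' quantiles.  After the transform, the sorted values of all columns are
#' identical.
#'
#' @param m Numeric matrix (no missing values), typically log2-CPM.
#' @return Matrix of the same dimensions.
#' @examples
#' quantileNormalize(cbind(c(1, 3), c(2, 4)))  # both columns 1.5, 3.5
#' @export
quantileNormalize <- function(m) {
    m <- as.matrix(m)
    if (anyNA(m))
        stop("quantile normalization requires a complete matrix")
    target <- rowMeans(apply(m, 2L, sort))
    out <- m
    for (i in seq_len(ncol(m))) {
        r <- rank(m[, i], ties.method = "average")
        lo <- floor(r); hi <- ceiling(r)
        out[, i] <- (target[lo] + target[hi]) / 2
    }
    out
}

#' Quantile normalization of log2-CPM
#'
#' Computes log2-CPM at full library sizes and quantile-normalizes the
#' resulting matrix across samples (\code{\link{quantileNormalize}}).
#'
#' @param counts An \linkS4class{AtacCountExperiment} or count matrix.
#' @param libSizes Library sizes for the CPM step.
#' @param prior Prior count.
#' @return A \linkS4class{NormalizationResult} carrying the transformed
#'   matrix.
#' @export
normQuantile <- function(counts, libSizes = NULL, prior = 0.5) {
    L <- .getLibSizes(counts, libSizes)
    lcpm <- log2cpm(.getCounts(counts), L, prior = prior)
    new("NormalizationResult", method = "quantile", factors = NULL,
        offsets = NULL, transformed = quantileNormalize(lcpm),
        effLibSizes = unname(L), details = list(prior = prior))
}

#' Log2-CPM-only normalization
#'
#' Plain full-library-size scaling on the log scale with no further
#' adjustment; keeps the assumptions of library-size normalization.
#'
#' @param counts An \linkS4class{AtacCountExperiment} or count matrix.
#' @param libSizes Library sizes.
#' @return A \linkS4class{NormalizationResult}.
#' @export
normLog2cpmOnly <- function(counts, libSizes = NULL) {
    L <- .getLibSizes(counts, libSizes)
    new("NormalizationResult", method = "log2cpm_only",
        factors = rep(1, length(L)), offsets = NULL, transformed = NULL,
        effLibSizes = unname(L), details = list())
}

#' Run one of the six normalization methods
#'
#' Dispatcher over the interchangeable normalization strategies compared by
#' this package.  \code{"tmm"} is computed from \code{binCounts} when
#' supplied (the recommended large-bin input) and from \code{counts}
#' otherwise.
#'
#' @param counts An \linkS4class{AtacCountExperiment} over the tested
#'   regions.
#' @param method One of \code{"libsize"}, \code{"reads_in_peaks"},
#'   \code{"tmm"}, \code{"loess"}, \code{"log2cpm_only"},
#'   \code{"quantile"}.
#' @param binCounts Optional \linkS4class{AtacCountExperiment} of large-bin
#'   counts for TMM.
#' @param ... Method-specific parameters passed through.
#' @return A \linkS4class{NormalizationResult}.
#' @export
normalizeCounts <- function(counts, method = .NORM_METHODS,
                            binCounts = NULL, ...) {
    method <- match.arg(method)
    switch(method,
        libsize = normLibsize(counts, ...),
        reads_in_peaks = normReadsInPeaks(counts),
        tmm = {
            res <- normTMM(if (is.null(binCounts)) counts else binCounts, ...)
            # factors transfer to the tested regions at the regions' own
            # library sizes
            L <- .getLibSizes(counts)
            initialize(res, effLibSizes = unname(L * res@factors))
        },
        loess = normLoess(counts, ...),
        log2cpm_only = normLog2cpmOnly(counts, ...),
        quantile = normQuantile(counts, ...))
}

#' Normalized log2-CPM matrix for the testing engine
#'
#' Materializes the matrix the moderated engine tests: log2-CPM at the
#' normalization's effective library sizes for factor methods, log2-CPM
#' minus the offset matrix for loess, and the transformed matrix itself for
#' quantile.
#'
#' @param counts The \linkS4class{AtacCountExperiment} the normalization
#'   was derived for.
#' @param norm A \linkS4class{NormalizationResult}.
#' @param prior Prior count.
#' @return Normalized log2-scale matrix, regions x samples.
#' @export
normalizedLog2cpm <- function(counts, norm, prior = 0.5) {
    stopifnot(is(norm, "NormalizationResult"))
    switch(norm@method,
        quantile = norm@transformed,
        loess = {
            # offsets were fit on log2(count + prior) and already absorb
            # depth; subtract them there, then shift by one common constant
            # onto the log2-CPM scale
            V <- log2(.getCounts(counts) + prior)
            V - norm@offsets + log2(1e6) - mean(log2(norm@effLibSizes + 1))
        },
        log2cpm(.getCounts(counts), norm@effLibSizes, prior = prior))
}
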