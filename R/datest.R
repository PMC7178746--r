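#' @importFrom stats model.matrix p.adjust pt lowess approx dnbinom dpois
#'   var sd setNames
NULL

#' Benjamini-Hochberg FDR
#'
#' Step-up adjusted p-values (q-values) controlling the false discovery
#' rate, with the usual monotonicity enforcement; a thin wrapper over
#' \code{stats::p.adjust(method = "BH")} so DA results carry a single,
#' named multiplicity correction.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Vector of BH-adjusted q-values.
#' @export
bhFdr <- function(p) {
    p.adjust(p, method = "BH")
}

#' Two-group design matrix with condition contrast
#'
#' @param condition Factor (or coercible) of sample group labels with
#'   exactly two levels; the second level is the tested effect.
#' @param batch Optional blocking factor added as a covariate.
#' @return List with \code{design} (n x p model matrix) and
#'   \code{contrast} (numeric vector selecting the condition effect).
#' @export
makeDesign <- function(condition, batch = NULL) {
    condition <- factor(condition)
    if (nlevels(condition) != 2L)
        stop("exactly two condition levels are required")
    df <- data.frame(condition = condition)
    form <- ~condition
    if (!is.null(batch)) {
        df$batch <- factor(batch)
        form <- ~condition + batch
    }
    design <- model.matrix(form, data = df)
    contrast <- as.numeric(colnames(design) ==
                           paste0("condition", levels(condition)[2L]))
    if (nrow(design) - ncol(design) < 1L)
        stop("no residual degrees of freedom; replicates are required")
    list(design = design, contrast = contrast)
}

#' Mean-variance observation weights
#'
#' The voom idea: on log2-CPM the residual standard deviation of count data
#' depends smoothly on abundance.  Each region is fitted by ordinary least
#' squares, the square root of the residual sd is smoothed against the mean
#' log2 count (lowess with the stated span), and each observation receives
#' the inverse fourth power of the trend evaluated at its fitted log2
#' count, clipped to [1e-6, 1e6].
#'
#' @param lcpm Log2-CPM matrix, regions x samples (>= 50 regions for a
#'   stable trend).
#' @param design Model matrix (n x p with n - p >= 1).
#' @param libSizes Library sizes used for the log2-CPM transform (needed to
#'   place the trend on the log2-count axis).
#' @param span Lowess span (default 0.5).
#' @return Weight matrix with the dimensions of \code{lcpm}.
#' @export
voomWeights <- function(lcpm, design, libSizes, span = 0.5) {
    E <- as.matrix(lcpm)
    X <- as.matrix(design)
    n <- ncol(E); p <- ncol(X)
    if (n - p < 1L)
        stop("no residual degrees of freedom; replicates are required")
    H <- X %*% solve(crossprod(X)) %*% t(X)
    fitted <- E %*% t(H)
    sigma <- sqrt(rowSums((E - fitted)^2) / (n - p))
    shift <- mean(log2(libSizes + 1)) - log2(1e6)
    sx <- rowMeans(E) + shift
    sy <- sqrt(sigma)
    l <- lowess(sx, sy, f = span)
    xcount <- sweep(fitted, 2L, log2(libSizes + 1) - log2(1e6), "+")
    trend <- approx(l$x, l$y, xout = as.vector(xcount), rule = 2,
                    ties = mean)$y
    w <- matrix(trend, nrow(E), n)^(-4)
    w[!is.finite(w)] <- 1e6
    pmin(pmax(w, 1e-6), 1e6)
}

# Newton inversion of the trigamma function (x > 0 from trigamma(x) = y).
.trigammaInverse <- function(y) {
    if (y > 1e7)
        return(1 / sqrt(y))
    if (y < 1e-6)
        return(1 / y)
    x <- 0.5 + 1 / y
    for (i in seq_len(50L)) {
        tri <- trigamma(x)
        dif <- tri * (1 - tri / y) / psigamma(x, 2L)
        x <- x + dif
        if (abs(dif) / x < 1e-8)
            break
    }
    x
}

# Moment-matching of the scaled inverse-chi-square prior on residual
# variances: closed-form digamma/trigamma system on log s^2.
.fitVariancePrior <- function(s2, df) {
    ok <- s2 > 0
    if (sum(ok) < 2L)
        return(list(d0 = 0, s02 = if (any(ok)) mean(s2[ok]) else 1))
    z <- log(s2[ok])
    e <- z - digamma(df / 2) + log(df / 2)
    evar <- var(e) - trigamma(df / 2)
    if (is.na(evar) || evar <= 0)
        return(list(d0 = Inf, s02 = exp(mean(e))))
    d0 <- 2 * .trigammaInverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated differential test
#'
#' Fits a weighted linear model per region on the normalized log2-CPM
#' matrix, then shrinks the per-region residual variances s_g^2 toward a
#' common prior estimated by moment matching on log s_g^2 (the
#' digamma/trigamma closed forms): the posterior variance is
#' (d0 s0^2 + d s_g^2) / (d0 + d) and the moderated t statistic for the
#' contrast is referred to a t distribution with d0 + d degrees of
#' freedom.  With prior df d0 = 0 this is the ordinary t-test; as d0 grows
#' all regions share one variance.
#'
#' @param E Normalized log2-scale matrix, regions x samples.
#' @param design Model matrix.
#' @param contrast Numeric vector (length p) selecting the tested effect.
#' @param weights Optional observation weight matrix
#'   (\code{\link{voomWeights}}).
#' @param A Optional per-region abundance; defaults to \code{rowMeans(E)}.
#' @param regions Optional \code{GRanges} aligned with the rows.
#' @param fdrThreshold Significance cutoff recorded in the result.
#' @return A \linkS4class{DAResult} whose \code{params} carry the
#'   hyperparameters (\code{d0}, \code{s02}) and residual df.
#' @export
fitModerated <- function(E, design, contrast, weights = NULL, A = NULL,
                         regions = NULL, fdrThreshold = 0.10) {
    E <- as.matrix(E)
    X <- as.matrix(design)
    m <- nrow(E); n <- ncol(E); p <- ncol(X)
    stopifnot(length(contrast) == p)
    d <- n - p
    if (d < 1L)
        stop("no residual degrees of freedom; replicates are required")
    beta <- numeric(m); s2 <- numeric(m); v <- numeric(m)
    if (is.null(weights)) {
        XtXi <- solve(crossprod(X))
        P <- XtXi %*% t(X)
        B <- E %*% t(P)                    # m x p coefficients
        fittedv <- B %*% t(X)
        s2 <- rowSums((E - fittedv)^2) / d
        beta <- as.vector(B %*% contrast)
        v <- rep(as.numeric(t(contrast) %*% XtXi %*% contrast), m)
    } else if (p == 2L && all(X[, 1L] == 1) && all(X[, 2L] %in% c(0, 1)) &&
               identical(as.numeric(contrast), c(0, 1))) {
        # vectorized two-group weighted LS (the common design)
        W <- as.matrix(weights)
        grp2 <- X[, 2L] == 1
        sw1 <- rowSums(W[, !grp2, drop = FALSE])
        sw2 <- rowSums(W[, grp2, drop = FALSE])
        mu1 <- rowSums((W * E)[, !grp2, drop = FALSE]) / sw1
        mu2 <- rowSums((W * E)[, grp2, drop = FALSE]) / sw2
        beta <- mu2 - mu1
        fittedv <- matrix(mu1, m, n)
        fittedv[, grp2] <- mu2
        s2 <- rowSums(W * (E - fittedv)^2) / d
        v <- 1 / sw1 + 1 / sw2
    } else {
        W <- as.matrix(weights)
        for (g in seq_len(m)) {
            w <- W[g, ]
            Xw <- X * w
            XtWXi <- solve(crossprod(X, Xw))
            b <- XtWXi %*% crossprod(Xw, E[g, ])
            r <- E[g, ] - as.vector(X %*% b)
            s2[g] <- sum(w * r^2) / d
            beta[g] <- sum(contrast * b)
            v[g] <- as.numeric(t(contrast) %*% XtWXi %*% contrast)
        }
    }
    prior <- .fitVariancePrior(s2, d)
    d0 <- prior$d0; s02 <- prior$s02
    if (is.infinite(d0)) {
        s2post <- rep(s02, m); dfTotal <- Inf
    } else if (d0 == 0) {
        s2post <- s2; dfTotal <- d
    } else {
        s2post <- (d0 * s02 + d * s2) / (d0 + d); dfTotal <- d0 + d
    }
    tstat <- beta / sqrt(s2post * v)
    pval <- 2 * pt(-abs(tstat), df = dfTotal)
    pval[!is.finite(tstat)] <- 1
    if (is.null(A))
        A <- rowMeans(E)
    if (is.null(regions))
        regions <- GRanges(rep("unknown", m), IRanges(seq_len(m), width = 1L))
    DAResult(regions, logFC = beta, A = A, p = pval,
             fdrThreshold = fdrThreshold, engine = "moderated",
             params = list(d0 = d0, s02 = s02, df = d, t = tstat))
}

#' Two-group negative binomial exact test
#'
#' Counts are rescaled to a common effective library size (rounded), a
#' common dispersion phi is estimated by the method of moments
#' (mean over regions of max(0, (s_g^2 - mu_g) / mu_g^2), with the pooled
#' within-group variance), and each region is tested conditionally on its
#' total: under the null the group sums are independent negative binomials
#' NB(n_k mu, phi / n_k), and the two-sided p-value doubles the smaller
#' conditional tail (capped at 1).  \code{tails = "smallp"} instead sums
#' the probabilities of all splits at most as likely as the observed one.
#' With phi = 0 the computation runs on the Poisson branch (conditionally
#' binomial splits).
#'
#' @param counts An \linkS4class{AtacCountExperiment} with exactly two
#'   conditions, or a count matrix plus \code{condition}.
#' @param condition Group labels when \code{counts} is a matrix.
#' @param effLibSizes Effective library sizes (e.g. from a factor
#'   normalization); defaults to the object's library sizes.
#' @param dispersion Common NB dispersion; estimated when \code{NULL}.
#' @param tails \code{"doubling"} (default) or \code{"smallp"}.
#' @param fdrThreshold Significance cutoff recorded in the result.
#' @return A \linkS4class{DAResult} (logFC is second condition vs first).
#' @export
nbExactTest <- function(counts, condition = NULL, effLibSizes = NULL,
                        dispersion = NULL, tails = c("doubling", "smallp"),
                        fdrThreshold = 0.10) {
    tails <- match.arg(tails)
    if (is(counts, "AtacCountExperiment")) {
        if (is.null(condition))
            condition <- sampleConditions(counts)
        if (is.null(effLibSizes))
            effLibSizes <- libSizes(counts)
        regions <- SummarizedExperiment::rowRanges(counts)
        cnt <- SummarizedExperiment::assay(counts, "counts")
    } else {
        cnt <- as.matrix(counts)
        regions <- NULL
        if (is.null(effLibSizes))
            effLibSizes <- colSums(cnt)
    }
    condition <- factor(condition)
    if (nlevels(condition) != 2L)
        stop("the exact test requires exactly two conditions")
    g1 <- condition == levels(condition)[1L]
    g2 <- !g1
    n1 <- sum(g1); n2 <- sum(g2)
    common <- exp(mean(log(effLibSizes)))
    y <- round(t(t(cnt) / effLibSizes * common))
    if (is.null(dispersion)) {
        mu <- rowMeans(y)
        v1 <- apply(y[, g1, drop = FALSE], 1L, var)
        v2 <- apply(y[, g2, drop = FALSE], 1L, var)
        s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        ok <- mu > 0
        dispersion <- if (any(ok))
            mean(pmax(0, (s2[ok] - mu[ok]) / mu[ok]^2)) else 0
    }
    s1 <- rowSums(y[, g1, drop = FALSE])
    s2sum <- rowSums(y[, g2, drop = FALSE])
    m <- nrow(y)
    pval <- numeric(m)
    for (g in seq_len(m)) {
        pval[g] <- .nbExactP(s1[g], s2sum[g], n1, n2, dispersion, tails)
    }
    mean1 <- s1 / n1; mean2 <- s2sum / n2
    logFC <- log2((mean2 + 0.5) / (mean1 + 0.5))
    A <- log2((mean1 + mean2) / 2 + 0.5) - log2(common + 1) + log2(1e6)
    if (is.null(regions))
        regions <- GRanges(rep("unknown", m), IRanges(seq_len(m), width = 1L))
    DAResult(regions, logFC = logFC, A = A, p = pval,
             fdrThreshold = fdrThreshold, engine = "nb_exact",
             params = list(dispersion = dispersion, tails = tails,
                           commonLibSize = common))
}

# Conditional two-sided exact p-value for a split (s1, s2) of the total
# over groups of sizes (n1, n2) at common dispersion phi.
.nbExactP <- function(s1, s2, n1, n2, phi, tails = "doubling") {
    total <- s1 + s2
    if (total == 0)
        return(1)
    mu <- total / (n1 + n2)
    x <- 0:total
    if (phi > 0) {
        lp <- dnbinom(x, size = n1 / phi, mu = n1 * mu, log = TRUE) +
              dnbinom(total - x, size = n2 / phi, mu = n2 * mu, log = TRUE)
    } else {
        lp <- dpois(x, lambda = n1 * mu, log = TRUE) +
              dpois(total - x, lambda = n2 * mu, log = TRUE)
    }
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    obs <- s1 + 1L
    if (tails == "smallp") {
        p <- sum(pr[pr <= pr[obs] * (1 + 1e-12)])
    } else {
        lower <- sum(pr[x <= s1])
        upper <- sum(pr[x >= s1])
        p <- 2 * min(lower, upper)
    }
    min(p, 1)
}

#' Run a full differential-accessibility approach
#'
#' Orchestrates one row of the approach grid: low-abundance filtering,
#' normalization by the chosen method, testing by the chosen engine, and
#' BH correction, recording the full provenance in the result.  Offset and
#' transform normalizations (loess, quantile, log2cpm-only) live on the
#' log scale and are incompatible with the count-scale exact test.
#'
#' @param counts An \linkS4class{AtacCountExperiment} with a two-level
#'   condition.
#' @param method Normalization method (see \code{\link{normalizeCounts}}).
#' @param engine \code{"moderated"} (default) or \code{"nb_exact"}.
#' @param binCounts Optional large-bin counts for TMM.
#' @param filter Apply the low-abundance filter first (default TRUE).
#' @param minAbundance Abundance cutoff for the filter; \code{NULL} for the
#'   default, \code{-Inf} to keep everything.
#' @param useWeights Use mean-variance weights in the moderated engine.
#' @param fdrThreshold Significance cutoff (default 0.10).
#' @param batch Optional blocking factor.
#' @return A \linkS4class{DAResult} for the regions surviving the filter.
#' @export
runApproach <- function(counts, method = .NORM_METHODS,
                        engine = c("moderated", "nb_exact"),
                        binCounts = NULL, filter = TRUE,
                        minAbundance = NULL, useWeights = TRUE,
                        fdrThreshold = 0.10, batch = NULL) {
    method <- match.arg(method)
    engine <- match.arg(engine)
    stopifnot(is(counts, "AtacCountExperiment"))
    if (engine == "nb_exact" &&
        method %in% c("quantile", "loess", "log2cpm_only"))
        stop(sprintf(
            "'%s' normalization is log-scale and cannot feed the count-scale exact test",
            method))
    if (filter) {
        keep <- abundanceFilter(counts, minAbundance = minAbundance)
        counts <- counts[keep, ]
    }
    norm <- normalizeCounts(counts, method = method, binCounts = binCounts)
    regions <- SummarizedExperiment::rowRanges(counts)
    if (engine == "nb_exact") {
        res <- nbExactTest(counts, effLibSizes = effectiveLibSizes(norm),
                           fdrThreshold = fdrThreshold)
        res@regions <- regions
    } else {
        des <- makeDesign(sampleConditions(counts), batch = batch)
        E <- normalizedLog2cpm(counts, norm)
        w <- if (useWeights)
            voomWeights(E, des$design, libSizes(counts)) else NULL
        res <- fitModerated(E, des$design, des$contrast, weights = w,
                            regions = regions, fdrThreshold = fdrThreshold)
    }
    res@params$approach <- list(method = method, engine = engine,
                                filtered = filter,
                                normDetails = norm@details)
    res
}
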