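#' @importFrom stats rnorm rnbinom rpois runif rbinom ave
NULL

#' Configuration for the negative binomial count simulator
#'
#' Defines a two-condition experiment of m regions whose counts follow
#' NB(mean, dispersion) with variance mu + phi mu^2.  Region baseline
#' abundances are log2-normal; a configurable fraction of regions is truly
#' differential (log2 effects drawn from a normal magnitude distribution,
#' a configurable share of them up in condition B); condition B can
#' additionally carry a global efficiency bias (a multiplier on every
#' region) and a trended bias (an M distortion linear in baseline
#' abundance — the minimal shape that loess corrects and linear factors
#' cannot).
#'
#' @param m Number of regions.
#' @param nPerCondition Replicates per condition.
#' @param baselineLog2Mean,baselineLog2Sd Normal parameters of the per-region
#'   baseline log2 expected count at the reference depth of 1e6 fragments.
#' @param dispersion NB dispersion phi (0 gives Poisson counts).
#' @param fracDA Fraction of regions truly differential.
#' @param lfcMean,lfcSd Normal parameters of the |log2 fold change|
#'   magnitude of DA regions (drawn magnitudes are clamped at 0.25).
#' @param upFraction Share of DA regions with increased accessibility in
#'   condition B.
#' @param globalBias Multiplier c applied to ALL condition-B means
#'   (efficiency bias; 1 = none).
#' @param trendAmplitude Slope of the linear trended bias: condition-B
#'   log2 means gain \code{trendAmplitude * (z - mean(z))} where z is the
#'   baseline log2 abundance (0 = none).
#' @param libSize Full library size per sample (scalar or length-2n
#'   vector).
#' @return List of class \code{"CountSimConfig"}.
#' @export
countSimConfig <- function(m = 10000L, nPerCondition = 3L,
                           baselineLog2Mean = 5, baselineLog2Sd = 2,
                           dispersion = 0.05, fracDA = 0,
                           lfcMean = 2, lfcSd = 0.5, upFraction = 0.5,
                           globalBias = 1, trendAmplitude = 0,
                           libSize = 1e6) {
    stopifnot(fracDA >= 0, fracDA <= 1, dispersion >= 0, globalBias > 0,
              upFraction >= 0, upFraction <= 1, m >= 1, nPerCondition >= 1)
    cfg <- list(m = as.integer(m), nPerCondition = as.integer(nPerCondition),
                baselineLog2Mean = baselineLog2Mean,
                baselineLog2Sd = baselineLog2Sd, dispersion = dispersion,
                fracDA = fracDA, lfcMean = lfcMean, lfcSd = lfcSd,
                upFraction = upFraction, globalBias = globalBias,
                trendAmplitude = trendAmplitude, libSize = libSize)
    class(cfg) <- "CountSimConfig"
    cfg
}

#' Simulate a two-condition NB count experiment with known truth
#'
#' Draws counts per \code{\link{countSimConfig}}: count_gi ~ NB with mean
#' L_i / 1e6 * 2^(z_g + effects_gi) and variance mu + phi mu^2, where the
#' condition-B effects stack the true log fold change (DA regions only),
#' the global efficiency bias log2(c), and the linear trend term.
#' Deterministic for a fixed seed.
#'
#' @param cfg A \code{"CountSimConfig"}.
#' @param seed Integer seed.
#' @return List: \code{counts} (an \linkS4class{AtacCountExperiment} with
#'   conditions A/B and full library sizes), \code{truth} (data.frame
#'   \code{isDA}, \code{trueLfc}, \code{baseline}), \code{sampleBias}
#'   (per-sample true efficiency factor).
#' @export
simulateCounts <- function(cfg, seed = 1L) {
    stopifnot(inherits(cfg, "CountSimConfig"))
    set.seed(as.integer(seed))
    m <- cfg$m; n <- cfg$nPerCondition
    z <- rnorm(m, cfg$baselineLog2Mean, cfg$baselineLog2Sd)
    nDA <- round(cfg$fracDA * m)
    isDA <- logical(m)
    isDA[sample.int(m, nDA)] <- TRUE
    lfc <- numeric(m)
    if (nDA > 0) {
        mag <- pmax(abs(rnorm(nDA, cfg$lfcMean, cfg$lfcSd)), 0.25)
        sgn <- ifelse(runif(nDA) < cfg$upFraction, 1, -1)
        lfc[isDA] <- sgn * mag
    }
    trend <- if (cfg$trendAmplitude != 0)
        cfg$trendAmplitude * (z - mean(z)) else numeric(m)
    effB <- lfc + log2(cfg$globalBias) + trend
    L <- rep_len(cfg$libSize, 2L * n)
    condition <- rep(c("A", "B"), each = n)
    mu <- matrix(0, m, 2L * n)
    for (i in seq_len(2L * n)) {
        shift <- if (condition[i] == "B") effB else 0
        mu[, i] <- L[i] / 1e6 * 2^(z + shift)
    }
    counts <- if (cfg$dispersion > 0) {
        matrix(rnbinom(m * 2L * n, mu = mu, size = 1 / cfg$dispersion),
               m, 2L * n)
    } else {
        matrix(rpois(m * 2L * n, lambda = mu), m, 2L * n)
    }
    colnames(counts) <- paste0(condition, rep(seq_len(n), 2L))
    regions <- GRanges("sim", IRanges(start = seq_len(m) * 1000L - 999L,
                                      width = 500L))
    ace <- AtacCountExperiment(counts, regions, libSizes = L,
                               condition = condition)
    list(counts = ace,
         truth = data.frame(isDA = isDA, trueLfc = lfc, baseline = z),
         sampleBias = ifelse(condition == "B", cfg$globalBias, 1))
}

#' Configuration for the fragment-library simulator
#'
#' Defines per-library fragment generation with controlled molecular
#' complexity: each library holds \code{nMolecules} distinct template
#' molecules placed either inside peaks (with probability
#' \code{peakFraction}, peak chosen proportionally to its accessibility
#' weight) or uniformly in the background, and \code{nReads} read pairs
#' are then drawn from the molecules WITH replacement, so duplication —
#' and hence estimable complexity — is controlled by the reads/molecules
#' ratio.  Condition-B libraries multiply the weights of the planted DA
#' peaks by \code{daEffect}.
#'
#' @param genome Named vector of chromosome lengths.
#' @param peaks \link[GenomicRanges]{GRanges} of accessible peaks.
#' @param daPeaks Integer indices of peaks planted as truly differential.
#' @param daEffect Linear weight multiplier on DA peaks in condition B.
#' @param peakFraction Probability a molecule falls in a peak (FRiP-like;
#'   default 0.6).
#' @param nMolecules Distinct molecules per library (recycled).
#' @param nReads Read pairs per library (recycled).
#' @param condition Condition label per library.
#' @param fragLenMean,fragLenSd Fragment length distribution (clipped to
#'   [60, 600] bp).
#' @param readLen Sequenced mate length (default 50 bp).
#' @return List of class \code{"FragmentSimConfig"}.
#' @export
fragmentSimConfig <- function(genome, peaks, daPeaks = integer(0),
                              daEffect = 4, peakFraction = 0.6,
                              nMolecules = 50000L, nReads = 75000L,
                              condition = c("A", "A", "A", "B", "B", "B"),
                              fragLenMean = 180, fragLenSd = 60,
                              readLen = 50L) {
    stopifnot(is(peaks, "GRanges"), peakFraction >= 0, peakFraction <= 1,
              daEffect > 0)
    nl <- length(condition)
    cfg <- list(genome = genome, peaks = peaks,
                daPeaks = as.integer(daPeaks), daEffect = daEffect,
                peakFraction = peakFraction,
                nMolecules = rep_len(as.integer(nMolecules), nl),
                nReads = rep_len(as.integer(nReads), nl),
                condition = condition, fragLenMean = fragLenMean,
                fragLenSd = fragLenSd, readLen = as.integer(readLen))
    class(cfg) <- "FragmentSimConfig"
    cfg
}

# Draw n molecule spans (0-based starts and lengths) for one library.
.drawMolecules <- function(cfg, n, weights) {
    genome <- cfg$genome
    len <- pmin(pmax(round(rnorm(n, cfg$fragLenMean, cfg$fragLenSd)),
                     60L), 600L)
    inPeak <- runif(n) < cfg$peakFraction
    chrom <- character(n); start <- integer(n)
    nPk <- sum(inPeak)
    if (nPk > 0) {
        pk <- sample.int(length(cfg$peaks), nPk, replace = TRUE,
                         prob = weights)
        pkStart <- start(cfg$peaks)[pk] - 1L
        pkWidth <- width(cfg$peaks)[pk]
        # centre the fragment near a uniform point inside the peak
        ctr <- pkStart + floor(runif(nPk) * pkWidth)
        start[inPeak] <- pmax(ctr - len[inPeak] %/% 2L, 0L)
        chrom[inPeak] <- as.character(GenomeInfoDb::seqnames(cfg$peaks))[pk]
    }
    nBg <- sum(!inPeak)
    if (nBg > 0) {
        chr <- sample(names(genome), nBg, replace = TRUE,
                      prob = genome / sum(genome))
        chrom[!inPeak] <- chr
        start[!inPeak] <- floor(runif(nBg) * pmax(genome[chr] - len[!inPeak], 1))
    }
    # clip to chromosome bounds
    maxEnd <- unname(genome[chrom])
    start <- pmin(start, pmax(maxEnd - len, 0L))
    data.frame(chrom = chrom, start = as.integer(start),
               end = as.integer(start + len))
}

#' Simulate paired-end fragment libraries with controlled complexity
#'
#' @param cfg A \code{"FragmentSimConfig"}.
#' @param seed Integer base seed; library i uses stream \code{seed + i} so
#'   adding a library does not perturb the others.
#' @return List: \code{libraries} (named list of
#'   \linkS4class{FragmentSet}s in unshifted 10-column BEDPE layout),
#'   \code{truth} (data.frame per peak: \code{isDA}, \code{effect}),
#'   \code{condition}.
#' @export
simulateFragments <- function(cfg, seed = 1L) {
    stopifnot(inherits(cfg, "FragmentSimConfig"))
    nl <- length(cfg$condition)
    baseW <- rep(1, length(cfg$peaks))
    libs <- vector("list", nl)
    for (i in seq_len(nl)) {
        set.seed(as.integer(seed) + i)
        w <- baseW
        if (cfg$condition[i] == "B" && length(cfg$daPeaks))
            w[cfg$daPeaks] <- w[cfg$daPeaks] * cfg$daEffect
        mol <- .drawMolecules(cfg, cfg$nMolecules[i], w)
        idx <- sample.int(nrow(mol), cfg$nReads[i], replace = TRUE)
        reads <- mol[idx, , drop = FALSE]
        rl <- pmin(cfg$readLen, reads$end - reads$start)
        rec <- DataFrame(chrom = reads$chrom,
                         m1_start = reads$start,
                         m1_end = reads$start + rl,
                         m2_start = reads$end - rl,
                         m2_end = reads$end,
                         name = paste0("lib", i, "_read", seq_along(idx)),
                         score = 0,
                         m1_strand = "+", m2_strand = "-")
        libs[[i]] <- FragmentSet(rec)
    }
    names(libs) <- paste0(cfg$condition, ave(seq_len(nl), cfg$condition,
                                             FUN = seq_along))
    truth <- data.frame(peak = seq_along(cfg$peaks),
                        isDA = seq_along(cfg$peaks) %in% cfg$daPeaks,
                        effect = ifelse(seq_along(cfg$peaks) %in% cfg$daPeaks,
                                        cfg$daEffect, 1))
    list(libraries = libs, truth = truth, condition = cfg$condition)
}
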