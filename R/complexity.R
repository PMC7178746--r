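#' Duplicate-frequency histogram of a fragment library
#'
#' Tabulates, over distinct fragment identities (chromosome, span and
#' ordered mate-strand pair), how many identities were sequenced exactly
#' j times.  The totals C = sum n_j (distinct fragments) and
#' R = sum j n_j (total reads) drive all complexity estimation.
#'
#' @param fragments Minimal-fragment \link[GenomicRanges]{GRanges} (from
#'   \code{\link{minimalFragments}}) or a \linkS4class{FragmentSet}.
#' @return A list of class \code{"DuplicateHistogram"} with components
#'   \code{freq} (named integer vector, j -> n_j), \code{distinct} (C) and
#'   \code{reads} (R).
#' @export
duplicateHistogram <- function(fragments) {
    if (is(fragments, "FragmentSet"))
        fragments <- minimalFragments(fragments)
    if (is(fragments, "GRanges")) {
        sp <- if ("strandPair" %in% colnames(S4Vectors::mcols(fragments)))
            fragments$strandPair else ""
        key <- paste(GenomeInfoDb::seqnames(fragments), start(fragments),
                     end(fragments), sp, sep = ":")
    } else {
        key <- as.character(fragments)
    }
    if (!length(key)) {
        h <- list(freq = stats::setNames(integer(0), character(0)),
                  distinct = 0L, reads = 0L)
        class(h) <- "DuplicateHistogram"
        return(h)
    }
    dup <- table(table(key))
    freq <- stats::setNames(as.integer(dup), names(dup))
    h <- list(freq = freq,
              distinct = sum(freq),
              reads = sum(as.integer(names(freq)) * freq))
    class(h) <- "DuplicateHistogram"
    h
}

#' Build a duplicate histogram directly from frequencies
#'
#' @param freq Named integer vector: multiplicity j -> number of distinct
#'   fragments n_j seen exactly j times.
#' @return A \code{"DuplicateHistogram"}.
#' @examples
#' dupHistogram(c(`1` = 50, `5` = 10))
#' @export
dupHistogram <- function(freq) {
    j <- as.integer(names(freq))
    if (any(is.na(j)) || any(j < 1L) || any(freq < 0))
        stop("frequencies must map multiplicities >= 1 to counts >= 0")
    h <- list(freq = stats::setNames(as.integer(freq), names(freq)),
              distinct = sum(as.integer(freq)),
              reads = sum(j * as.integer(freq)))
    class(h) <- "DuplicateHistogram"
    h
}

#' @export
print.DuplicateHistogram <- function(x, ...) {
    cat(sprintf("DuplicateHistogram: %d distinct / %d reads (%.1f%% duplication)\n",
        x$distinct, x$reads,
        if (x$reads > 0) 100 * (1 - x$distinct / x$reads) else 0))
    invisible(x)
}

#' Estimate library molecular complexity
#'
#' Fits the Lander-Waterman saturation model: sequencing R reads from a
#' library of N equally likely distinct molecules yields
#' E[C] = N (1 - exp(-R/N)) distinct observations.  Given the observed
#' (C, R) from a duplicate histogram, the estimated complexity N-hat solves
#' C = N (1 - exp(-R/N)) by bisection on [C, 1e12 C] to 1e-6 relative
#' tolerance.  With no duplication (R = C) the complexity is unbounded and
#' an error is raised.
#'
#' @param h A \code{"DuplicateHistogram"}.
#' @return List of class \code{"ComplexityEstimate"}: \code{estimate}
#'   (N-hat), \code{distinct} (C), \code{reads} (R), \code{method}.
#' @export
estimateComplexity <- function(h) {
    stopifnot(inherits(h, "DuplicateHistogram"))
    C <- h$distinct; R <- h$reads
    if (C == 0L)
        stop("empty library: no fragments observed")
    if (R <= C)
        stop("no duplicates observed; complexity is unbounded")
    f <- function(N) N * (1 - exp(-R / N)) - C
    lo <- C; hi <- 1e12 * C
    # f is increasing in N; f(C) < 0, f(Inf) -> R - C > 0
    for (iter in seq_len(200L)) {
        mid <- (lo + hi) / 2
        if (f(mid) < 0) lo <- mid else hi <- mid
        if ((hi - lo) / hi < 1e-6)
            break
    }
    est <- list(estimate = (lo + hi) / 2, distinct = C, reads = R,
                method = "lander-waterman")
    class(est) <- "ComplexityEstimate"
    est
}

#' @export
print.ComplexityEstimate <- function(x, ...) {
    cat(sprintf("ComplexityEstimate (%s): N = %.0f from C = %d, R = %d\n",
        x$method, x$estimate, x$distinct, x$reads))
    invisible(x)
}

#' Expected distinct fragments after binomial thinning
#'
#' If each read is kept independently with probability p, a fragment
#' identity observed j times survives with probability 1 - (1-p)^j; the
#' expected distinct count is sum_j n_j (1 - (1-p)^j), strictly increasing
#' in p.
#'
#' @param h A \code{"DuplicateHistogram"}.
#' @param p Keep probability in [0, 1].
#' @return Expected number of distinct fragments after thinning.
#' @export
expectedDistinctAfterThinning <- function(h, p) {
    stopifnot(inherits(h, "DuplicateHistogram"), p >= 0, p <= 1)
    j <- as.integer(names(h$freq))
    sum(h$freq * (1 - (1 - p)^j))
}

#' Solve for the thinning rate reaching a target distinct count
#'
#' Inverts \code{\link{expectedDistinctAfterThinning}} by bisection (the
#' expectation is strictly increasing in p) to absolute tolerance 1e-9.
#'
#' @param h A \code{"DuplicateHistogram"}.
#' @param targetDistinct Desired expected distinct count, in (0, C].
#' @return Keep probability p.
#' @examples
#' solveSubsampleRate(dupHistogram(c(`1` = 100)), 50)  # 0.5
#' @export
solveSubsampleRate <- function(h, targetDistinct) {
    stopifnot(inherits(h, "DuplicateHistogram"))
    if (targetDistinct <= 0)
        stop("target must be positive")
    if (targetDistinct > h$distinct)
        stop(sprintf(
            "target (%.1f) exceeds the observed distinct count (%d)",
            targetDistinct, h$distinct))
    lo <- 0; hi <- 1
    while (hi - lo > 1e-9) {
        mid <- (lo + hi) / 2
        if (expectedDistinctAfterThinning(h, mid) < targetDistinct)
            lo <- mid
        else hi <- mid
    }
    (lo + hi) / 2
}

#' Random subsampling of fragment records
#'
#' Keeps each record independently with probability p using a seeded
#' generator, so results are reproducible for a fixed (input order, p,
#' seed).  Optionally deduplicates AFTER thinning (one record per distinct
#' fragment identity).
#'
#' @param fragments A \linkS4class{FragmentSet} or minimal-fragment
#'   \code{GRanges}.
#' @param p Keep probability.
#' @param seed Integer seed.
#' @param dedup Drop duplicate fragment identities after thinning.
#' @return Object of the same class as \code{fragments}.
#' @export
subsampleFragments <- function(fragments, p, seed, dedup = FALSE) {
    stopifnot(p >= 0, p <= 1)
    n <- length(fragments)
    keep <- if (n == 0L) logical(0) else {
        set.seed(as.integer(seed))
        stats::runif(n) < p
    }
    out <- fragments[keep]
    if (dedup && length(out)) {
        mf <- if (is(out, "FragmentSet")) minimalFragments(out) else out
        sp <- if ("strandPair" %in% colnames(S4Vectors::mcols(mf)))
            mf$strandPair else ""
        key <- paste(GenomeInfoDb::seqnames(mf), start(mf), end(mf), sp,
                     sep = ":")
        out <- out[!duplicated(key)]
    }
    out
}

#' Equalize estimated molecular complexity across libraries
#'
#' ATAC libraries prepared at different transposition efficiencies end up
#' with different numbers of distinct molecules, which confounds count
#' comparisons even at matched read depth.  This routine estimates each
#' library's complexity from its duplicate histogram, takes as target the
#' distinct-fragment count of the least complex library, solves each
#' library's thinning rate so its EXPECTED distinct count matches the
#' target, and subsamples reads accordingly.  The least complex library is
#' left untouched (p = 1); each library uses its own seeded stream
#' (\code{seed + library index}) so adding a library does not perturb the
#' others.
#'
#' @param libraries Named list of \linkS4class{FragmentSet}s or
#'   minimal-fragment \code{GRanges} (>= 2).
#' @param seed Integer base seed.
#' @param dedup Deduplicate after thinning.
#' @return List with \code{libraries} (the thinned inputs) and
#'   \code{report}, a data.frame of per-library reads R, distinct C,
#'   estimated complexity N-hat, thinning rate p and seed used.
#' @export
equalizeComplexity <- function(libraries, seed = 1L, dedup = FALSE) {
    if (length(libraries) < 2L)
        stop("need at least 2 libraries")
    hists <- lapply(libraries, duplicateHistogram)
    nhat <- vapply(hists, function(h) {
        if (h$reads > h$distinct) estimateComplexity(h)$estimate
        else Inf
    }, numeric(1))
    target_lib <- which.min(nhat)
    target <- hists[[target_lib]]$distinct
    p <- vapply(seq_along(libraries), function(i) {
        if (i == target_lib || hists[[i]]$distinct <= target)
            1
        else solveSubsampleRate(hists[[i]], target)
    }, numeric(1))
    thinned <- lapply(seq_along(libraries), function(i) {
        if (p[i] >= 1 && !dedup)
            libraries[[i]]
        else subsampleFragments(libraries[[i]], p[i],
                                seed = as.integer(seed) + i, dedup = dedup)
    })
    names(thinned) <- names(libraries)
    report <- data.frame(
        library = if (is.null(names(libraries)))
            paste0("lib", seq_along(libraries)) else names(libraries),
        reads = vapply(hists, `[[`, numeric(1), "reads"),
        distinct = vapply(hists, `[[`, numeric(1), "distinct"),
        estimated_complexity = nhat,
        target_distinct = target,
        subsample_p = p,
        seed = as.integer(seed) + seq_along(libraries),
        row.names = NULL)
    list(libraries = thinned, report = report)
}
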