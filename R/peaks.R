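#' @importFrom GenomicRanges findOverlaps pintersect reduce resize
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
NULL

#' ENCODE-style naive-overlap consensus peaks
#'
#' Retains the peaks called on pooled replicates that are reproduced in
#' every individual replicate: a pooled peak P is kept iff for EVERY
#' replicate set there is a replicate peak R whose overlap with P covers at
#' least \code{minFrac} of the shorter of the two peaks (the either-peak
#' rule, matching \code{bedtools intersect -e -f 0.5 -F 0.5}); with
#' \code{rule = "pooled"} the fraction is measured against the pooled peak
#' only.  Output order follows the pooled input.
#'
#' @param pooled \link[GenomicRanges]{GRanges} of pooled-replicate peaks.
#' @param replicates List of >= 2 \code{GRanges}, one per replicate.
#' @param minFrac Required overlap fraction (default 0.5).
#' @param rule \code{"either"} (default) or \code{"pooled"}.
#' @return The retained subset of \code{pooled}.
#' @export
naiveOverlap <- function(pooled, replicates, minFrac = 0.5,
                         rule = c("either", "pooled")) {
    rule <- match.arg(rule)
    stopifnot(is(pooled, "GRanges"))
    if (!is.list(replicates) || length(replicates) < 2L)
        stop("need at least 2 replicate peak sets")
    keep <- rep(TRUE, length(pooled))
    for (rep_gr in replicates) {
        stopifnot(is(rep_gr, "GRanges"))
        ok <- rep(FALSE, length(pooled))
        if (length(rep_gr) && length(pooled)) {
            hits <- findOverlaps(pooled, rep_gr)
            if (length(hits)) {
                q <- queryHits(hits); s <- subjectHits(hits)
                ovl <- width(pintersect(pooled[q], rep_gr[s]))
                ref <- if (rule == "either")
                    pmin(width(pooled)[q], width(rep_gr)[s])
                else width(pooled)[q]
                ok[unique(q[ovl >= minFrac * ref])] <- TRUE
            }
        }
        keep <- keep & ok
    }
    pooled[keep]
}

#' Tile a genome with fixed-width sliding windows
#'
#' Windows start at position 0 of each chromosome and advance by
#' \code{spacing}; a window extending past the chromosome end is discarded.
#'
#' @param genome Named vector of chromosome lengths (bp).
#' @param width Window width in bp (default 300).
#' @param spacing Start-to-start distance in bp (default \code{width},
#'   i.e. non-overlapping tiles).
#' @return \link[GenomicRanges]{GRanges} of windows with the genome attached
#'   as seqinfo.
#' @examples
#' makeWindows(c(chr1 = 1000), width = 300)  # 3 windows
#' @export
makeWindows <- function(genome, width = 300L, spacing = width) {
    stopifnot(width > 0L, spacing > 0L)
    si <- genomeSeqinfo(genome)
    grl <- lapply(names(genome), function(chr) {
        L <- genome[[chr]]
        if (L < width)
            return(GRanges(seqinfo = si))
        starts <- seq.int(0L, L - width, by = spacing)
        GRanges(chr, IRanges(starts + 1L, starts + width), seqinfo = si)
    })
    out <- do.call(c, grl)
    metadata(out)$provenance <- "windows"
    out
}

#' Local-background enrichment filter for windows
#'
#' Keeps a window iff its pooled fragment density exceeds the density of its
#' surrounding local neighborhood by more than \code{foldThreshold}.  The
#' neighborhood count is first rescaled to the window's width, then a 0.5
#' continuity correction is added to both window-width-equivalent counts,
#' so empty windows over empty background give a ratio of exactly 1
#' (dropped for any threshold > 1) and division by zero never occurs.
#'
#' @param windowCounts,neighborhoodCounts Row-aligned count matrices (or
#'   \linkS4class{AtacCountExperiment}s) for the windows and for their
#'   flanking neighborhoods (the window's own fragments excluded).
#' @param width Window width in bp.
#' @param neighborhood Total neighborhood span in bp; the flank length used
#'   for the background density is \code{neighborhood - width}.
#' @param foldThreshold Required linear fold enrichment (default 3).
#' @param prior Continuity correction (default 0.5).
#' @return Logical keep-mask, one element per window.
#' @export
localEnrichmentFilter <- function(windowCounts, neighborhoodCounts,
                                  width = 300L, neighborhood = 2000L,
                                  foldThreshold = 3, prior = 0.5) {
    wc <- if (is(windowCounts, "AtacCountExperiment"))
        SummarizedExperiment::assay(windowCounts, "counts") else as.matrix(windowCounts)
    nc <- if (is(neighborhoodCounts, "AtacCountExperiment"))
        SummarizedExperiment::assay(neighborhoodCounts, "counts") else as.matrix(neighborhoodCounts)
    if (nrow(wc) != nrow(nc))
        stop("window and neighborhood count matrices must be row-aligned")
    stopifnot(neighborhood > width, foldThreshold > 1)
    w <- rowSums(wc) + prior
    b <- rowSums(nc) * width / (neighborhood - width) + prior
    w / b > foldThreshold
}

#' Count fragments in window neighborhoods
#'
#' Convenience helper computing, for each window, the pooled per-sample
#' count of fragments overlapping the \code{neighborhood}-wide interval
#' centred on the window minus the fragments counted in the window itself
#' (csaw's local-background idiom).
#'
#' @param fragments List of minimal-fragment \code{GRanges}, one per sample.
#' @param windows Window \code{GRanges}.
#' @param neighborhood Neighborhood span in bp (default 2000).
#' @return Matrix of neighborhood counts, windows x samples.
#' @export
neighborhoodCounts <- function(fragments, windows, neighborhood = 2000L) {
    wide <- suppressWarnings(resize(windows, neighborhood, fix = "center"))
    wideC <- vapply(fragments, function(fr)
        GenomicRanges::countOverlaps(wide, fr, minoverlap = 1L),
        numeric(length(windows)))
    winC <- vapply(fragments, function(fr)
        GenomicRanges::countOverlaps(windows, fr, minoverlap = 1L),
        numeric(length(windows)))
    m <- pmax(wideC - winC, 0)
    if (is.null(dim(m)))
        m <- matrix(m, nrow = length(windows))
    m
}

#' Low-abundance region filter
#'
#' Keeps a region iff its average log2-CPM across all samples (at effective
#' library sizes) reaches \code{minAbundance}.  The default cutoff is the
#' abundance of a hypothetical region holding 5 fragments at the mean
#' library size.
#'
#' @param counts An \linkS4class{AtacCountExperiment} or count matrix.
#' @param minAbundance Average log2-CPM cutoff; \code{NULL} for the default.
#' @param effLibSizes Effective library sizes; defaults to the object's
#'   library sizes.
#' @param prior Prior count for the log2-CPM transform.
#' @return Logical keep-mask.
#' @export
abundanceFilter <- function(counts, minAbundance = NULL, effLibSizes = NULL,
                            prior = 0.5) {
    cnt <- if (is(counts, "AtacCountExperiment"))
        SummarizedExperiment::assay(counts, "counts") else as.matrix(counts)
    if (is.null(effLibSizes)) {
        effLibSizes <- if (is(counts, "AtacCountExperiment")) libSizes(counts)
                       else colSums(cnt)
    }
    if (is.null(minAbundance))
        minAbundance <- log2((5 + prior) / (mean(effLibSizes) + 1) * 1e6)
    ave <- rowMeans(log2cpm(cnt, effLibSizes, prior = prior))
    ave >= minAbundance
}

#' Simes combined p-value
#'
#' For member p-values p(1) <= ... <= p(k), the Simes combination is
#' min_i k p(i) / i — a valid p-value for the union null under independence
#' (and positive dependence), used when merging adjacent tested windows.
#'
#' @param p Numeric vector of member p-values.
#' @return Combined p-value.
#' @examples
#' simesP(c(0.01, 0.04))  # 0.02
#' @export
simesP <- function(p) {
    p <- p[!is.na(p)]
    if (!length(p))
        return(NA_real_)
    k <- length(p)
    min(k * sort(p) / seq_len(k))
}

#' Merge adjacent significant windows into regions
#'
#' Windows on the same chromosome separated by at most \code{gap} bp are
#' unioned into one region; each merged region receives the Simes
#' combination of its members' p-values (valid type-I error control for the
#' merged test), the log fold change of the member with the smallest
#' p-value, and a BH FDR computed across merged regions.
#'
#' @param da A \linkS4class{DAResult} computed on windows (coordinate
#'   sorted).
#' @param gap Maximum inter-window gap in bp (default 100).
#' @return \link[GenomicRanges]{GRanges} of merged regions with metadata
#'   columns \code{nWindows}, \code{combined_p}, \code{fdr}, \code{logFC}
#'   and the member window indices in \code{revmap}.
#' @export
mergeWindows <- function(da, gap = 100L) {
    stopifnot(is(da, "DAResult"))
    win <- daRegions(da)
    tb <- daTable(da)
    if (length(win) == 0L)
        return(GRanges(nWindows = integer(), combined_p = numeric(),
                       fdr = numeric(), logFC = numeric()))
    merged <- reduce(win, min.gapwidth = gap + 1L, with.revmap = TRUE)
    rev <- mcols(merged)$revmap
    combined <- vapply(rev, function(i) simesP(tb$p[i]), numeric(1))
    lfc <- vapply(rev, function(i) tb$logFC[i][which.min(tb$p[i])], numeric(1))
    mcols(merged)$nWindows <- lengths(rev)
    mcols(merged)$combined_p <- combined
    mcols(merged)$fdr <- bhFdr(combined)
    mcols(merged)$logFC <- lfc
    merged
}
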