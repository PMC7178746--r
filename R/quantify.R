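#' @importFrom GenomicRanges countOverlaps
NULL

#' Count fragments overlapping query regions
#'
#' Cell (g, i) is the number of sample-i fragments whose minimal span
#' overlaps region g by at least 1 bp.  A fragment overlapping two regions
#' increments both (overlap counting, csaw's idiom); \code{mode =
#' "midpoint"} instead assigns each fragment to the region containing its
#' midpoint.
#'
#' @param fragments Named list of minimal-fragment \code{GRanges} (or
#'   \linkS4class{FragmentSet}s), one per sample.
#' @param regions Query \link[GenomicRanges]{GRanges}.
#' @param libSizes Per-library total fragment counts; defaults to
#'   \code{lengths(fragments)}.
#' @param condition Group labels, one per sample.
#' @param mode \code{"overlap"} (default) or \code{"midpoint"}.
#' @return An \linkS4class{AtacCountExperiment}.
#' @export
countFragments <- function(fragments, regions, libSizes = NULL,
                           condition = NULL, mode = c("overlap", "midpoint")) {
    mode <- match.arg(mode)
    fragments <- lapply(fragments, function(f)
        if (is(f, "FragmentSet")) minimalFragments(f) else f)
    cnt <- vapply(fragments, function(fr) {
        if (mode == "midpoint") {
            mid <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(fr),
                IRanges(start(fr) + (width(fr) - 1L) %/% 2L, width = 1L))
            countOverlaps(regions, mid)
        } else {
            countOverlaps(regions, fr, minoverlap = 1L)
        }
    }, numeric(length(regions)))
    if (is.null(dim(cnt)))
        cnt <- matrix(cnt, nrow = length(regions))
    if (!is.null(names(fragments)))
        colnames(cnt) <- names(fragments)
    if (is.null(libSizes))
        libSizes <- vapply(fragments, length, numeric(1))
    AtacCountExperiment(cnt, regions, libSizes = libSizes,
                        condition = condition)
}

#' Count fragments in large genomic bins
#'
#' Tiles each chromosome with non-overlapping bins of \code{binWidth} bp
#' (default 10 kb; a trailing partial bin is dropped) and counts fragments
#' per bin.  Bin counts feed scale-factor normalization (TMM), where
#' genome-scale background rather than peak signal should determine the
#' factors.
#'
#' @param fragments Named list of minimal-fragment \code{GRanges} or
#'   \linkS4class{FragmentSet}s.
#' @param genome Named vector of chromosome lengths.
#' @param binWidth Bin width in bp.
#' @param libSizes,condition Passed to \code{\link{countFragments}}.
#' @return An \linkS4class{AtacCountExperiment} over the bins.
#' @export
binGenomeCounts <- function(fragments, genome, binWidth = 10000L,
                            libSizes = NULL, condition = NULL) {
    bins <- makeWindows(genome, width = binWidth, spacing = binWidth)
    metadata(bins)$provenance <- "bins"
    countFragments(fragments, bins, libSizes = libSizes,
                   condition = condition)
}

#' Fraction of reads in peaks (FRiP)
#'
#' Per-library enrichment efficiency: the fraction of all library fragments
#' that fall inside the peak set.  Requires the experiment's library sizes
#' to be full-library totals.
#'
#' @param counts An \linkS4class{AtacCountExperiment} counted over peaks.
#' @return Named numeric vector of per-sample FRiP scores in [0, 1].
#' @export
frip <- function(counts) {
    stopifnot(is(counts, "AtacCountExperiment"))
    L <- libSizes(counts)
    if (any(L == 0))
        stop("library sizes must be positive to compute FRiP")
    inPeaks <- colSums(SummarizedExperiment::assay(counts, "counts"))
    pmin(inPeaks / L, 1)
}

#' Log2 counts per million
#'
#' The voom-style transform: log2((count + prior) / (L + 1) * 1e6), with
#' prior 0.5 and the +1 library-size stabilizer.
#'
#' @param counts Count matrix or \linkS4class{AtacCountExperiment}.
#' @param effLibSizes Effective library sizes per sample; defaults to the
#'   experiment's library sizes.
#' @param prior Prior count (default 0.5).
#' @return Matrix of log2-CPM values with the input dimensions.
#' @examples
#' log2cpm(matrix(0), effLibSizes = 1e6 - 1)  # log2(0.5) = -1
#' @export
log2cpm <- function(counts, effLibSizes = NULL, prior = 0.5) {
    cnt <- if (is(counts, "AtacCountExperiment"))
        SummarizedExperiment::assay(counts, "counts") else as.matrix(counts)
    if (is.null(effLibSizes)) {
        if (!is(counts, "AtacCountExperiment"))
            stop("effLibSizes required for plain matrices")
        effLibSizes <- libSizes(counts)
    }
    stopifnot(all(effLibSizes > 0), length(effLibSizes) == ncol(cnt))
    log2(t((t(cnt) + prior) / (effLibSizes + 1)) * 1e6)
}

#' Average abundance (A) per region
#'
#' @param counts Count matrix or \linkS4class{AtacCountExperiment}.
#' @param effLibSizes,prior As in \code{\link{log2cpm}}.
#' @return Numeric vector of per-region mean log2-CPM.
#' @export
aveLog2cpm <- function(counts, effLibSizes = NULL, prior = 0.5) {
    rowMeans(log2cpm(counts, effLibSizes, prior = prior))
}
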