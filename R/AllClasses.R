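#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Paired-end ATAC fragment set
#'
#' An S4 container for paired-end ATAC-seq fragments in the 10-column BEDPE
#' dialect: one record per sequenced fragment, holding both mate intervals
#' (0-based half-open), mate strands, a name and a score.  Both mates must lie
#' on the same chromosome and carry opposite strands (a properly paired
#' fragment).  The \code{shifted} flag records whether Tn5 insertion-site
#' correction has already been applied, so downstream steps can refuse to
#' shift twice.
#'
#' @slot records A \link[S4Vectors]{DataFrame} with columns \code{chrom},
#'   \code{m1_start}, \code{m1_end}, \code{m2_start}, \code{m2_end},
#'   \code{name}, \code{score}, \code{m1_strand}, \code{m2_strand}; any extra
#'   columns read from a file are preserved verbatim.
#' @slot shifted Logical scalar; \code{TRUE} after \code{\link{tn5Shift}}.
#'
#' @seealso \code{\link{readBedpe}}, \code{\link{tn5Shift}},
#'   \code{\link{minimalFragments}}
#' @export
setClass("FragmentSet",
    representation(records = "DataFrame", shifted = "logical"),
    prototype(shifted = FALSE))

.FRAG_COLS <- c("chrom", "m1_start", "m1_end", "m2_start", "m2_end",
                "name", "score", "m1_strand", "m2_strand")

setValidity("FragmentSet", function(object) {
    rec <- object@records
    miss <- setdiff(.FRAG_COLS, colnames(rec))
    if (length(miss))
        return(paste("missing columns:", paste(miss, collapse = ", ")))
    if (nrow(rec) == 0L)
        return(TRUE)
    for (m in c("m1", "m2")) {
        s <- rec[[paste0(m, "_start")]]
        e <- rec[[paste0(m, "_end")]]
        if (any(s < 0))
            return(sprintf("%s has negative start coordinates", m))
        if (any(s >= e))
            return(sprintf("%s has start >= end (0-based half-open required)", m))
    }
    st <- cbind(rec$m1_strand, rec$m2_strand)
    if (!all(st %in% c("+", "-")))
        return("mate strands must be '+' or '-'")
    if (any(rec$m1_strand == rec$m2_strand))
        return("mates of a proper pair must carry opposite strands")
    if (length(object@shifted) != 1L)
        return("'shifted' must be a logical scalar")
    TRUE
})

#' Construct a FragmentSet
#'
#' @param records A data.frame or DataFrame carrying the nine standard BEDPE
#'   fragment columns (see \linkS4class{FragmentSet}); extra columns are kept.
#' @param shifted Logical; whether Tn5 shifting has already been applied.
#' @return A \linkS4class{FragmentSet}.
#' @examples
#' fs <- FragmentSet(data.frame(chrom = "chr1",
#'     m1_start = 100, m1_end = 150, m2_start = 180, m2_end = 230,
#'     name = "frag1", score = 0, m1_strand = "+", m2_strand = "-"))
#' length(fs)
#' @export
FragmentSet <- function(records = DataFrame(), shifted = FALSE) {
    rec <- as(records, "DataFrame")
    if (nrow(rec) == 0L && !all(.FRAG_COLS %in% colnames(rec))) {
        rec <- DataFrame(chrom = character(), m1_start = integer(),
                         m1_end = integer(), m2_start = integer(),
                         m2_end = integer(), name = character(),
                         score = numeric(), m1_strand = character(),
                         m2_strand = character())
    }
    for (col in c("m1_start", "m1_end", "m2_start", "m2_end"))
        rec[[col]] <- as.integer(rec[[col]])
    new("FragmentSet", records = rec, shifted = shifted)
}

#' @describeIn FragmentSet number of fragments
#' @param x A FragmentSet.
#' @export
setMethod("length", "FragmentSet", function(x) nrow(x@records))

#' @export
setMethod("show", "FragmentSet", function(object) {
    cat(sprintf("FragmentSet with %d fragments (%s)\n", length(object),
        if (object@shifted) "Tn5-shifted" else "unshifted"))
    if (length(object)) {
        rec <- object@records
        n <- min(5L, nrow(rec))
        print(as.data.frame(rec[seq_len(n), .FRAG_COLS]))
        if (nrow(rec) > n) cat("...\n")
    }
})

#' @export
setMethod("[", "FragmentSet", function(x, i, j, ..., drop = FALSE) {
    initialize(x, records = x@records[i, , drop = FALSE])
})

#' Fragment records as a data.frame
#' @param x A \linkS4class{FragmentSet}.
#' @param row.names,optional,... Passed on for S3 compatibility; unused.
#' @return data.frame of the underlying records.
#' @export
as.data.frame.FragmentSet <- function(x, row.names = NULL, optional = FALSE, ...) {
    as.data.frame(x@records)
}

#' @export
setMethod("as.data.frame", "FragmentSet", as.data.frame.FragmentSet)

#' Has the Tn5 coordinate shift been applied?
#' @param x A \linkS4class{FragmentSet}.
#' @return Logical scalar.
#' @export
isShifted <- function(x) {
    stopifnot(is(x, "FragmentSet"))
    x@shifted
}

#' ATAC-seq count experiment
#'
#' A \link[SummarizedExperiment]{RangedSummarizedExperiment} subclass holding
#' integer fragment counts for a set of query regions (peaks, windows or
#' genomic bins) across samples.  \code{colData} must carry a \code{libSize}
#' column with the TOTAL post-filter fragment count of each library (not the
#' column sum, since regions usually cover only part of the genome) and a
#' \code{condition} column with the group labels used for differential
#' testing.
#'
#' @seealso \code{\link{countFragments}}, \code{\link{libSizes}},
#'   \code{\link{sampleConditions}}
#' @export
#' @import SummarizedExperiment
setClass("AtacCountExperiment", contains = "RangedSummarizedExperiment")

setValidity("AtacCountExperiment", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0) || any(cnt != round(cnt)))
        return("counts must be non-negative integers")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("libSize", "condition") %in% colnames(cd)))
        return("colData must contain 'libSize' and 'condition'")
    if (any(cd$libSize < 0))
        return("libSize must be non-negative")
    TRUE
})

#' Construct an AtacCountExperiment
#'
#' @param counts Integer matrix, regions x samples.
#' @param rowRanges \link[GenomicRanges]{GRanges} of the counted regions
#'   (one per matrix row).
#' @param libSizes Numeric vector of per-library total fragment counts; when
#'   missing, the matrix column sums are used (and noted in the metadata).
#' @param condition Factor/character of group labels, one per sample.
#' @return An \linkS4class{AtacCountExperiment}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 500), width = 300))
#' m <- matrix(1:4, nrow = 2, dimnames = list(NULL, c("a", "b")))
#' ace <- AtacCountExperiment(m, gr, libSizes = c(100, 120),
#'                            condition = c("ctl", "mut"))
#' libSizes(ace)
#' @export
AtacCountExperiment <- function(counts, rowRanges, libSizes = NULL,
                                condition = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    from_colsums <- is.null(libSizes)
    if (from_colsums)
        libSizes <- colSums(counts)
    if (is.null(condition))
        condition <- rep("all", ncol(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowRanges = rowRanges,
        colData = DataFrame(libSize = as.numeric(libSizes),
                            condition = factor(condition),
                            row.names = colnames(counts)))
    obj <- new("AtacCountExperiment", se)
    metadata(obj)$libSizeSource <-
        if (from_colsums) "column sums" else "supplied totals"
    obj
}

#' Per-library total fragment counts
#' @param x An \linkS4class{AtacCountExperiment}.
#' @return Named numeric vector of library sizes.
#' @export
libSizes <- function(x) {
    stopifnot(is(x, "AtacCountExperiment"))
    stats::setNames(SummarizedExperiment::colData(x)$libSize, colnames(x))
}

#' Sample condition labels
#' @param x An \linkS4class{AtacCountExperiment}.
#' @return Factor of condition labels, one per sample.
#' @export
sampleConditions <- function(x) {
    stopifnot(is(x, "AtacCountExperiment"))
    SummarizedExperiment::colData(x)$condition
}

#' Result of a count normalization method
#'
#' Normalization methods differ in what they produce: scale-factor methods
#' (\code{libsize}, \code{reads_in_peaks}, \code{tmm}) yield one positive
#' factor per sample with unit geometric mean, consumed as effective library
#' sizes; \code{loess} yields a regions x samples matrix of log2-scale
#' offsets, row-centred, subtracted from log2-CPM before testing;
#' \code{quantile} yields the transformed log2-CPM matrix directly;
#' \code{log2cpm_only} is the identity on log2-CPM (full-library scaling and
#' nothing else).
#'
#' @slot method One of \code{"libsize"}, \code{"reads_in_peaks"},
#'   \code{"tmm"}, \code{"loess"}, \code{"log2cpm_only"}, \code{"quantile"}.
#' @slot factors Per-sample scale factors (factor methods), else \code{NULL}.
#' @slot offsets Log2-scale offset matrix (loess), else \code{NULL}.
#' @slot transformed Normalized matrix (quantile), else \code{NULL}.
#' @slot effLibSizes Effective library sizes \eqn{L_i s_i} for factor
#'   methods, else \code{NULL}.
#' @slot details Method-specific diagnostics (e.g. TMM reference sample).
#' @export
setClass("NormalizationResult",
    representation(method = "character", factors = "numericOrNULL",
                   offsets = "matrixOrNULL", transformed = "matrixOrNULL",
                   effLibSizes = "numericOrNULL", details = "list"),
    prototype(details = list()))

.NORM_METHODS <- c("libsize", "reads_in_peaks", "tmm", "loess",
                   "log2cpm_only", "quantile")

setValidity("NormalizationResult", function(object) {
    if (length(object@method) != 1L || !object@method %in% .NORM_METHODS)
        return(paste("method must be one of:",
                     paste(.NORM_METHODS, collapse = ", ")))
    if (!is.null(object@factors)) {
        if (any(object@factors <= 0))
            return("scale factors must be positive")
        gm <- exp(mean(log(object@factors)))
        if (abs(gm - 1) > 1e-8)
            return("scale factors must have geometric mean 1")
    }
    if (!is.null(object@offsets)) {
        rm <- rowMeans(object@offsets)
        if (max(abs(rm)) > 1e-8)
            return("loess offsets must be row-centred")
    }
    TRUE
})

#' @export
setMethod("show", "NormalizationResult", function(object) {
    cat(sprintf("NormalizationResult [%s]\n", object@method))
    if (!is.null(object@factors)) {
        cat("  factors: ")
        cat(signif(object@factors, 4), sep = ", ")
        cat("\n")
    }
    if (!is.null(object@offsets))
        cat(sprintf("  offsets: %d x %d log2-scale matrix\n",
            nrow(object@offsets), ncol(object@offsets)))
    if (!is.null(object@transformed))
        cat(sprintf("  transformed: %d x %d matrix\n",
            nrow(object@transformed), ncol(object@transformed)))
})

#' Normalization method tag
#' @param x A \linkS4class{NormalizationResult}.
#' @return Character scalar method tag.
#' @export
normMethod <- function(x) {
    stopifnot(is(x, "NormalizationResult"))
    x@method
}

#' Per-sample scale factors of a factor-based normalization
#' @param x A \linkS4class{NormalizationResult}.
#' @return Numeric vector of factors (geometric mean 1), or NULL for
#'   offset/transform methods.
#' @export
normFactors <- function(x) {
    stopifnot(is(x, "NormalizationResult"))
    x@factors
}

#' Log2-scale normalization offsets
#' @param x A \linkS4class{NormalizationResult}.
#' @return Offset matrix or NULL.
#' @export
normOffsets <- function(x) {
    stopifnot(is(x, "NormalizationResult"))
    x@offsets
}

#' Effective library sizes implied by a factor normalization
#' @param x A \linkS4class{NormalizationResult}.
#' @return Numeric vector L_i * s_i, or NULL.
#' @export
effectiveLibSizes <- function(x) {
    stopifnot(is(x, "NormalizationResult"))
    x@effLibSizes
}

#' Differential accessibility result
#'
#' Per-region output of a DA engine: log2 fold change (M), average abundance
#' (A, log2-CPM), raw p-value, Benjamini-Hochberg FDR, and the call direction
#' (sign of logFC for regions below the significance threshold, 0 otherwise).
#'
#' @slot regions \link[GenomicRanges]{GRanges} of the tested regions.
#' @slot table \link[S4Vectors]{DataFrame} with columns \code{logFC},
#'   \code{A}, \code{p}, \code{fdr}, \code{direction}.
#' @slot engine \code{"moderated"} or \code{"nb_exact"}.
#' @slot params List with the run provenance (normalization method, FDR
#'   threshold, design, hyperparameters).
#' @export
setClass("DAResult",
    representation(regions = "GRanges", table = "DataFrame",
                   engine = "character", params = "list"),
    prototype(engine = "moderated", params = list()))

setValidity("DAResult", function(object) {
    tb <- object@table
    need <- c("logFC", "A", "p", "fdr", "direction")
    if (!all(need %in% colnames(tb)))
        return(paste("table must contain:", paste(need, collapse = ", ")))
    if (nrow(tb) != length(object@regions))
        return("table rows must align with regions")
    if (nrow(tb)) {
        if (any(tb$p < 0 | tb$p > 1, na.rm = TRUE))
            return("p-values must lie in [0,1]")
        if (any(tb$fdr < tb$p - 1e-12, na.rm = TRUE))
            return("BH FDR cannot be smaller than the raw p-value")
    }
    TRUE
})

#' Construct a DAResult
#' @param regions GRanges of tested regions.
#' @param logFC,A,p Per-region statistics (log2 fold change, abundance,
#'   raw p-value).
#' @param fdr Optional precomputed BH-FDR; computed from \code{p} if missing.
#' @param fdrThreshold Significance cutoff used to set the direction column.
#' @param engine Engine tag.
#' @param params Provenance list.
#' @return A \linkS4class{DAResult}.
#' @export
DAResult <- function(regions, logFC, A, p, fdr = NULL, fdrThreshold = 0.10,
                     engine = "moderated", params = list()) {
    if (is.null(fdr))
        fdr <- bhFdr(p)
    direction <- ifelse(!is.na(fdr) & fdr < fdrThreshold, sign(logFC), 0)
    params$fdrThreshold <- fdrThreshold
    new("DAResult", regions = regions,
        table = DataFrame(logFC = logFC, A = A, p = p, fdr = fdr,
                          direction = direction),
        engine = engine, params = params)
}

#' @export
setMethod("length", "DAResult", function(x) nrow(x@table))

#' @export
setMethod("show", "DAResult", function(object) {
    thr <- object@params$fdrThreshold
    sig <- sum(object@table$fdr < thr, na.rm = TRUE)
    cat(sprintf("DAResult: %d regions tested (%s engine)\n",
        length(object), object@engine))
    cat(sprintf("  %d significant at FDR < %g (%d up / %d down)\n", sig, thr,
        sum(object@table$direction > 0), sum(object@table$direction < 0)))
})

#' Per-region DA statistics
#' @param x A \linkS4class{DAResult}.
#' @return DataFrame with logFC, A, p, fdr, direction.
#' @export
daTable <- function(x) {
    stopifnot(is(x, "DAResult"))
    x@table
}

#' Tested regions of a DAResult
#' @param x A \linkS4class{DAResult}.
#' @return GRanges aligned with \code{daTable(x)}.
#' @export
daRegions <- function(x) {
    stopifnot(is(x, "DAResult"))
    x@regions
}
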