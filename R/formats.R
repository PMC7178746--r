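#' @importFrom utils read.table write.table
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom GenomeInfoDb Seqinfo seqlengths
NULL

#' Read a 10-column BEDPE fragment file
#'
#' Parses a tab-separated paired-end BEDPE file into a
#' \linkS4class{FragmentSet}.  The first ten standard columns (chrom1,
#' start1, end1, chrom2, start2, end2, name, score, strand1, strand2) are
#' interpreted; extra columns are preserved verbatim and written back
#' unchanged by \code{\link{writeBedpe}}.  Coordinates are 0-based
#' half-open.  Mates must be on one chromosome with opposite strands.
#'
#' @param path Path to a BEDPE file.
#' @param shifted Logical; set \code{TRUE} if the file already carries
#'   Tn5-shifted coordinates.
#' @return A \linkS4class{FragmentSet}.
#' @seealso \code{\link{writeBedpe}}, \code{\link{tn5Shift}}
#' @export
readBedpe <- function(path, shifted = FALSE) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(FragmentSet(shifted = shifted))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 10L)) {
        bad <- which(nf < 10L)[1L]
        stop(sprintf("malformed BEDPE line %d: %d column(s), need >= 10",
                     bad, nf[bad]))
    }
    get <- function(i) vapply(fields, `[[`, character(1), i)
    rec <- DataFrame(chrom = get(1),
                     m1_start = suppressWarnings(as.integer(get(2))),
                     m1_end = suppressWarnings(as.integer(get(3))),
                     chrom2 = get(4),
                     m2_start = suppressWarnings(as.integer(get(5))),
                     m2_end = suppressWarnings(as.integer(get(6))),
                     name = get(7), score = suppressWarnings(as.numeric(get(8))),
                     m1_strand = get(9), m2_strand = get(10))
    bad <- which(is.na(rec$m1_start) | is.na(rec$m1_end) |
                 is.na(rec$m2_start) | is.na(rec$m2_end))
    if (length(bad))
        stop(sprintf("malformed BEDPE line %d: non-numeric coordinate", bad[1L]))
    bad <- which(rec$chrom != rec$chrom2)
    if (length(bad))
        stop(sprintf("malformed BEDPE line %d: mates on different chromosomes",
                     bad[1L]))
    bad <- which(rec$m1_start >= rec$m1_end | rec$m2_start >= rec$m2_end)
    if (length(bad))
        stop(sprintf("malformed BEDPE line %d: start >= end", bad[1L]))
    rec$chrom2 <- NULL
    if (any(nf > 10L)) {
        for (k in seq_len(max(nf) - 10L)) {
            rec[[paste0("extra", k)]] <-
                vapply(fields, function(f)
                    if (length(f) >= 10L + k) f[[10L + k]] else "",
                    character(1))
        }
    }
    FragmentSet(rec, shifted = shifted)
}

#' Write a FragmentSet to 10-column BEDPE
#'
#' Round-trips with \code{\link{readBedpe}}: the ten standard columns are
#' written byte-identically for valid inputs, and extra columns follow.
#'
#' @param x A \linkS4class{FragmentSet}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeBedpe <- function(x, path) {
    stopifnot(is(x, "FragmentSet"))
    rec <- x@records
    out <- data.frame(rec$chrom, rec$m1_start, rec$m1_end,
                      rec$chrom, rec$m2_start, rec$m2_end,
                      rec$name, rec$score, rec$m1_strand, rec$m2_strand,
                      check.names = FALSE)
    extra <- setdiff(colnames(rec), .FRAG_COLS)
    for (col in extra)
        out[[col]] <- rec[[col]]
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Tn5 insertion-site coordinate shift
#'
#' The Tn5 transposase inserts adapters as a dimer and duplicates 9 bp of
#' target sequence, so the sequenced 5' ends do not coincide with the centre
#' of the insertion event.  The community-standard correction moves each
#' mate's 5' coordinate inward: plus-strand mates have their start increased
#' by 4 bp, minus-strand mates have their end decreased by 5 bp.  All other
#' fields are untouched.  The returned set carries \code{shifted = TRUE} and
#' the function refuses to shift an already-shifted set.
#'
#' @param x A \linkS4class{FragmentSet} with mate strands present.
#' @param plusShift,minusShift Shift magnitudes (defaults +4 / -5 bp).
#' @return The shifted \linkS4class{FragmentSet}.
#' @examples
#' fs <- FragmentSet(data.frame(chrom = "chr1",
#'     m1_start = 100, m1_end = 150, m2_start = 180, m2_end = 230,
#'     name = ".", score = 0, m1_strand = "+", m2_strand = "-"))
#' as.data.frame(tn5Shift(fs))[, c("m1_start", "m2_end")]  # 104, 225
#' @export
tn5Shift <- function(x, plusShift = 4L, minusShift = 5L) {
    stopifnot(is(x, "FragmentSet"))
    if (isShifted(x))
        stop("FragmentSet is already Tn5-shifted; refusing to shift twice")
    rec <- x@records
    if (nrow(rec) == 0L)
        return(initialize(x, shifted = TRUE))
    shift_mate <- function(s, e, strand) {
        plus <- strand == "+"
        s[plus] <- s[plus] + as.integer(plusShift)
        e[!plus] <- e[!plus] - as.integer(minusShift)
        list(s = s, e = e)
    }
    m1 <- shift_mate(rec$m1_start, rec$m1_end, rec$m1_strand)
    m2 <- shift_mate(rec$m2_start, rec$m2_end, rec$m2_strand)
    bad <- which(m1$s >= m1$e | m2$s >= m2$e | m1$s < 0L | m2$s < 0L |
                 m1$e <= 0L | m2$e <= 0L)
    if (length(bad))
        stop(sprintf(
            "Tn5 shift collapses or underflows record %d ('%s')",
            bad[1L], rec$name[bad[1L]]))
    rec$m1_start <- m1$s; rec$m1_end <- m1$e
    rec$m2_start <- m2$s; rec$m2_end <- m2$e
    initialize(x, records = rec, shifted = TRUE)
}

#' Convert paired fragments to minimal fragment spans
#'
#' Collapses each 10-column BEDPE record to the outermost fragment span
#' [min(mate starts), max(mate ends)), the "minimal" single-interval dialect
#' used for fragment-level counting and duplicate detection.
#'
#' @param x A \linkS4class{FragmentSet}.
#' @return A \link[GenomicRanges]{GRanges} of fragment spans with metadata
#'   columns \code{name}, \code{score} and \code{strandPair} (the ordered
#'   mate-strand pair, part of the duplicate identity tuple).
#' @export
minimalFragments <- function(x) {
    stopifnot(is(x, "FragmentSet"))
    rec <- x@records
    if (nrow(rec) == 0L)
        return(GRanges(name = character(), score = numeric(),
                       strandPair = character()))
    s <- pmin(rec$m1_start, rec$m2_start)
    e <- pmax(rec$m1_end, rec$m2_end)
    GRanges(rec$chrom, IRanges(s + 1L, e),  # GRanges is 1-based closed
            name = rec$name, score = rec$score,
            strandPair = paste0(rec$m1_strand, rec$m2_strand))
}

#' Remove records overlapping blacklisted regions
#'
#' ENCODE blacklist regions are highly repetitive or unstructured loci with
#' artifactually high signal; any record overlapping a blacklist interval by
#' at least 1 bp is dropped.  Works on interval sets (\code{GRanges}) and on
#' \linkS4class{FragmentSet}s (tested on the minimal fragment span).
#' Survivor order is preserved.
#'
#' @param x A \link[GenomicRanges]{GRanges} or \linkS4class{FragmentSet}.
#' @param blacklist \link[GenomicRanges]{GRanges} of regions to exclude.
#' @return Object of the same class as \code{x} with overlapping records
#'   removed.
#' @export
filterBlacklist <- function(x, blacklist) {
    stopifnot(is(blacklist, "GRanges"))
    if (is(x, "FragmentSet")) {
        if (length(x) == 0L || length(blacklist) == 0L)
            return(x)
        hit <- overlapsAny(minimalFragments(x), blacklist, minoverlap = 1L)
        return(x[!hit])
    }
    stopifnot(is(x, "GRanges"))
    if (length(x) == 0L || length(blacklist) == 0L)
        return(x)
    x[!overlapsAny(x, blacklist, minoverlap = 1L)]
}

#' Drop fragments on user-named chromosomes
#'
#' Typically used to remove mitochondrial fragments (e.g. \code{"chrM"}).
#'
#' @param x A \linkS4class{FragmentSet}.
#' @param chroms Character vector of chromosome names to drop.
#' @return Filtered \linkS4class{FragmentSet}.
#' @export
dropChroms <- function(x, chroms) {
    stopifnot(is(x, "FragmentSet"))
    if (length(x) == 0L)
        return(x)
    x[!(x@records$chrom %in% chroms)]
}

#' Read a chrom.sizes genome table
#'
#' @param path Two-column tab-separated file: chromosome name, length (bp).
#' @return Named integer vector of chromosome lengths (a genome table).
#' @export
readGenomeTable <- function(path) {
    tb <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("chrom", "length"),
                     colClasses = c("character", "integer"))
    if (anyDuplicated(tb$chrom))
        stop("duplicated chromosome names in genome table")
    if (any(tb$length <= 0))
        stop("chromosome lengths must be positive")
    stats::setNames(tb$length, tb$chrom)
}

#' Genome table as a Seqinfo
#' @param genome Named vector of chromosome lengths.
#' @return A \link[GenomeInfoDb]{Seqinfo}.
#' @export
genomeSeqinfo <- function(genome) {
    Seqinfo(seqnames = names(genome), seqlengths = unname(genome))
}

#' Read ENCODE peak / BED interval files
#'
#' Reads BED3/BED6 and ENCODE broadPeak (9-column) / narrowPeak (10-column)
#' files into a \link[GenomicRanges]{GRanges}.  Peak formats carry
#' \code{signalValue}, \code{pValue} and \code{qValue} metadata columns
#' (plus \code{peak} for narrowPeak summit offsets).
#'
#' @param path Input file path.
#' @param format One of \code{"auto"}, \code{"bed"}, \code{"broadPeak"},
#'   \code{"narrowPeak"}; \code{"auto"} decides from the file extension and
#'   column count.
#' @return A \link[GenomicRanges]{GRanges}.
#' @export
readPeakFile <- function(path, format = c("auto", "bed", "broadPeak",
                                          "narrowPeak")) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, broadpeak = "broadPeak",
                         narrowpeak = "narrowPeak", "bed")
        if (format == "bed") {
            first <- readLines(path, n = 1L)
            nf <- length(strsplit(first, "\t", fixed = TRUE)[[1L]])
            if (nf == 9L) format <- "broadPeak"
            if (nf == 10L) format <- "narrowPeak"
        }
    }
    extra <- switch(format,
        broadPeak = c(signalValue = "numeric", pValue = "numeric",
                      qValue = "numeric"),
        narrowPeak = c(signalValue = "numeric", pValue = "numeric",
                       qValue = "numeric", peak = "integer"),
        NULL)
    gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
    as(gr, "GRanges")
}

#' Write regions to BED6 with ENCODE-scaled scores
#'
#' Scores are written as \code{-10 log10(p)} capped at 1000 when a
#' \code{combined_p} metadata column is present, otherwise the existing
#' score (or 0).
#'
#' @param regions A \link[GenomicRanges]{GRanges}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeBed6 <- function(regions, path) {
    mc <- S4Vectors::mcols(regions)
    score <- if ("combined_p" %in% colnames(mc)) {
        pmin(round(-10 * log10(pmax(mc$combined_p, 1e-300))), 1000)
    } else if ("score" %in% colnames(mc)) {
        mc$score
    } else rep(0, length(regions))
    nm <- if ("name" %in% colnames(mc)) mc$name
          else paste0("region", seq_along(regions))
    st <- as.character(strand(regions))
    st[st == "*"] <- "."
    out <- data.frame(as.character(seqnames(regions)), start(regions) - 1L,
                      end(regions), nm, score, st)
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
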