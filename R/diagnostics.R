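#' @importFrom stats median phyper predict
#' @importFrom GenomicRanges promoters
NULL

#' MA data with a robust abundance trend
#'
#' Extracts the (A, M) scatter of a DA result and fits a robust loess
#' trend of M on A.  An upward or downward shift of the trend flags a
#' global difference (biological or technical); curvature flags a trended,
#' abundance-dependent bias that linear scale factors cannot remove.
#'
#' @param da A \linkS4class{DAResult}.
#' @param span Loess span (default 0.5).
#' @return List of class \code{"MAData"}: \code{A}, \code{M},
#'   \code{significant} flag, \code{trend} (fitted values aligned with A),
#'   \code{medianM}, \code{trendRange}.
#' @export
maData <- function(da, span = 0.5) {
    stopifnot(is(da, "DAResult"))
    tb <- daTable(da)
    if (nrow(tb) == 0L)
        stop("no regions in DA result")
    A <- tb$A; M <- tb$logFC
    trend <- if (sd(A) > 0) {
        fit <- loess(M ~ A, span = span, degree = 1, family = "symmetric",
                     control = loess.control(surface = "interpolate"))
        stats::fitted(fit)
    } else rep(mean(M), length(M))
    out <- list(A = A, M = M,
                significant = tb$fdr < da@params$fdrThreshold,
                trend = trend, medianM = median(M),
                trendRange = range(trend))
    class(out) <- "MAData"
    out
}

#' @export
print.MAData <- function(x, ...) {
    cat(sprintf("MAData: %d regions, median M = %.3f, trend in [%.3f, %.3f]\n",
        length(x$M), x$medianM, x$trendRange[1], x$trendRange[2]))
    invisible(x)
}

#' MA plot of a DA result
#'
#' @param x An \code{"MAData"} (or \linkS4class{DAResult}, converted on the
#'   fly).
#' @param main Plot title.
#' @param ... Passed to \code{plot()}.
#' @return Invisibly, the MAData.
#' @importFrom graphics points abline
#' @export
plotMAData <- function(x, main = "MA plot", ...) {
    if (is(x, "DAResult"))
        x <- maData(x)
    plot(x$A, x$M, pch = 16, cex = 0.3,
         col = ifelse(x$significant, "red", "black"),
         xlab = "A (average log2-CPM)", ylab = "M (log2 fold change)",
         main = main, ...)
    o <- order(x$A)
    graphics::lines(x$A[o], x$trend[o], col = "blue", lwd = 2)
    abline(h = 0, lty = 2, col = "grey")
    invisible(x)
}

#' FDR threshold reaching a given rejection rate
#'
#' Different DA approaches need very different FDR cutoffs to reject the
#' same fraction of tested regions; this returns the q-value of the
#' ceiling(rate * m)-th smallest FDR, the smallest threshold rejecting at
#' least \code{rate} of the tested regions.
#'
#' @param da A \linkS4class{DAResult}.
#' @param rate Target rejection fraction (default 0.05).
#' @return The FDR threshold.
#' @export
fdrAtRejectionRate <- function(da, rate = 0.05) {
    q <- sort(daTable(da)$fdr)
    m <- length(q)
    if (m < 1 / rate)
        stop("too few regions for the requested rejection rate")
    q[ceiling(rate * m)]
}

#' Annotate regions as promoter or distal
#'
#' A region is a promoter region iff it overlaps (>= 1 bp) the
#' strand-oriented window [TSS - upstream, TSS + downstream) of any gene;
#' regions overlapping several promoter windows keep all gene links.  When
#' the regions carry an \code{fdr} metadata column, the per-gene best
#' (lowest) promoter FDR is also reported.
#'
#' @param regions Query \link[GenomicRanges]{GRanges} (e.g.
#'   \code{daRegions} of a result, with \code{fdr} in \code{mcols}).
#' @param tss \code{GRanges} of transcription start sites (width-1 anchors
#'   or gene bodies; the strand-aware start is used) with a \code{gene_id}
#'   metadata column.
#' @param upstream,downstream Window extent in bp (defaults 3000/3000; use
#'   2000/200 for the compact yeast genome).
#' @return List of class \code{"PromoterAnnotation"}: \code{class} (factor
#'   promoter/distal per region), \code{links} (data.frame region ->
#'   gene_id), \code{geneBestFdr} (named vector, when FDRs were supplied).
#' @export
annotatePromoters <- function(regions, tss, upstream = 3000L,
                              downstream = 3000L) {
    stopifnot(is(regions, "GRanges"), is(tss, "GRanges"))
    if (!"gene_id" %in% colnames(mcols(tss)))
        stop("tss must carry a 'gene_id' metadata column")
    anchors <- resize(tss, width = 1L, fix = "start")
    win <- suppressWarnings(promoters(anchors, upstream = upstream,
                                      downstream = downstream))
    win <- win[width(win) > 0L]
    hits <- findOverlaps(regions, win, minoverlap = 1L)
    cls <- factor(ifelse(seq_along(regions) %in% queryHits(hits),
                         "promoter", "distal"),
                  levels = c("promoter", "distal"))
    links <- data.frame(region = queryHits(hits),
                        gene_id = win$gene_id[subjectHits(hits)])
    geneBest <- NULL
    if ("fdr" %in% colnames(mcols(regions)) && nrow(links)) {
        fdr <- mcols(regions)$fdr[links$region]
        geneBest <- tapply(fdr, links$gene_id, min)
        geneBest <- setNames(as.numeric(geneBest), names(geneBest))
    }
    out <- list(class = cls, links = links, geneBestFdr = geneBest)
    class(out) <- "PromoterAnnotation"
    out
}

#' @export
print.PromoterAnnotation <- function(x, ...) {
    cat(sprintf("PromoterAnnotation: %d promoter / %d distal regions, %d gene links\n",
        sum(x$class == "promoter"), sum(x$class == "distal"), nrow(x$links)))
    invisible(x)
}

#' Compare DA calls across approaches
#'
#' Summarizes a set of DA results run on the same data: per approach the
#' number of significant regions up/down, the promoter/distal split (and
#' direction within promoters) when annotations are supplied, and the
#' gene-set overlap structure (pairwise intersections plus upset-style
#' exclusive combination counts) of genes with a significant DA promoter.
#'
#' @param daList Named list of \linkS4class{DAResult}s.
#' @param annotations Optional named list of \code{"PromoterAnnotation"}s
#'   aligned with \code{daList}.
#' @param fdrThreshold Significance cutoff (default 0.10).
#' @return List of class \code{"ComparisonSummary"}: \code{counts}
#'   (data.frame per approach), \code{geneSets}, \code{pairwise}
#'   (intersection-size matrix), \code{upset} (exclusive combination
#'   counts).
#' @export
compareApproaches <- function(daList, annotations = NULL,
                              fdrThreshold = 0.10) {
    stopifnot(is.list(daList), length(daList) >= 2L)
    nm <- names(daList)
    if (is.null(nm))
        nm <- paste0("approach", seq_along(daList))
    counts <- do.call(rbind, lapply(seq_along(daList), function(i) {
        tb <- daTable(daList[[i]])
        sig <- !is.na(tb$fdr) & tb$fdr < fdrThreshold
        row <- data.frame(approach = nm[i], tested = nrow(tb),
                          significant = sum(sig),
                          up = sum(sig & tb$logFC > 0),
                          down = sum(sig & tb$logFC < 0),
                          promoter = NA_integer_, distal = NA_integer_,
                          promoter_up = NA_integer_,
                          promoter_down = NA_integer_)
        if (!is.null(annotations)) {
            cls <- annotations[[i]]$class
            row$promoter <- sum(sig & cls == "promoter")
            row$distal <- sum(sig & cls == "distal")
            row$promoter_up <- sum(sig & cls == "promoter" & tb$logFC > 0)
            row$promoter_down <- sum(sig & cls == "promoter" & tb$logFC < 0)
        }
        row
    }))
    geneSets <- NULL; pairwise <- NULL; upset <- NULL
    if (!is.null(annotations)) {
        geneSets <- lapply(seq_along(daList), function(i) {
            tb <- daTable(daList[[i]])
            ln <- annotations[[i]]$links
            sig <- which(!is.na(tb$fdr) & tb$fdr < fdrThreshold)
            unique(ln$gene_id[ln$region %in% sig])
        })
        names(geneSets) <- nm
        k <- length(geneSets)
        pairwise <- matrix(0L, k, k, dimnames = list(nm, nm))
        for (i in seq_len(k)) for (j in seq_len(k))
            pairwise[i, j] <- length(intersect(geneSets[[i]], geneSets[[j]]))
        allGenes <- unique(unlist(geneSets))
        if (length(allGenes)) {
            member <- vapply(geneSets, function(s) allGenes %in% s,
                             logical(length(allGenes)))
            if (is.null(dim(member)))
                member <- matrix(member, nrow = length(allGenes))
            combo <- apply(member, 1L, function(r)
                paste(nm[r], collapse = "&"))
            upset <- sort(table(combo), decreasing = TRUE)
        }
    }
    out <- list(counts = counts, geneSets = geneSets,
                pairwise = pairwise, upset = upset)
    class(out) <- "ComparisonSummary"
    out
}

#' @export
print.ComparisonSummary <- function(x, ...) {
    print(x$counts)
    invisible(x)
}

#' Precision-recall curve for predicting DE status from promoter DA
#'
#' Sweeps genes by decreasing confidence score (1 - best promoter DA FDR),
#' grouping tied scores, and records precision and recall at each distinct
#' score; the area under the curve is the step-interpolated integral
#' (sum over recall increments of the precision attained there).
#'
#' @param geneBestFdr Named numeric vector of per-gene best promoter DA
#'   FDR values.
#' @param deStatus Named logical vector of true differential-expression
#'   status for the same genes (>= 1 positive and >= 1 negative).
#' @return List of class \code{"PRCurve"}: \code{recall},
#'   \code{precision}, \code{score} (per sweep point), \code{auc},
#'   \code{prevalence}.
#' @export
prCurve <- function(geneBestFdr, deStatus) {
    if (!is.null(names(geneBestFdr)) && !is.null(names(deStatus)))
        deStatus <- deStatus[names(geneBestFdr)]
    labels <- as.logical(deStatus)
    stopifnot(length(labels) == length(geneBestFdr), !anyNA(labels))
    if (!any(labels))
        stop("no positive genes; PR curve undefined")
    if (all(labels))
        stop("no negative genes; PR curve undefined")
    score <- 1 - geneBestFdr
    o <- order(score, decreasing = TRUE)
    score <- score[o]; labels <- labels[o]
    grp <- cumsum(!duplicated(score))
    tp <- cumsum(labels); fp <- cumsum(!labels)
    last <- which(!duplicated(grp, fromLast = TRUE))  # last index per tie group
    tp <- tp[last]; fp <- fp[last]
    P <- sum(labels)
    recall <- tp / P
    precision <- tp / (tp + fp)
    auc <- sum(diff(c(0, recall)) * precision)
    out <- list(recall = recall, precision = precision,
                score = score[last], auc = auc,
                prevalence = P / length(labels))
    class(out) <- "PRCurve"
    out
}

#' @export
print.PRCurve <- function(x, ...) {
    cat(sprintf("PRCurve: AUPR = %.3f (prevalence %.3f, %d sweep points)\n",
        x$auc, x$prevalence, length(x$recall)))
    invisible(x)
}

#' Hypergeometric gene-set enrichment
#'
#' Observed/expected ratio and upper-tail cumulative hypergeometric
#' p-value P(X >= observed) for the overlap of a hit list with an
#' annotated set inside a finite gene universe.
#'
#' @param hits Character vector of hit genes (subset of universe).
#' @param annotatedSet Character vector of set genes (subset of universe).
#' @param universe Character vector of all considered genes.
#' @return List: \code{observed}, \code{expected}, \code{oeRatio},
#'   \code{p}.
#' @examples
#' enrichment(letters[1:4], letters[1:5], letters[1:10])
#' @export
enrichment <- function(hits, annotatedSet, universe) {
    hits <- unique(hits); annotatedSet <- unique(annotatedSet)
    universe <- unique(universe)
    if (!all(hits %in% universe) || !all(annotatedSet %in% universe))
        stop("hits and annotated set must be subsets of the universe")
    observed <- length(intersect(hits, annotatedSet))
    expected <- length(hits) * length(annotatedSet) / length(universe)
    oe <- if (expected > 0) observed / expected else NA_real_
    p <- phyper(observed - 1L, length(annotatedSet),
                length(universe) - length(annotatedSet), length(hits),
                lower.tail = FALSE)
    list(observed = observed, expected = expected, oeRatio = oe, p = p)
}

#' Mean promoter accessibility change per expression class
#'
#' For time-course designs: the mean log2 accessibility change (M) of the
#' promoter regions linked to each expression class (e.g. stable /
#' upregulated / downregulated genes), per timepoint, with class sizes.
#'
#' @param daList Named list of \linkS4class{DAResult}s, one per timepoint
#'   (each vs the common control).
#' @param annotations Matching list of \code{"PromoterAnnotation"}s.
#' @param geneClasses Named character vector mapping gene id to class.
#' @return data.frame with timepoint, class, meanM, se, n; empty classes
#'   are omitted with a warning.
#' @export
classMeanLogfc <- function(daList, annotations, geneClasses) {
    nm <- names(daList)
    if (is.null(nm))
        nm <- paste0("t", seq_along(daList))
    rows <- list()
    for (i in seq_along(daList)) {
        tb <- daTable(daList[[i]])
        ln <- annotations[[i]]$links
        ln <- ln[ln$gene_id %in% names(geneClasses), , drop = FALSE]
        cls <- geneClasses[ln$gene_id]
        M <- tb$logFC[ln$region]
        for (cl in unique(geneClasses)) {
            sel <- cls == cl
            if (!any(sel)) {
                warning(sprintf("class '%s' empty at timepoint %s; omitted",
                                cl, nm[i]))
                next
            }
            rows[[length(rows) + 1L]] <- data.frame(
                timepoint = nm[i], class = cl, meanM = mean(M[sel]),
                se = sd(M[sel]) / sqrt(sum(sel)), n = sum(sel))
        }
    }
    do.call(rbind, rows)
}
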