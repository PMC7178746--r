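# Independent brute-force oracles used to cross-check the package
# implementations on small instances.  These deliberately use a different
# computational route than the package code.

# Trimmed weighted-mean scale factors, written sort-first (the package uses
# rank-based selection).
tmmOracle <- function(cnt, L, mTrim = 0.15, aTrim = 0.025) {
    uq <- apply(cnt, 2, function(y) quantile(y / sum(y) * 1e6, 0.75))
    ref <- which.min(abs(uq - mean(uq)))
    f <- vapply(seq_len(ncol(cnt)), function(i) {
        if (i == ref) return(1)
        y <- cnt[, i]; yr <- cnt[, ref]
        keep <- y > 0 & yr > 0
        y <- y[keep]; yr <- yr[keep]
        M <- log2((y / L[i]) / (yr / L[ref]))
        A <- 0.5 * log2((y / L[i]) * (yr / L[ref]))
        n <- length(M)
        selM <- order(M)[(floor(n * mTrim) + 1):(n - floor(n * mTrim))]
        selA <- order(A)[(floor(n * aTrim) + 1):(n - floor(n * aTrim))]
        sel <- intersect(selM, selA)
        w <- 1 / ((L[i] - y) / (L[i] * y) + (L[ref] - yr) / (L[ref] * yr))
        2^(sum(w[sel] * M[sel]) / sum(w[sel]))
    }, numeric(1))
    f / exp(mean(log(f)))
}

# All-pairs interval overlap counter on plain vectors.
bruteCount <- function(regStart, regEnd, frStart, frEnd, regChr, frChr) {
    vapply(seq_along(regStart), function(g) {
        sum(frChr == regChr[g] & frStart <= regEnd[g] & frEnd >= regStart[g])
    }, numeric(1))
}

# Naive-overlap retention decided by exhaustive pairwise scan.
naiveOverlapOracle <- function(pooled, replicates, minFrac = 0.5) {
    ps <- GenomicRanges::start(pooled); pe <- GenomicRanges::end(pooled)
    pc <- as.character(GenomeInfoDb::seqnames(pooled))
    keep <- vapply(seq_along(pooled), function(i) {
        all(vapply(replicates, function(r) {
            rs <- GenomicRanges::start(r); re <- GenomicRanges::end(r)
            rc <- as.character(GenomeInfoDb::seqnames(r))
            any(vapply(seq_along(r), function(j) {
                if (rc[j] != pc[i]) return(FALSE)
                ovl <- min(pe[i], re[j]) - max(ps[i], rs[j]) + 1
                if (ovl <= 0) return(FALSE)
                ovl >= minFrac * min(pe[i] - ps[i] + 1, re[j] - rs[j] + 1)
            }, logical(1)))
        }, logical(1)))
    }, logical(1))
    pooled[keep]
}

# Step-up BH by the direct formula.
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    out <- numeric(m)
    out[o] <- pmin(q, 1)
    out
}

# Upper-tail hypergeometric P(X >= k) by explicit combinatorial sums.
hyperEnumOracle <- function(observed, setSize, universeSize, hitSize) {
    ks <- observed:min(setSize, hitSize)
    sum(vapply(ks, function(k)
        choose(setSize, k) * choose(universeSize - setSize, hitSize - k),
        numeric(1))) / choose(universeSize, hitSize)
}

# Small fragment fixture: a FragmentSet from a coordinate table.
makeFrags <- function(df) {
    df$name <- if (is.null(df$name)) paste0("f", seq_len(nrow(df))) else df$name
    df$score <- 0
    if (is.null(df$m1_strand)) df$m1_strand <- "+"
    if (is.null(df$m2_strand)) df$m2_strand <- "-"
    FragmentSet(df)
}

gr <- function(chr, start0, end0, ...) {
    # convenience: build GRanges from 0-based half-open coordinates
    GenomicRanges::GRanges(chr, IRanges::IRanges(start0 + 1L, end0), ...)
}
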