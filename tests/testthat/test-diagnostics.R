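test_that("MA data summarizes null and shifted experiments correctly", {
    sim <- simulateCounts(countSimConfig(m = 3000), seed = 41)
    da <- runApproach(sim$counts, method = "libsize", filter = FALSE)
    md <- maData(da)
    expect_lt(abs(md$medianM), 0.05)
    ctr <- md$A >= quantile(md$A, 0.05) & md$A <= quantile(md$A, 0.95)
    expect_lt(max(abs(md$trend[ctr])), 0.1)
    # a global 2x efficiency gain appears as a constant +1 trend
    sim2 <- simulateCounts(countSimConfig(m = 3000, globalBias = 2), seed = 42)
    da2 <- runApproach(sim2$counts, method = "libsize", filter = FALSE)
    md2 <- maData(da2)
    expect_equal(median(md2$trend), 1, tolerance = 0.1)
    empty <- DAResult(GenomicRanges::GRanges(), logFC = numeric(),
                      A = numeric(), p = numeric())
    expect_error(maData(empty), "no regions")
})

test_that("FDR-at-rejection-rate picks the right order statistic", {
    mk <- function(q) {
        n <- length(q)
        new("DAResult", regions = gr("chr1", seq_len(n) * 100,
                                     seq_len(n) * 100 + 50),
            table = S4Vectors::DataFrame(logFC = numeric(n), A = numeric(n),
                                         p = q, fdr = q,
                                         direction = numeric(n)),
            engine = "moderated", params = list(fdrThreshold = 0.1))
    }
    expect_equal(fdrAtRejectionRate(mk(seq(0.01, 0.20, by = 0.01)),
                                    rate = 0.25), 0.05)
    expect_equal(fdrAtRejectionRate(mk(rep(0.5, 20)), rate = 0.05), 0.5)
    expect_equal(fdrAtRejectionRate(mk(seq(0.01, 0.20, by = 0.01)),
                                    rate = 0.05), 0.01)
    expect_error(fdrAtRejectionRate(mk(rep(0.5, 10)), rate = 0.05),
                 "too few")
})

test_that("promoter annotation is strand-aware with >= 1 bp overlap", {
    p1 <- 9999; p2 <- 49999   # 0-based TSS positions
    tss <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(p1, p2) + 1L, width = 1),
        strand = c("+", "-"), gene_id = c("g1", "g2"))
    # symmetric +-3 kb: region [TSS+2999, TSS+3100) overlaps by 1 bp
    reg <- gr("chr1", c(p1 + 2999, p1 + 3100), c(p1 + 3100, p1 + 3200))
    ann <- annotatePromoters(reg, tss, 3000, 3000)
    expect_equal(as.character(ann$class), c("promoter", "distal"))
    expect_equal(sum(ann$class == "promoter") + sum(ann$class == "distal"),
                 length(reg))
    # asymmetric yeast window (-2000/+200) flips orientation on the minus
    # strand: upstream means larger coordinates
    upTss <- gr("chr1", p2 + 300, p2 + 1500)
    annY <- annotatePromoters(upTss, tss, 2000, 200)
    expect_equal(as.character(annY$class), "promoter")
    dnTss <- gr("chr1", p2 - 1500, p2 - 300)  # beyond the +200 downstream
    annY2 <- annotatePromoters(dnTss, tss, 2000, 200)
    expect_equal(as.character(annY2$class), "distal")
    # strand flip with symmetric windows leaves interior classes unchanged
    regIn <- gr("chr1", c(p1 + 500, p1 + 9000), c(p1 + 700, p1 + 9300))
    tssFlip <- tss
    GenomicRanges::strand(tssFlip) <- c("-", "+")
    expect_equal(annotatePromoters(regIn, tss, 3000, 3000)$class,
                 annotatePromoters(regIn, tssFlip, 3000, 3000)$class)
})

test_that("per-gene best promoter FDR takes the minimum over regions", {
    tss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, width = 1),
                                  strand = "+", gene_id = "g1")
    reg <- gr("chr1", c(9000, 10500), c(9500, 11000))
    S4Vectors::mcols(reg)$fdr <- c(0.2, 0.04)
    ann <- annotatePromoters(reg, tss, 3000, 3000)
    expect_equal(unname(ann$geneBestFdr["g1"]), 0.04)
})

test_that("PR curve reproduces hand-computed sweeps", {
    # worked 4-gene case: scores .9/.8/.7/.6, labels 1/0/1/0
    pr <- prCurve(setNames(c(0.1, 0.2, 0.3, 0.4), paste0("g", 1:4)),
                  setNames(c(TRUE, FALSE, TRUE, FALSE), paste0("g", 1:4)))
    expect_equal(pr$auc, 0.5 * 1 + 0.5 * 2 / 3, tolerance = 1e-12)
    expect_true(all(diff(pr$recall) >= 0))
    # perfect separation
    prP <- prCurve(c(a = 0.01, b = 0.02, c = 0.8, d = 0.9),
                   c(a = TRUE, b = TRUE, c = FALSE, d = FALSE))
    expect_equal(prP$auc, 1)
    # constant score collapses to a single point at the prevalence
    prC <- prCurve(rep(0.5, 10), c(rep(TRUE, 3), rep(FALSE, 7)))
    expect_length(prC$recall, 1L)
    expect_equal(prC$precision, 0.3)
    expect_equal(prC$auc, 0.3)
    expect_error(prCurve(c(0.1, 0.2), c(FALSE, FALSE)), "no positive")
})

test_that("random scores give AUPR near the prevalence", {
    set.seed(55)
    labels <- c(rep(TRUE, 30), rep(FALSE, 70))
    aucs <- vapply(1:200, function(i)
        prCurve(runif(100), sample(labels))$auc, numeric(1))
    expect_lt(abs(mean(aucs) - 0.3), 0.05)
})

test_that("hypergeometric enrichment matches combinatorial enumeration", {
    e <- enrichment(letters[1:4], letters[1:5], letters[1:10])
    expect_equal(e$oeRatio, 2)
    expect_equal(e$p, 5 / 210, tolerance = 1e-12)
    # exhaustive check on small universes
    set.seed(6)
    for (i in 1:10) {
        uni <- paste0("x", 1:sample(8:20, 1))
        setg <- sample(uni, sample.int(length(uni), 1))
        hits <- sample(uni, sample.int(length(uni), 1))
        e2 <- enrichment(hits, setg, uni)
        expect_equal(e2$p,
                     hyperEnumOracle(e2$observed, length(setg),
                                     length(uni), length(hits)),
                     tolerance = 1e-12)
    }
    eu <- enrichment(letters[1:10], letters[1:5], letters[1:10])
    expect_equal(eu$oeRatio, 1)
    expect_equal(eu$p, 1)
    e0 <- enrichment(letters[6:10], letters[1:5], letters[1:10])
    expect_equal(e0$oeRatio, 0)
})

test_that("approach comparison tabulates directions and gene overlaps", {
    regions <- gr("chr1", (0:9) * 10000, (0:9) * 10000 + 500)
    mkDa <- function(fdr, lfc) DAResult(regions, logFC = lfc,
                                        A = rep(5, 10), p = fdr, fdr = fdr)
    daA <- mkDa(c(rep(0.01, 4), rep(0.5, 6)), c(1, 1, -1, 1, rep(0.1, 6)))
    tss <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges((0:9) * 10000 + 250, width = 1), strand = "+",
        gene_id = paste0("g", 1:10))
    ann <- annotatePromoters(regions, tss, 3000, 3000)
    cmp <- compareApproaches(list(x = daA, y = daA),
                             annotations = list(ann, ann),
                             fdrThreshold = 0.1)
    expect_equal(cmp$counts$up, c(3L, 3L))
    expect_equal(cmp$counts$down, c(1L, 1L))
    expect_equal(cmp$pairwise["x", "y"], 4L)
    expect_equal(unname(cmp$upset["x&y"]), 4L)
    # disjoint gene sets -> zero off-diagonal intersections
    daB <- mkDa(c(rep(0.5, 4), rep(0.01, 6)), rep(1, 10))
    cmp2 <- compareApproaches(list(x = daA, y = daB),
                              annotations = list(ann, ann),
                              fdrThreshold = 0.1)
    expect_equal(cmp2$pairwise["x", "y"], 0L)
    # three hand-built sets with known exclusive combination counts
    daC <- mkDa(c(0.01, 0.01, 0.5, 0.5, 0.01, rep(0.5, 5)), rep(1, 10))
    cmp3 <- compareApproaches(list(a = daA, b = daB, c = daC),
                              annotations = list(ann, ann, ann),
                              fdrThreshold = 0.1)
    expect_equal(unname(cmp3$upset["a&c"]), 2L)   # g1, g2
    expect_equal(unname(cmp3$upset["b&c"]), 1L)   # g5
    expect_equal(unname(cmp3$upset["a"]), 2L)     # g3, g4
    expect_equal(unname(cmp3$upset["b"]), 5L)     # g6..g10
})

test_that("class mean logFC recovers constructed promoter responses", {
    regions <- gr("chr1", (0:29) * 10000, (0:29) * 10000 + 500)
    tss <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges((0:29) * 10000 + 250, width = 1), strand = "+",
        gene_id = paste0("g", 1:30))
    cls <- setNames(rep(c("up", "stable", "down"), each = 10),
                    paste0("g", 1:30))
    set.seed(64)
    M <- rep(c(1, 0, -1), each = 10) + rnorm(30, sd = 0.05)
    da <- DAResult(regions, logFC = M, A = rep(5, 30), p = rep(0.5, 30))
    ann <- annotatePromoters(regions, tss, 3000, 3000)
    out <- classMeanLogfc(list(t15 = da), list(ann), cls)
    expect_equal(out$meanM[out$class == "up"], 1, tolerance = 0.1)
    expect_equal(out$meanM[out$class == "stable"], 0, tolerance = 0.1)
    expect_equal(out$meanM[out$class == "down"], -1, tolerance = 0.1)
    expect_equal(out$n, rep(10L, 3))
    # single gene per class is that gene's M; empty classes warn
    out1 <- classMeanLogfc(list(t = da), list(ann),
                           c(g1 = "solo"))
    expect_equal(out1$meanM, M[1])
})
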