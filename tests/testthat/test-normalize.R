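test_that("library-size factors scale with depth under unit geometric mean", {
    cnt <- matrix(5L, 10, 2)
    expect_equal(normFactors(normLibsize(cnt, libSizes = c(1e6, 1e6))),
                 c(1, 1))
    f <- normFactors(normLibsize(cnt, libSizes = c(1e6, 2e6)))
    expect_equal(f, c(1 / sqrt(2), sqrt(2)))
    # permutation equivariance
    f2 <- normFactors(normLibsize(cnt, libSizes = c(2e6, 1e6)))
    expect_equal(f2, rev(f))
})

test_that("reads-in-peaks factors respond to peak counts, not depth", {
    set.seed(8)
    a <- matrix(rpois(200, 20), 100, 2)
    expect_equal(normFactors(normReadsInPeaks(a[, c(1, 1)])), c(1, 1))
    b <- cbind(a[, 1], 3L * a[, 1])
    f <- normFactors(normReadsInPeaks(b))
    expect_equal(f[2] / f[1], 3)
    # adding out-of-peak depth changes libsize factors but not these
    ace1 <- AtacCountExperiment(b, gr("chr1", (0:99) * 1000, (0:99) * 1000 + 500),
                                libSizes = c(1e5, 3e5), condition = c("a", "b"))
    ace2 <- AtacCountExperiment(b, gr("chr1", (0:99) * 1000, (0:99) * 1000 + 500),
                                libSizes = c(9e5, 3e5), condition = c("a", "b"))
    expect_equal(normFactors(normReadsInPeaks(ace1)),
                 normFactors(normReadsInPeaks(ace2)))
    expect_false(isTRUE(all.equal(normFactors(normLibsize(ace1)),
                                  normFactors(normLibsize(ace2)))))
    expect_error(normReadsInPeaks(cbind(a[, 1], 0L * a[, 1])), "zero")
})

test_that("TMM absorbs pure depth differences and identical columns", {
    set.seed(21)
    a <- matrix(rpois(500, 50) + 1L, 500, 1)
    pure <- cbind(a, 2L * a)
    expect_equal(normFactors(normTMM(pure)), c(1, 1), tolerance = 1e-12)
    expect_equal(normFactors(normTMM(cbind(a, a))), c(1, 1),
                 tolerance = 1e-12)
})

test_that("TMM matches the brute-force trimmed-weighted-mean oracle", {
    set.seed(90)
    for (i in 1:3) {
        mu <- exp(rnorm(800, 4, 1))
        cnt <- cbind(rpois(800, mu), rpois(800, mu * 1.3), rpois(800, mu))
        gain <- sample.int(800, 80)
        cnt[gain, 2] <- cnt[gain, 2] * 4L
        L <- colSums(cnt)
        got <- normFactors(normTMM(cnt, libSizes = L))
        want <- tmmOracle(cnt, L)
        expect_equal(got, want, tolerance = 1e-6)
    }
})

test_that("TMM corrects composition bias so null bins recenter at M ~ 0", {
    set.seed(4)
    mu <- exp(rnorm(1100, 5, 0.6))
    cnt <- cbind(rpois(1100, mu), rpois(1100, mu))
    gain <- 1:100
    cnt[gain, 2] <- cnt[gain, 2] * 4L
    L <- colSums(cnt)
    res <- normTMM(cnt, libSizes = L)
    eff <- effectiveLibSizes(res)
    nullBins <- setdiff(seq_len(1100), gain)
    M <- log2((cnt[nullBins, 2] + 0.5) / (eff[2] + 1)) -
         log2((cnt[nullBins, 1] + 0.5) / (eff[1] + 1))
    expect_lt(abs(median(M)), 0.05)
})

test_that("TMM factors approach 1 on null data", {
    set.seed(61)
    mu <- exp(rnorm(10000, 4.5, 1))
    cnt <- cbind(rpois(10000, mu), rpois(10000, mu), rpois(10000, mu))
    expect_equal(normFactors(normTMM(cnt)), rep(1, 3), tolerance = 0.02)
})

test_that("loess offsets vanish for identical samples and capture shifts", {
    set.seed(12)
    y <- rpois(400, exp(rnorm(400, 4, 1)))
    same <- cbind(y, y)
    o <- normOffsets(normLoess(same))
    expect_lt(max(abs(o)), 1e-8)
    # constant +1 log2 shift in sample B -> offsets about +-0.5 after centring
    shifted <- cbind(y, as.integer(round(y * 2)))
    o2 <- normOffsets(normLoess(shifted))
    expect_equal(unname(apply(o2, 2, median)), c(-0.5, 0.5), tolerance = 0.1)
    # degenerate abundance -> zero offsets
    o3 <- normOffsets(normLoess(matrix(5L, 60, 2)))
    expect_true(all(o3 == 0))
})

test_that("loess normalization removes an injected linear M(A) trend", {
    sim <- simulateCounts(countSimConfig(m = 4000, trendAmplitude = 0.5),
                          seed = 16)
    ace <- sim$counts
    E <- normalizedLog2cpm(ace, normLoess(ace))
    A <- rowMeans(E)
    M <- rowMeans(E[, 4:6]) - rowMeans(E[, 1:3])
    fit <- loess(M ~ A, span = 0.5, degree = 1, family = "symmetric")
    ctr <- A >= quantile(A, 0.05) & A <= quantile(A, 0.95)
    expect_lt(max(abs(fitted(fit)[ctr])), 0.1)
})

test_that("quantile normalization equalizes column distributions exactly", {
    out <- quantileNormalize(cbind(c(1, 3), c(2, 4)))
    expect_equal(out, cbind(c(1.5, 3.5), c(1.5, 3.5)))
    set.seed(3)
    m <- matrix(rnorm(600), 200, 3)
    expect_equal(quantileNormalize(cbind(m[, 1], m[, 1])),
                 cbind(m[, 1], m[, 1]))
    qn <- quantileNormalize(m)
    expect_identical(sort(qn[, 1]), sort(qn[, 2]))
    expect_identical(sort(qn[, 2]), sort(qn[, 3]))
})

test_that("quantile normalization agrees with the limma reference", {
    skip_if_not_installed("limma")
    set.seed(44)
    m <- matrix(rnorm(900), 300, 3)
    m[sample(900, 30)] <- m[1]  # inject ties
    expect_equal(quantileNormalize(m),
                 unname(limma::normalizeQuantiles(m, ties = TRUE)),
                 tolerance = 1e-12)
})

test_that("all factor methods return unit geometric mean factors", {
    set.seed(50)
    cnt <- matrix(rpois(1200, 40) + 1L, 300, 4)
    ace <- AtacCountExperiment(cnt, gr("chr1", (0:299) * 1000,
                                      (0:299) * 1000 + 500),
                               libSizes = c(2e5, 3e5, 2.5e5, 4e5),
                               condition = c("a", "a", "b", "b"))
    for (meth in c("libsize", "reads_in_peaks", "tmm")) {
        f <- normFactors(normalizeCounts(ace, meth))
        expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
        expect_true(all(f > 0))
    }
})

test_that("the normalized matrix matches each method's contract", {
    set.seed(77)
    cnt <- matrix(rpois(800, 60), 200, 4)
    ace <- AtacCountExperiment(cnt, gr("chr1", (0:199) * 1000,
                                      (0:199) * 1000 + 500),
                               libSizes = rep(1e5, 4),
                               condition = c("a", "a", "b", "b"))
    # factor methods: plain log2cpm at effective sizes
    nl <- normalizeCounts(ace, "libsize")
    expect_equal(unname(normalizedLog2cpm(ace, nl)),
                 log2cpm(cnt, effectiveLibSizes(nl)))
    # quantile: the engine consumes the transformed matrix itself
    nq <- normalizeCounts(ace, "quantile")
    Eq <- normalizedLog2cpm(ace, nq)
    expect_identical(Eq, nq@transformed)
    # sorted columns agree up to within-column tie averaging on counts
    expect_lt(mean(abs(sort(Eq[, 1]) - sort(Eq[, 4]))), 0.02)
    # loess: per-region row means preserved up to the common constant
    nlo <- normalizeCounts(ace, "loess")
    Elo <- normalizedLog2cpm(ace, nlo)
    V <- log2(cnt + 0.5) + log2(1e6) - mean(log2(1e5 + 1))
    expect_equal(unname(rowMeans(Elo)), unname(rowMeans(V)))
})
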