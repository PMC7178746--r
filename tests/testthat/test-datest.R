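test_that("BH adjustment matches the step-up formula and is rank-based", {
    expect_equal(bhFdr(c(0.005, 0.1)), c(0.01, 0.1))
    expect_equal(bhFdr(rep(0.03, 5)), rep(0.03, 5))
    set.seed(2)
    p <- runif(200)
    expect_equal(bhFdr(p), bhOracle(p))
    o <- sample(200)
    expect_equal(bhFdr(p)[o], bhFdr(p[o]))
})

test_that("design construction requires two conditions and replicates", {
    d <- makeDesign(c("ctl", "ctl", "mut", "mut"))
    expect_equal(dim(d$design), c(4L, 2L))
    expect_equal(sum(d$contrast), 1)
    expect_error(makeDesign(c("a", "b", "c")), "two condition")
    expect_error(makeDesign(c("a", "b")), "residual")
})

test_that("mean-variance weights track the abundance-variance trend", {
    des <- makeDesign(rep(c("A", "B"), each = 3))
    L <- rep(1e6, 6)
    set.seed(10)
    # homoskedastic data: weights nearly constant
    E <- matrix(rnorm(3000 * 6, mean = 8, sd = 0.4), 3000, 6)
    w <- voomWeights(E, des$design, L)
    expect_lt(sd(w) / mean(w), 0.10)
    # identical rows get identical weights
    E2 <- E; E2[2, ] <- E2[1, ]
    w2 <- voomWeights(E2, des$design, L)
    expect_equal(w2[1, ], w2[2, ])
    # NB-like counts: variance falls with abundance so weights rise with it
    mu <- exp(rnorm(2000, 4, 1.5))
    cnt <- matrix(rnbinom(2000 * 6, mu = rep(mu, 6), size = 10), 2000, 6)
    lc <- log2cpm(cnt, rep(sum(mu), 6))
    w3 <- voomWeights(lc, des$design, rep(sum(mu), 6))
    expect_gt(cor(rowMeans(lc), rowMeans(w3), method = "spearman"), 0)
})

test_that("moderated engine matches limma's eBayes route exactly", {
    skip_if_not_installed("limma")
    set.seed(9)
    m <- 1500
    sdg <- sqrt(1 / rgamma(m, shape = 4, rate = 4))
    E <- matrix(rnorm(m * 6, sd = rep(sdg, 6)), m, 6)
    des <- makeDesign(rep(c("A", "B"), each = 3))
    da <- fitModerated(E, des$design, des$contrast)
    ref <- limma::eBayes(limma::lmFit(E, des$design))
    expect_equal(da@params$d0, ref$df.prior, tolerance = 1e-6)
    expect_equal(da@params$s02, ref$s2.prior, tolerance = 1e-6)
    expect_equal(daTable(da)$p, unname(ref$p.value[, 2]), tolerance = 1e-10)
    expect_equal(daTable(da)$logFC, unname(ref$coefficients[, 2]),
                 tolerance = 1e-10)
})

test_that("moderated t collapses to the ordinary and pooled limits", {
    set.seed(18)
    E <- matrix(rnorm(400 * 6, sd = rep(sqrt(1 / rgamma(400, 4, 4)), 6)),
                400, 6)
    des <- makeDesign(rep(c("A", "B"), each = 3))
    X <- des$design
    XtXi <- solve(crossprod(X))
    B <- E %*% t(XtXi %*% t(X))
    res <- E - B %*% t(X)
    s2 <- rowSums(res^2) / 4
    v <- XtXi[2, 2]
    # d0 = 0: ordinary t
    tOrd <- B[, 2] / sqrt(s2 * v)
    # d0 = Inf: z-like with the common s0
    da <- fitModerated(E, X, des$contrast)
    d0 <- da@params$d0; s02 <- da@params$s02
    tMod <- da@params$t
    tInf <- B[, 2] / sqrt(s02 * v)
    # the moderated t interpolates between the two limits
    expect_true(all(
        (abs(tMod) - pmin(abs(tOrd), abs(tInf)) > -1e-8) &
        (abs(tMod) - pmax(abs(tOrd), abs(tInf)) < 1e-8)))
    # and reproduces the posterior-variance formula directly
    s2post <- (d0 * s02 + 4 * s2) / (d0 + 4)
    expect_equal(tMod, B[, 2] / sqrt(s2post * v), tolerance = 1e-10)
})

test_that("moderated engine is calibrated under the null", {
    sim <- simulateCounts(countSimConfig(m = 5000, nPerCondition = 2),
                          seed = 23)
    da <- runApproach(sim$counts, method = "libsize", fdrThreshold = 0.05)
    p <- daTable(da)$p
    # p-values are discrete at low counts, so check uniformity through
    # rejection fractions at several cutoffs instead of a KS statistic
    m <- length(p)
    for (alpha in c(0.01, 0.05)) {
        mcErr <- sqrt(alpha * (1 - alpha) / m)
        expect_lt(abs(mean(p < alpha) - alpha), 4 * mcErr + 0.005)
    }
    expect_lte(sum(daTable(da)$fdr < 0.05), 5)
    frac05 <- mean(p < 0.05)
    expect_gt(frac05, 0.03)
    expect_lt(frac05, 0.07)
})

test_that("NB exact test matches full enumeration on small totals", {
    phi <- 0.15
    oracle <- function(s1, s2, n1, n2, phi) {
        tot <- s1 + s2; x <- 0:tot; mu <- tot / (n1 + n2)
        pr <- if (phi > 0)
            dnbinom(x, size = n1 / phi, mu = n1 * mu) *
            dnbinom(tot - x, size = n2 / phi, mu = n2 * mu)
        else dpois(x, n1 * mu) * dpois(tot - x, n2 * mu)
        pr <- pr / sum(pr)
        min(1, 2 * min(sum(pr[x <= s1]), sum(pr[x >= s1])))
    }
    for (s1 in c(0, 3, 11, 15)) for (s2 in c(0, 2, 9, 15)) {
        expect_equal(danorm:::.nbExactP(s1, s2, 3, 3, phi),
                     oracle(s1, s2, 3, 3, phi), tolerance = 1e-12)
        expect_equal(danorm:::.nbExactP(s1, s2, 2, 4, 0),
                     oracle(s1, s2, 2, 4, 0), tolerance = 1e-12)
    }
    expect_equal(danorm:::.nbExactP(0, 0, 3, 3, 0.1), 1)
})

test_that("the Poisson branch reduces to the conditional binomial split", {
    # with phi = 0 and equal group sizes the conditional law is
    # Binomial(total, 1/2)
    for (s1 in c(2, 7, 13)) {
        tot <- 20
        pr <- dbinom(0:tot, tot, 0.5)
        want <- min(1, 2 * min(sum(pr[0:tot <= s1]), sum(pr[0:tot >= s1])))
        expect_equal(danorm:::.nbExactP(s1, tot - s1, 3, 3, 0), want,
                     tolerance = 1e-12)
    }
})

test_that("detection power is monotone in effect size", {
    cfgLo <- countSimConfig(m = 3000, fracDA = 0.1, lfcMean = 1, lfcSd = 0.01)
    cfgHi <- countSimConfig(m = 3000, fracDA = 0.1, lfcMean = 2, lfcSd = 0.01)
    simLo <- simulateCounts(cfgLo, seed = 31)
    simHi <- simulateCounts(cfgHi, seed = 31)
    tpAt <- function(sim) {
        da <- runApproach(sim$counts, method = "libsize", filter = FALSE,
                          fdrThreshold = 0.05)
        sum(daTable(da)$fdr < 0.05 & sim$truth$isDA)
    }
    expect_gte(tpAt(simHi), tpAt(simLo))
})

test_that("approach orchestration validates combinations and is deterministic", {
    sim <- simulateCounts(countSimConfig(m = 800, fracDA = 0.1), seed = 12)
    expect_error(runApproach(sim$counts, method = "quantile",
                             engine = "nb_exact"), "count-scale")
    da1 <- runApproach(sim$counts, method = "tmm")
    da2 <- runApproach(sim$counts, method = "tmm")
    expect_identical(daTable(da1), daTable(da2))
    expect_equal(da1@params$approach$method, "tmm")
    # the nb_exact engine runs on factor normalizations
    dan <- runApproach(sim$counts, method = "libsize", engine = "nb_exact")
    expect_s4_class(dan, "DAResult")
    expect_true(all(daTable(dan)$p >= 0 & daTable(dan)$p <= 1))
})

test_that("DAResult enforces its probability invariants", {
    regions <- gr("chr1", c(0, 100), c(50, 150))
    da <- DAResult(regions, logFC = c(1, -1), A = c(5, 6),
                   p = c(0.01, 0.5))
    tb <- daTable(da)
    expect_true(all(tb$fdr >= tb$p))
    expect_error(DAResult(regions, logFC = c(1, -1), A = c(5, 6),
                          p = c(-0.1, 0.5)))
})
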