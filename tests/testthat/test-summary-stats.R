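test_that("homogeneous K matches hand-computed and brute-force values", {
    pp <- PointPattern(c(2, 2, 8), c(2, 3, 8), Window(10, 10))
    est <- estimateK(pp, r = 1.5, correction = "none")
    expect_equal(est@K, 100 / (3 * 2) * 2) # one close pair, both orders

    # translation weights on a 2-point pattern, frozen from the brute-force
    # pair-loop oracle: area/(n(n-1)) * 2 * area/((W-1)(H-0)) = 111.11
    pp2 <- PointPattern(c(4, 5), c(5, 5), Window(10, 10))
    expect_equal(estimateK(pp2, 1, "translation")@K,
                 bruteForceK(pp2, 1, "translation"))
    expect_equal(estimateK(pp2, 1, "translation")@K, 10000 / 90,
                 tolerance = 1e-12)

    # oracle equality on a moderate random pattern, both corrections
    set.seed(31)
    pp3 <- PointPattern(runif(40, 0, 100), runif(40, 0, 60),
                        Window(100, 60))
    rs <- c(5, 10, 20, 30)
    for (corr in c("none", "translation"))
        expect_equal(estimateK(pp3, rs, corr)@K, bruteForceK(pp3, rs, corr),
                     tolerance = 1e-10)
})

test_that("K is non-decreasing in r and errors on degenerate input", {
    set.seed(8)
    for (i in 1:5) {
        pp <- simulateCSR(5e-3, Window(100, 80), seed = i)
        for (corr in c("none", "translation")) {
            K <- estimateK(pp, seq(2, 60, by = 2), corr)@K
            expect_true(all(diff(K) >= 0))
        }
    }
    one <- PointPattern(1, 1, Window(10, 10))
    expect_error(estimateK(one, 1), "degenerate")
    pp <- PointPattern(c(1, 2), c(1, 2), Window(10, 10))
    expect_error(estimateK(pp, 100), "diagonal")
})

test_that("duplicate coordinates contribute pairs at r = 0 without dividing by zero", {
    pp <- PointPattern(c(3, 3, 7), c(4, 4, 7), Window(10, 10))
    est <- estimateK(pp, r = c(0, 1), correction = "none")
    expect_true(all(is.finite(est@K)))
    expect_equal(est@K[1], 100 / 6 * 2) # the duplicate pair counts at r = 0
})

test_that("inhomogeneous K reduces to homogeneous K on a constant surface", {
    pp <- simulateCSR(2e-3, Window(400, 300), seed = 12)
    n <- npoints(pp)
    for (corr in c("none", "translation")) {
        kh <- estimateK(pp, c(10, 25, 50), corr)@K
        ki <- estimateKinhom(pp, lambda = n / (400 * 300),
                             r = c(10, 25, 50), correction = corr)@K
        expect_equal(ki, (n - 1) / n * kh, tolerance = 1e-12)
    }
})

test_that("inhomogeneous K weights pairs by 1/(lambda_i lambda_j)", {
    pp <- PointPattern(c(4, 5), c(5, 5), Window(10, 10))
    est <- estimateKinhom(pp, lambda = c(0.1, 0.2), r = 2,
                          correction = "none")
    expect_equal(est@K, 2 * (1 / (0.1 * 0.2)) / 100)
    expect_error(estimateKinhom(pp, lambda = c(0.1, 0), r = 2), "positive")
    expect_error(estimateKinhom(pp, lambda = c(0.1, 0.2, 0.3), r = 2),
                 "one value per point")
})

test_that("inhomogeneous K with the true intensity is unbiased for a trended Poisson process", {
    win <- Window(500, 250)
    surf <- trendSurface(win, nBumps = 3, minScale = 80, maxScale = 120,
                         targetMass = 400, seed = 99)
    rs <- c(20, 40, 60)
    nrep <- 60
    vals <- matrix(NA_real_, nrep, length(rs))
    for (i in seq_len(nrep)) {
        pp <- simulateIPP(surf, seed = 1000 + i)
        lam <- evalSurface(surf, pp@x, pp@y)
        vals[i, ] <- estimateKinhom(pp, lambda = lam, r = rs)@K
    }
    m <- colMeans(vals)
    se <- apply(vals, 2, sd) / sqrt(nrep)
    expect_true(all(abs(m - pi * rs^2) < 3 * se))
})

test_that("aggregation index exceeds 1 below the cluster scale of a Thomas process", {
    hits <- vapply(1:40, function(i) {
        pp <- simulateHPCP(4e-4, 10, 10, Window(500, 500), seed = 500 + i)
        agg <- aggregationIndex(estimateK(pp, r = 10))
        agg > 1
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("group profiles average the aggregation statistic with SE across species", {
    mkest <- function(vals, r = c(10, 20)) {
        new("KEstimate", r = r, K = vals * pi * r^2, correction = "none",
            kind = "homogeneous")
    }
    ests <- list(a = mkest(c(2, 2)), b = mkest(c(4, 4)), c = mkest(c(1, 1)))
    groups <- c(a = "g1", b = "g1", c = "g2")
    prof <- suppressWarnings(groupAggregationProfile(ests, groups))
    g1 <- prof[prof$group == "g1", ]
    expect_equal(g1$mean, c(3, 3))
    expect_equal(g1$se, c(1, 1)) # sd = sqrt(2), n = 2
    g2 <- prof[prof$group == "g2", ]
    expect_equal(g2$mean, c(1, 1))
    expect_warning(groupAggregationProfile(ests["c"], groups), "single")
    expect_equal(suppressWarnings(
        groupAggregationProfile(ests["c"], groups))$se, c(0, 0))
    expect_error(groupAggregationProfile(ests, c(a = "g1")), "missing")
    # Poisson-like species: all means 1, SE 0
    flat <- list(a = mkest(c(1, 1)), b = mkest(c(1, 1)))
    pf <- groupAggregationProfile(flat, c(a = "g", b = "g"))
    expect_equal(pf$mean, c(1, 1))
    expect_equal(pf$se, c(0, 0))
})
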