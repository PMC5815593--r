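test_that("contingency tables count species by class and group", {
    empty <- buildContingency(data.frame(species = character(0),
                                         group = character(0),
                                         best_model = character(0)))
    expect_equal(dim(empty), c(3L, 5L))
    expect_true(all(empty == 0))

    rec <- data.frame(
        species = paste0("s", 1:6),
        group = c("anemochorous", "anemochorous", "anemochorous",
                  rep("zoo-small", 3)),
        best_model = c("HPCP", "HPCP", "IPP", rep("IPCP", 3)))
    tab <- buildContingency(rec)
    expect_equal(tab["HPCP", "anemochorous"], 2L)
    expect_equal(tab["IPP", "anemochorous"], 1L)
    expect_equal(tab["IPCP", "zoo-small"], 3L)
    expect_equal(sum(tab), 6L)
    expect_error(buildContingency(rbind(rec, rec[1, ])), "once")
    bad <- rec; bad$group[1] <- "hydrochorous"
    expect_error(buildContingency(bad), "unknown group")

    # the packaged census table: row totals and the published marginals
    pub <- bciSyndromeModelCounts()
    expect_equal(sum(pub[, "anemochorous"]), 24L) # 5 + 10 + 9
    expect_equal(sum(pub), 229L)
    expect_equal(unname(rowSums(pub)), c(40L, 45L, 144L))
})

test_that("Monte-Carlo Fisher p-values agree with exhaustive enumeration", {
    tables <- list(
        matrix(c(3, 0, 0, 2), 2),
        matrix(c(3, 0, 0, 0, 2, 1), nrow = 2, byrow = TRUE),
        matrix(c(5, 1, 2, 4), 2))
    for (tab in tables) {
        pEnum <- fisherExactEnum(tab)
        expect_equal(pEnum, fisher.test(tab)$p.value, tolerance = 1e-9)
        nS <- 4000
        pMC <- fisherExactMC(tab, nSims = nS, seed = 101)$p_value
        expect_lt(abs(pMC - pEnum),
                  3 * sqrt(pEnum * (1 - pEnum) / nS) + 1 / nS)
    }
    # exact-independence table: p ~ 1
    ind <- outer(c(10, 10), c(10, 10)) / 20
    expect_gt(fisherExactMC(ind, 2000, seed = 1)$p_value, 0.9)
    # p respects the (1 + count)/(B + 1) floor
    skew <- matrix(c(20, 0, 0, 20), 2)
    p <- fisherExactMC(skew, 2000, seed = 2)$p_value
    expect_gte(p, 1 / 2001)
    expect_error(fisherExactMC(matrix(1:4, 2), nSims = 10), "nSims")
    expect_warning(fisherExactMC(rbind(c(5, 5), c(0, 0), c(4, 6)), 1000,
                                 seed = 3), "zero")
})

test_that("adjusted residuals are unit-variance-standardised departures", {
    # independence table: all residuals 0
    ind <- outer(c(10, 20), c(6, 24)) / 30
    expect_true(all(abs(contingencyResiduals(ind)) < 1e-12))
    # 2x2 diagonal table, residuals computed by hand from the formula:
    # O-E = 5, V = 5 (1 - 1/2)(1 - 1/2) = 1.25, r = +-sqrt(20)
    tab <- matrix(c(10, 0, 0, 10), 2)
    res <- contingencyResiduals(tab)
    expect_equal(abs(as.numeric(res)), rep(sqrt(20), 4))
    expect_equal(res[1, 1], sqrt(20))
    expect_equal(res[1, 2], -sqrt(20))
    # weighted row/column sums vanish: r_ij sqrt(V_ij) = O - E
    pub <- bciSyndromeModelCounts()
    N <- sum(pub); E <- outer(rowSums(pub), colSums(pub)) / N
    V <- E * outer(1 - rowSums(pub) / N, 1 - colSums(pub) / N)
    resid <- contingencyResiduals(pub)
    expect_equal(unname(rowSums(resid * sqrt(V))), rep(0, 3))
    expect_equal(unname(colSums(resid * sqrt(V))), rep(0, 5))
    # the published table flags anemochorous/HPCP as significantly enriched
    expect_gt(resid["HPCP", "anemochorous"], 2)
    expect_warning(contingencyResiduals(matrix(c(2, 0, 3, 0), 2)), "zero")
})

test_that("rank tests reproduce hand-computed statistics", {
    kw <- kruskalWallisTest(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
    expect_equal(kw$statistic, 7.2)
    expect_equal(kw$df, 2)
    expect_warning(kw0 <- kruskalWallisTest(list(c(2, 2), c(2, 2))),
                   "identical")
    expect_equal(kw0$statistic, 0)
    expect_equal(kw0$p_value, 1)
    expect_error(kruskalWallisTest(list(1:3)), "2 non-empty")

    w <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))
    expect_equal(w$statistic, 0)
    expect_equal(w$p_value, 0.1) # exact, 2/20 rank splits as extreme
    w2 <- wilcoxonRankSum(c(1, 4), c(2, 3))
    expect_equal(w2$statistic, 2) # = n_a n_b / 2
    expect_equal(w2$p_value, 1)
    w3 <- wilcoxonRankSum(c(2, 5, 9), c(2, 5, 9))
    expect_equal(w3$statistic, 3 * 3 / 2) # midranks on identical multisets
    expect_error(wilcoxonRankSum(numeric(0), 1:3), "non-empty")
    wl <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6), alternative = "less")
    expect_equal(wl$p_value, 0.05)

    # two tie-free groups: H equals the squared standardised W
    a <- c(1, 2, 5); b <- c(3, 4, 6)
    H <- kruskalWallisTest(list(a, b))$statistic
    W <- wilcoxonRankSum(a, b)$statistic
    z <- (W - 9 / 2) / sqrt(3 * 3 * 7 / 12)
    expect_equal(H, z^2, tolerance = 1e-10)
})

test_that("tie handling matches a permutation oracle on small tied data", {
    a <- c(1, 2, 2, 4); b <- c(2, 3, 4, 4)
    W <- wilcoxonRankSum(a, b)$statistic
    # enumerate all 70 assignments of the pooled values to group a
    pool <- c(a, b)
    combs <- combn(8, 4)
    stats <- apply(combs, 2, function(idx)
        sum(rank(pool)[idx]) - 4 * 5 / 2)
    expect_equal(W, sum(rank(pool)[1:4]) - 10)
    pPerm <- mean(abs(stats - 8) >= abs(W - 8) - 1e-9)
    pNorm <- wilcoxonRankSum(a, b, exact = FALSE)$p_value
    expect_lt(abs(pPerm - pNorm), 0.12) # normal approx vs exact permutation
})

test_that("sigma summaries aggregate per cell with SE across species", {
    res <- data.frame(
        species = paste0("s", 1:7),
        group = c(rep("anemochorous", 3), "zoo-small", "zoo-small",
                  "autochorous", "zoo-large"),
        best_model = c("HPCP", "HPCP", "HPCP", "IPCP", "IPCP", "IPP", "HPCP"),
        sigma = c(10, 20, 30, 5, 7, NA, 40))
    s <- suppressWarnings(summarizeSigma(res))
    cell <- s$cells[s$cells$group == "anemochorous" & s$cells$model == "HPCP", ]
    expect_equal(cell$n, 3L)
    expect_equal(cell$mean_sigma, 20)
    expect_equal(cell$se_sigma, sd(c(10, 20, 30)) / sqrt(3), tolerance = 1e-6)
    single <- s$cells[s$cells$group == "zoo-large" & s$cells$model == "HPCP", ]
    expect_equal(single$se_sigma, 0)
    emptyCell <- s$cells[s$cells$group == "autochorous" &
                         s$cells$model == "HPCP", ]
    expect_equal(emptyCell$n, 0L)
    expect_true(is.na(emptyCell$mean_sigma))
    # IPP species carry no sigma and are excluded from the pooled set
    expect_equal(nrow(s$pooled), 6L)
    expect_false("s6" %in% s$pooled$species)

    # the published counts give the 189-species cluster pool
    fix <- countsToResults(bciSyndromeModelCounts())
    pool <- suppressWarnings(summarizeSigma(fix))$pooled
    expect_equal(nrow(pool), 189L) # 45 HPCP + 144 IPCP winners
})
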