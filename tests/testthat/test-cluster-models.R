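test_that("theoretical K forms evaluate to their closed-form values", {
    expect_equal(KPoisson(0), 0)
    expect_equal(KPoisson(10), pi * 100)
    expect_equal(KPoisson(250), 196349.5, tolerance = 1e-6)
    expect_error(KPoisson(-1), "non-negative")

    expect_equal(KThomas(10, 0.01, 5), pi * 100 + 100 * (1 - exp(-1)))
    # sigma -> infinity: cluster excess vanishes
    expect_equal(KThomas(50, 0.01, 1e9), KPoisson(50), tolerance = 1e-6)
    # r -> infinity: excess saturates at 1/kappa
    expect_equal(KThomas(1e6, 0.01, 5) - KPoisson(1e6), 100)
    expect_error(KThomas(1, -0.1, 5), "positive")
    expect_error(KThomas(1, 0.1, 0), "positive")
    # excess is positive, increasing, bounded by 1/kappa
    r <- seq(1, 200, by = 1)
    excess <- KThomas(r, 2e-4, 12) - KPoisson(r)
    expect_true(all(excess > 0))
    # saturates to 1/kappa, with cancellation noise, in double precision
    expect_true(all(diff(excess) >= -1e-6))
    expect_true(all(diff(excess[r <= 60]) > 0))
    expect_true(all(excess <= 1 / 2e-4 + 1e-6))
})

test_that("residual AIC orders fits by discrepancy and parameter count", {
    expect_lt(computeAIC(1, 2, 128), computeAIC(2, 2, 128))
    expect_lt(computeAIC(5, 1, 128), computeAIC(5, 2, 128))
    expect_equal(computeAIC(128, 2, 128), 4) # m ln(1) + 2k
    expect_warning(aic0 <- computeAIC(0, 2, 128), "perfect")
    expect_identical(aic0, -Inf)
    expect_equal(computeAIC(5, 2, 128, variant = "raw"), 9)
})

test_that("minimum contrast recovers parameters exactly from noise-free Thomas curves", {
    win <- Window(500, 500)
    pp <- simulateCSR(2e-3, win, seed = 1) # only supplies n and the window
    r <- fittingGrid(win)
    for (true in list(c(4e-4, 10), c(2e-3, 5), c(5e-5, 30))) {
        fit <- fitHPCP(pp, r, Khat = KThomas(r, true[1], true[2]))
        expect_equal(fit@kappa, true[1], tolerance = 1e-3)
        expect_equal(fit@sigma, true[2], tolerance = 1e-3)
        expect_lt(fit@D, 1e-8)
        expect_equal(fit@mu, npoints(pp) / (fit@kappa * 500^2),
                     tolerance = 1e-3)
    }
})

test_that("the optimiser beats a coarse grid-search oracle on the same contrast", {
    win <- Window(500, 500)
    pp <- simulateHPCP(4e-4, 10, 10, win, seed = 77)
    r <- fittingGrid(win)
    Khat <- estimateK(pp, r)@K
    q <- 1 / 4
    lattice <- expand.grid(kappa = 10^seq(-5, -2, length.out = 25),
                           sigma = exp(seq(log(2), log(60), length.out = 25)))
    gridBest <- min(vapply(seq_len(nrow(lattice)), function(i)
        sum((Khat^q - KThomas(r, lattice$kappa[i], lattice$sigma[i])^q)^2),
        numeric(1)))
    fit <- fitHPCP(pp, r, Khat = Khat)
    expect_lte(fit@D, gridBest + 1e-10)
})

test_that("simulated Thomas patterns yield sigma estimates near truth", {
    win <- Window(500, 500)
    sig <- vapply(1:12, function(i)
        fitHPCP(simulateHPCP(4e-4, 10, 10, win, seed = 2000 + i))@sigma,
        numeric(1))
    expect_lt(abs(median(sig) - 10) / 10, 0.2)
})

test_that("IPP fits flatten CSR patterns and IPCP reduces to HPCP on a flat surface", {
    win <- Window(500, 500)
    pp <- simulateCSR(2e-3, win, seed = 5)
    r <- fittingGrid(win)
    # large bandwidth on CSR: surface ~ flat, Kinhom ~ pi r^2, tiny D
    ipp <- fitIPP(pp, bandwidth = 200, r = r)
    expect_lt(ipp@D, fitIPP(pp, bandwidth = 12.5, r = r)@D + 1e-9)
    expect_identical(ipp@k, 1)
    # IPCP against the homogeneous empirical K equals the HPCP optimum
    pph <- simulateHPCP(4e-4, 10, 10, win, seed = 6)
    Khat <- estimateK(pph, r)@K
    hp <- fitHPCP(pph, r, Khat = Khat)
    ipcpFlat <- fitIPCP(pph, bandwidth = 100, r = r, KhatInhom = Khat)
    expect_equal(ipcpFlat@kappa, hp@kappa, tolerance = 1e-4)
    expect_equal(ipcpFlat@sigma, hp@sigma, tolerance = 1e-4)
    # internal consistency: D re-evaluates identically from the fitted params
    q <- 1 / 4
    Dre <- sum((Khat^q - KThomas(r, ipcpFlat@kappa, ipcpFlat@sigma)^q)^2)
    expect_equal(Dre, ipcpFlat@D, tolerance = 1e-10)
})

test_that("selection returns the full candidate set and breaks AIC ties toward simplicity", {
    win <- Window(500, 500)
    sel <- selectModel(simulateHPCP(4e-4, 10, 10, win, seed = 11),
                       bandwidths = c(25, 100), r = fittingGrid(win))
    rep <- fitReport(sel)
    expect_equal(nrow(rep), 1 + 2 * 2) # HPCP + (IPP, IPCP) per bandwidth
    expect_equal(sum(rep$best), 1L)
    expect_true(all(rep$k[rep$model == "IPP"] == 1))
    expect_true(all(rep$k[rep$model == "IPCP"] == 3))
    expect_true(is.na(rep$bandwidth[rep$model == "HPCP"]))
    expect_true(all(is.na(rep$sigma[rep$model == "IPP"])))
    # sigma reported only for cluster classes; 2 sigma is the cluster size
    expect_equal(rep$cluster_size, 2 * rep$sigma)

    # deterministic tie in AIC: the less complex class wins
    mk <- function(cls, aic, bw = NA_real_) new("ModelFit",
        modelClass = cls,
        kappa = if (cls == "IPP") NA_real_ else 1e-4,
        sigma = if (cls == "IPP") NA_real_ else 10,
        mu = if (cls == "IPP") NA_real_ else 5,
        bandwidth = if (cls == "HPCP") NA_real_ else bw, D = 1,
        k = c(IPP = 1, HPCP = 2, IPCP = 3)[[cls]], AIC = aic,
        converged = TRUE)
    fits <- list(mk("IPCP", -5, 50), mk("HPCP", -5), mk("IPP", -5, 50))
    expect_equal(stemPPM:::.pickBest(fits), 3L) # the IPP candidate
    fits2 <- list(mk("IPCP", -5, 50), mk("HPCP", -5))
    expect_equal(stemPPM:::.pickBest(fits2), 2L)
    # within a class, smaller bandwidth wins the tie
    fits3 <- list(mk("IPP", -5, 100), mk("IPP", -5, 25))
    expect_equal(stemPPM:::.pickBest(fits3), 2L)
    # all failed -> NA (selectModel turns this into an 'unfit' error)
    bad <- mk("HPCP", Inf); bad@converged <- FALSE
    expect_true(is.na(stemPPM:::.pickBest(list(bad))))
})
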