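#' Theoretical K function of the homogeneous Poisson process
#' @param r distance (m), r >= 0.
#' @return pi r^2.
#' @export
KPoisson <- function(r) {
    if (any(r < 0)) stop("r must be non-negative")
    pi * r^2
}

#' Theoretical K function of the (modified) Thomas cluster process
#'
#' K(r) = pi r^2 + (1/kappa) (1 - exp(-r^2 / (4 sigma^2))): Poisson parents
#' of intensity kappa, each offspring displaced by an isotropic Gaussian of
#' standard deviation sigma. The excess over pi r^2 is positive, increasing
#' in r and saturates at 1/kappa.
#'
#' @param r distance (m), r >= 0.
#' @param kappa parent intensity (parents / m^2), > 0.
#' @param sigma offspring displacement sd (m), > 0.
#' @return K values (m^2).
#' @examples
#' KThomas(10, kappa = 0.01, sigma = 5) # 314.159 + 100 (1 - e^-1)
#' @export
KThomas <- function(r, kappa, sigma) {
    if (any(r < 0)) stop("r must be non-negative")
    if (kappa <= 0 || sigma <= 0) stop("kappa and sigma must be positive")
    pi * r^2 + (1 / kappa) * (1 - exp(-r^2 / (4 * sigma^2)))
}

#' Fitting grid for minimum contrast
#'
#' Equally spaced distances from rmax/steps to rmax. The default rmax is a
#' quarter of the window's short side (125 m on a 1000 x 500 m plot).
#'
#' @param window a [Window-class] (used for the default rmax).
#' @param rmax largest fitting distance (m).
#' @param steps number of grid points (default 128).
#' @return numeric vector of distances.
#' @export
fittingGrid <- function(window = Window(), rmax = min(window@width,
                        window@height) / 4, steps = 128L) {
    seq(rmax / steps, rmax, length.out = steps)
}

# Minimum-contrast discrepancy: sum over the fitting grid of squared
# differences of the q-th powers of empirical and theoretical K. q = 1/4 is
# the variance-stabilising convention for K.
.contrast <- function(Khat, Ktheo, q) sum((Khat^q - Ktheo^q)^2)

# Minimise .contrast over (kappa, sigma) on log scale with bounded L-BFGS-B
# from a lattice of method-of-moments starts. Returns the best of all starts.
.minContrastThomas <- function(Khat, r, q, n, area,
                               kappaBounds = c(1e-7, 1),
                               sigmaBounds = c(0.5, 500)) {
    obj <- function(p) {
        Kt <- KThomas(r, exp(p[1L]), exp(p[2L]))
        .contrast(Khat, Kt, q)
    }
    starts <- expand.grid(mu = c(2, 5, 20), sigma = c(5, 15, 50))
    starts$kappa <- pmin(pmax(n / (area * starts$mu), kappaBounds[1L]),
                         kappaBounds[2L])
    best <- NULL
    for (s in seq_len(nrow(starts))) {
        fit <- tryCatch(
            optim(log(c(starts$kappa[s], starts$sigma[s])), obj,
                  method = "L-BFGS-B",
                  lower = log(c(kappaBounds[1L], sigmaBounds[1L])),
                  upper = log(c(kappaBounds[2L], sigmaBounds[2L]))),
            error = function(e) NULL)
        if (!is.null(fit) && (is.null(best) || fit$value < best$value))
            best <- fit
    }
    if (is.null(best))
        return(list(kappa = NA_real_, sigma = NA_real_, D = Inf,
                    converged = FALSE))
    list(kappa = exp(best$par[1L]), sigma = exp(best$par[2L]),
         D = best$value, converged = TRUE)
}

#' Residual-based AIC for a minimum-contrast fit
#'
#' Scores a fit by its contrast discrepancy D (the sum of squared
#' transformed-K residuals over the m fitting distances) and its parameter
#' count k. The default Gaussian-residual form AIC = m log(D/m) + 2k is
#' scale-free across models whose empirical K differs (homogeneous vs
#' intensity-reweighted); the raw alternative AIC = D + 2k is available via
#' `variant`. A perfect fit (D = 0) returns -Inf with a warning.
#'
#' @param D discrepancy, >= 0.
#' @param k number of free parameters.
#' @param m number of fitting distances, m >= k + 2.
#' @param variant "gaussian" (default) or "raw".
#' @return the AIC score.
#' @export
computeAIC <- function(D, k, m, variant = c("gaussian", "raw")) {
    variant <- match.arg(variant)
    stopifnot(D >= 0, m >= k + 2)
    if (D == 0) {
        warning("perfect fit (D = 0); AIC is -Inf")
        return(-Inf)
    }
    if (variant == "gaussian") m * log(D / m) + 2 * k else D + 2 * k
}

.newFit <- function(modelClass, kappa = NA_real_, sigma = NA_real_,
                    mu = NA_real_, bandwidth = NA_real_, D, k,
                    aicVariant, m, converged = TRUE) {
    aic <- if (is.finite(D)) computeAIC(D, k, m, aicVariant) else Inf
    new("ModelFit", modelClass = modelClass, kappa = kappa, sigma = sigma,
        mu = mu, bandwidth = bandwidth, D = D, k = as.numeric(k), AIC = aic,
        converged = converged)
}

#' Fit a homogeneous Poisson cluster process by minimum contrast
#'
#' Estimates (kappa, sigma) of a Thomas process by minimising
#' D(kappa, sigma) = sum_r (Khat(r)^q - K_Thomas(r; kappa, sigma)^q)^2 over
#' the fitting grid, from a lattice of method-of-moments starting values
#' with box constraints kappa in [1e-7, 1], sigma in [0.5, 500] m. The mean
#' offspring number is derived as mu = n / (kappa area) and the mean cluster
#' size is reported as 2 sigma. Two parameters are charged (k = 2).
#'
#' @param pattern a [PointPattern-class].
#' @param r fitting grid; default [fittingGrid()] of the pattern's window.
#' @param q contrast exponent (default 1/4).
#' @param correction edge correction for the empirical K.
#' @param aicVariant AIC form, see [computeAIC()].
#' @param Khat optional precomputed empirical K on `r` (vector), to avoid
#'   re-estimation when several models share it.
#' @return a [ModelFit-class] with modelClass "HPCP".
#' @export
fitHPCP <- function(pattern, r = fittingGrid(pattern@window), q = 1/4,
                    correction = "translation",
                    aicVariant = c("gaussian", "raw"), Khat = NULL) {
    aicVariant <- match.arg(aicVariant)
    if (is.null(Khat))
        Khat <- estimateK(pattern, r, correction)@K
    mc <- .minContrastThomas(Khat, r, q, npoints(pattern),
                             windowArea(pattern@window))
    mu <- if (is.finite(mc$kappa))
        npoints(pattern) / (mc$kappa * windowArea(pattern@window))
        else NA_real_
    .newFit("HPCP", kappa = mc$kappa, sigma = mc$sigma, mu = mu,
            D = mc$D, k = 2, aicVariant = aicVariant, m = length(r),
            converged = mc$converged)
}

#' Fit an inhomogeneous Poisson process at a given bandwidth
#'
#' The intensity surface is the leave-one-out Gaussian kernel estimate at
#' bandwidth h; conditional on that surface the model has no free shape
#' parameters, so the discrepancy is the contrast of the inhomogeneous
#' empirical K against the Poisson expectation pi r^2 and only the bandwidth
#' is charged (k = 1).
#'
#' @inheritParams fitHPCP
#' @param bandwidth kernel bandwidth (m).
#' @param KhatInhom optional precomputed inhomogeneous K on `r` for this
#'   bandwidth.
#' @return a [ModelFit-class] with modelClass "IPP".
#' @export
fitIPP <- function(pattern, bandwidth, r = fittingGrid(pattern@window),
                   q = 1/4, correction = "translation",
                   aicVariant = c("gaussian", "raw"), KhatInhom = NULL) {
    aicVariant <- match.arg(aicVariant)
    if (is.null(KhatInhom))
        KhatInhom <- estimateKinhom(pattern, r = r, correction = correction,
                                    bandwidth = bandwidth)@K
    D <- .contrast(KhatInhom, KPoisson(r), q)
    .newFit("IPP", bandwidth = bandwidth, D = D, k = 1,
            aicVariant = aicVariant, m = length(r))
}

#' Fit an inhomogeneous Poisson cluster process at a given bandwidth
#'
#' Minimum contrast of the Thomas K against the intensity-reweighted
#' empirical K computed with the bandwidth's surface: dispersal limitation
#' (kappa, sigma) on top of environmental heterogeneity (the surface). Three
#' parameters are charged (kappa, sigma and the bandwidth; k = 3).
#'
#' @inheritParams fitIPP
#' @return a [ModelFit-class] with modelClass "IPCP".
#' @export
fitIPCP <- function(pattern, bandwidth, r = fittingGrid(pattern@window),
                    q = 1/4, correction = "translation",
                    aicVariant = c("gaussian", "raw"), KhatInhom = NULL) {
    aicVariant <- match.arg(aicVariant)
    if (is.null(KhatInhom))
        KhatInhom <- estimateKinhom(pattern, r = r, correction = correction,
                                    bandwidth = bandwidth)@K
    mc <- .minContrastThomas(KhatInhom, r, q, npoints(pattern),
                             windowArea(pattern@window))
    mu <- if (is.finite(mc$kappa))
        npoints(pattern) / (mc$kappa * windowArea(pattern@window))
        else NA_real_
    .newFit("IPCP", kappa = mc$kappa, sigma = mc$sigma, mu = mu,
            bandwidth = bandwidth, D = mc$D, k = 3, aicVariant = aicVariant,
            m = length(r), converged = mc$converged)
}

# complexity order used for AIC tie-breaks: fewer parameters win
.classComplexity <- c(IPP = 1, HPCP = 2, IPCP = 3)

#' Select the best-fitting point process for one species
#'
#' Builds the full candidate set — one IPP and one IPCP fit per bandwidth in
#' the grid, plus the (bandwidth-free) HPCP fit — and returns all candidates
#' with the minimum-AIC fit marked. Exact AIC ties are broken toward the
#' less complex class (IPP < HPCP < IPCP by parameter count) and, within a
#' class, toward the smaller bandwidth.
#'
#' @inheritParams fitHPCP
#' @param bandwidths candidate kernel bandwidths; default [bandwidthGrid()].
#' @return a [ModelSelection-class].
#' @export
selectModel <- function(pattern, bandwidths = bandwidthGrid(),
                        r = fittingGrid(pattern@window), q = 1/4,
                        correction = "translation",
                        aicVariant = c("gaussian", "raw")) {
    aicVariant <- match.arg(aicVariant)
    Khat <- estimateK(pattern, r, correction)@K
    fits <- list(fitHPCP(pattern, r, q, correction, aicVariant, Khat = Khat))
    for (h in sort(bandwidths)) {
        KhI <- estimateKinhom(pattern, r = r, correction = correction,
                              bandwidth = h)@K
        fits <- c(fits,
                  fitIPP(pattern, h, r, q, correction, aicVariant,
                         KhatInhom = KhI),
                  fitIPCP(pattern, h, r, q, correction, aicVariant,
                          KhatInhom = KhI))
    }
    best <- .pickBest(fits)
    if (is.na(best))
        stop("unfit: all candidate fits failed for species '",
             speciesId(pattern), "'")
    new("ModelSelection", speciesId = speciesId(pattern), fits = fits,
        bestIndex = best)
}

# minimum-AIC candidate; exact ties go to the less complex class, then the
# smaller bandwidth. NA if no candidate converged to a usable score.
.pickBest <- function(fits) {
    ok <- vapply(fits, function(f)
        (f@converged && is.finite(f@AIC)) || identical(f@AIC, -Inf),
        logical(1))
    if (!any(ok)) return(NA_integer_)
    aic <- vapply(fits, function(f) f@AIC, numeric(1))
    cmplx <- .classComplexity[vapply(fits, modelClass, character(1))]
    bw <- vapply(fits, function(f) f@bandwidth, numeric(1))
    aic[!ok] <- Inf
    as.integer(order(aic, cmplx, ifelse(is.na(bw), 0, bw))[1L])
}

#' Flatten candidate fits of one or more selections to a data.frame
#'
#' @param selections a [ModelSelection-class] or list of them.
#' @return data.frame with one row per candidate fit: species, model,
#'   kappa, sigma, cluster_size (2 sigma), mu, bandwidth, D, k, AIC,
#'   best (logical).
#' @export
fitReport <- function(selections) {
    if (is(selections, "ModelSelection")) selections <- list(selections)
    do.call(rbind, lapply(selections, function(sel) {
        data.frame(
            species = speciesId(sel),
            model = vapply(sel@fits, modelClass, character(1)),
            kappa = vapply(sel@fits, function(f) f@kappa, numeric(1)),
            sigma = vapply(sel@fits, function(f) f@sigma, numeric(1)),
            cluster_size = 2 * vapply(sel@fits, function(f) f@sigma,
                                      numeric(1)),
            mu = vapply(sel@fits, function(f) f@mu, numeric(1)),
            bandwidth = vapply(sel@fits, function(f) f@bandwidth, numeric(1)),
            D = vapply(sel@fits, function(f) f@D, numeric(1)),
            k = vapply(sel@fits, function(f) f@k, numeric(1)),
            AIC = vapply(sel@fits, function(f) f@AIC, numeric(1)),
            best = seq_along(sel@fits) == sel@bestIndex)
    }))
}
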