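#' Simulate complete spatial randomness (homogeneous Poisson)
#'
#' N ~ Poisson(lambda * area) points placed uniformly on the window.
#'
#' @param lambda intensity (points / m^2), >= 0.
#' @param window a [Window-class].
#' @param seed optional integer; if given, the realisation is reproducible
#'   and the caller's RNG stream is left untouched.
#' @param speciesId label for the resulting pattern.
#' @return a [PointPattern-class].
#' @export
simulateCSR <- function(lambda, window = Window(), seed = NULL,
                        speciesId = "csr") {
    if (lambda < 0) stop("lambda must be non-negative")
    withSeed(seed, {
        n <- rpois(1L, lambda * windowArea(window))
        PointPattern(runif(n, 0, window@width), runif(n, 0, window@height),
                     window, speciesId)
    })
}

#' Simulate an inhomogeneous Poisson process
#'
#' Rejection (thinning) sampler: a homogeneous Poisson pattern at the
#' surface's maximum intensity is thinned, keeping each point with
#' probability lambda(x) / lambda_max. The expected count is the integral of
#' the surface over the window.
#'
#' @param surface an [IntensitySurface-class] (finite, non-negative).
#' @param seed optional integer seed.
#' @param speciesId label for the resulting pattern.
#' @return a [PointPattern-class].
#' @export
simulateIPP <- function(surface, seed = NULL, speciesId = "ipp") {
    lamMax <- max(surface@values)
    w <- surface@window
    if (lamMax == 0)
        return(PointPattern(numeric(0), numeric(0), w, speciesId))
    withSeed(seed, {
        n <- rpois(1L, lamMax * windowArea(w))
        x <- runif(n, 0, w@width); y <- runif(n, 0, w@height)
        keep <- runif(n) < evalSurface(surface, x, y) / lamMax
        PointPattern(x[keep], y[keep], w, speciesId)
    })
}

#' Simulate a homogeneous Poisson (Thomas) cluster process
#'
#' Two-step construction: Poisson parents of intensity kappa on the window
#' dilated by `dilation * sigma` on every side (so clusters whose parents
#' fall just outside still contribute offspring, removing edge bias), then a
#' Poisson(mu) number of offspring per parent, displaced by an isotropic
#' Gaussian of standard deviation sigma. Only offspring inside the window
#' are returned; parents are discarded. Expected count is kappa mu area.
#'
#' @param kappa parent intensity (parents / m^2), > 0.
#' @param mu mean offspring per parent, >= 0.
#' @param sigma offspring displacement sd (m), > 0.
#' @param window a [Window-class].
#' @param seed optional integer seed.
#' @param dilation parent-window margin in units of sigma (default 4,
#'   covering > 99.99% of offspring mass).
#' @param speciesId label for the resulting pattern.
#' @return a [PointPattern-class].
#' @export
simulateHPCP <- function(kappa, mu, sigma, window = Window(), seed = NULL,
                         dilation = 4, speciesId = "hpcp") {
    if (kappa <= 0 || sigma <= 0 || mu < 0)
        stop("require kappa > 0, sigma > 0, mu >= 0")
    withSeed(seed, .rThomas(kappa, mu, sigma, window, dilation, speciesId))
}

.rThomas <- function(kappa, mu, sigma, window, dilation, speciesId) {
    m <- dilation * sigma
    W <- window@width; H <- window@height
    nPar <- rpois(1L, kappa * (W + 2 * m) * (H + 2 * m))
    if (nPar == 0L || mu == 0)
        return(PointPattern(numeric(0), numeric(0), window, speciesId))
    px <- runif(nPar, -m, W + m); py <- runif(nPar, -m, H + m)
    nOff <- rpois(nPar, mu)
    x <- rep(px, nOff) + rnorm(sum(nOff), 0, sigma)
    y <- rep(py, nOff) + rnorm(sum(nOff), 0, sigma)
    keep <- x >= 0 & x <= W & y >= 0 & y <= H
    PointPattern(x[keep], y[keep], window, speciesId)
}

#' Simulate an inhomogeneous Poisson cluster process
#'
#' A homogeneous Thomas realisation whose offspring are thinned by
#' p(x) = lambda(x) / lambda_max: dispersal limitation (the clusters) with
#' intensity modulated by environmental heterogeneity (the surface), giving
#' the product-form intensity the fitted model assumes. Expected count is
#' kappa mu times the integral of lambda / lambda_max.
#'
#' @inheritParams simulateHPCP
#' @param surface an [IntensitySurface-class] modulating retention.
#' @return a [PointPattern-class].
#' @export
simulateIPCP <- function(kappa, mu, sigma, surface, seed = NULL,
                         dilation = 4, speciesId = "ipcp") {
    if (kappa <= 0 || sigma <= 0 || mu < 0)
        stop("require kappa > 0, sigma > 0, mu >= 0")
    lamMax <- max(surface@values)
    w <- surface@window
    withSeed(seed, {
        pp <- .rThomas(kappa, mu, sigma, w, dilation, speciesId)
        if (npoints(pp) == 0L || lamMax == 0)
            return(PointPattern(numeric(0), numeric(0), w, speciesId))
        keep <- runif(npoints(pp)) <
            evalSurface(surface, pp@x, pp@y) / lamMax
        PointPattern(pp@x[keep], pp@y[keep], w, speciesId)
    })
}

#' Random Gaussian-bump trend surface
#'
#' A smooth synthetic heterogeneity surface: a mixture of `nBumps` Gaussian
#' bumps with scales at least `minScale` (default 50 m, well separated from
#' within-cluster scales of a few tens of metres) on a positive baseline,
#' rescaled so the surface integrates to `targetMass` over the window.
#'
#' @param window a [Window-class].
#' @param nBumps number of bumps (default drawn uniformly from 3..10).
#' @param minScale,maxScale bump scale range (m).
#' @param baseline baseline level relative to the mean bump height (0..1).
#' @param targetMass desired integral (expected point count).
#' @param cellSize raster cell (m).
#' @param seed optional integer seed.
#' @return an [IntensitySurface-class] (bandwidth slot NA: parametric, not a
#'   kernel estimate).
#' @export
trendSurface <- function(window = Window(), nBumps = NULL, minScale = 50,
                         maxScale = 150, baseline = 0.2, targetMass = 500,
                         cellSize = 5, seed = NULL) {
    withSeed(seed, {
        if (is.null(nBumps)) nBumps <- sample(3:10, 1L)
        nx <- max(1L, round(window@width / cellSize))
        ny <- max(1L, round(window@height / cellSize))
        cx <- (seq_len(nx) - 0.5) * cellSize
        cy <- (seq_len(ny) - 0.5) * cellSize
        bx <- runif(nBumps, 0, window@width)
        by <- runif(nBumps, 0, window@height)
        sc <- runif(nBumps, minScale, maxScale)
        vals <- matrix(0, ny, nx)
        for (b in seq_len(nBumps))
            vals <- vals + outer(exp(-(cy - by[b])^2 / (2 * sc[b]^2)),
                                 exp(-(cx - bx[b])^2 / (2 * sc[b]^2)))
        vals <- vals + baseline * mean(vals)
        vals <- vals * targetMass / (sum(vals) * cellSize^2)
        new("IntensitySurface", values = vals, cellSize = cellSize,
            bandwidth = NA_real_, window = window)
    })
}

#' Flat (constant) intensity surface
#' @param window a [Window-class].
#' @param lambda constant intensity (points / m^2).
#' @param cellSize raster cell (m).
#' @return an [IntensitySurface-class].
#' @export
flatSurface <- function(window = Window(), lambda, cellSize = 5) {
    nx <- max(1L, round(window@width / cellSize))
    ny <- max(1L, round(window@height / cellSize))
    new("IntensitySurface",
        values = matrix(lambda, ny, nx), cellSize = cellSize,
        bandwidth = NA_real_, window = window)
}
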