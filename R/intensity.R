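# Fraction of a bivariate Gaussian kernel's mass (sd = h, centred at (x, y))
# that falls inside the rectangular window — separable product of normal CDFs.
# This is the Diggle edge-correction denominator; closed form, no raster.
.kernelEdgeMass <- function(x, y, h, window) {
    (pnorm((window@width - x) / h) - pnorm(-x / h)) *
        (pnorm((window@height - y) / h) - pnorm(-y / h))
}

#' Gaussian-kernel intensity surface
#'
#' Nonparametric estimate of the intensity lambda(x, y) from the pattern
#' itself: an isotropic Gaussian kernel of standard deviation `bandwidth` is
#' placed on every point and each kernel is divided by the fraction of its
#' mass inside the window (uniform edge correction), so the surface
#' integrates to n over the window regardless of how close points sit to the
#' boundary. Values are evaluated at cell centres of a regular raster.
#'
#' @param pattern a [PointPattern-class] with n >= 1.
#' @param bandwidth kernel standard deviation (m), > 0.
#' @param cellSize raster cell edge (m); default 5 m, must not exceed the
#'   bandwidth (undersmoothing the raster defeats the estimate).
#' @return an [IntensitySurface-class].
#' @examples
#' pp <- PointPattern(500, 250, Window(1000, 500))
#' surf <- kernelIntensity(pp, bandwidth = 10)
#' max(intensityValues(surf)) # ~ 1 / (2 pi 10^2)
#' @export
kernelIntensity <- function(pattern, bandwidth, cellSize = 5) {
    if (bandwidth <= 0) stop("bandwidth must be positive")
    if (cellSize > bandwidth)
        stop("cellSize must not exceed the bandwidth")
    if (npoints(pattern) < 1L) stop("need at least one point")
    w <- pattern@window
    nx <- max(1L, round(w@width / cellSize))
    ny <- max(1L, round(w@height / cellSize))
    cx <- (seq_len(nx) - 0.5) * cellSize
    cy <- (seq_len(ny) - 0.5) * cellSize
    vals <- matrix(0, nrow = ny, ncol = nx)
    mass <- .kernelEdgeMass(pattern@x, pattern@y, bandwidth, w)
    for (i in seq_len(npoints(pattern))) {
        gx <- dnorm(cx, mean = pattern@x[i], sd = bandwidth)
        gy <- dnorm(cy, mean = pattern@y[i], sd = bandwidth)
        vals <- vals + outer(gy, gx) / mass[i]
    }
    new("IntensitySurface", values = vals, cellSize = cellSize,
        bandwidth = bandwidth, window = w)
}

#' Kernel intensity evaluated at the data points
#'
#' Exact (closed-form, not raster) evaluation of the edge-corrected Gaussian
#' kernel estimate at the pattern's own points. With `leaveOneOut = TRUE`
#' (the default, and the convention used by [estimateKinhom()]) each point's
#' own kernel contribution 1/(2 pi h^2 m_i) is subtracted, which is always
#' strictly less than the full estimate.
#'
#' @param pattern a [PointPattern-class].
#' @param bandwidth kernel standard deviation (m).
#' @param leaveOneOut subtract each point's own contribution?
#' @return numeric vector of intensities (points / m^2), one per point.
#' @export
lambdaAtPoints <- function(pattern, bandwidth, leaveOneOut = TRUE) {
    if (bandwidth <= 0) stop("bandwidth must be positive")
    x <- pattern@x; y <- pattern@y
    n <- length(x)
    mass <- .kernelEdgeMass(x, y, bandwidth, pattern@window)
    d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
    kern <- exp(-d2 / (2 * bandwidth^2)) / (2 * pi * bandwidth^2)
    # contribution of kernel j (renormalised by its own edge mass) at point i
    lam <- as.numeric(kern %*% (1 / mass))
    if (leaveOneOut) {
        lam <- lam - (1 / (2 * pi * bandwidth^2)) / mass
        # an isolated point's leave-one-out estimate can underflow to zero;
        # floor it at a negligible fraction of the homogeneous intensity so
        # reweighting by 1/lambda stays finite (such fits score poorly anyway)
        lam <- pmax(lam, 1e-8 * n / windowArea(pattern@window))
    }
    lam
}

#' Look up surface values at arbitrary locations (nearest cell centre)
#' @param surface an [IntensitySurface-class].
#' @param x,y coordinates (m) inside the window.
#' @return numeric vector of intensities.
#' @export
evalSurface <- function(surface, x, y) {
    cs <- surface@cellSize
    ix <- pmin(pmax(ceiling(x / cs), 1L), ncol(surface@values))
    iy <- pmin(pmax(ceiling(y / cs), 1L), nrow(surface@values))
    surface@values[cbind(iy, ix)]
}

#' Integral of the surface over the window
#' @param surface an [IntensitySurface-class].
#' @return total mass (expected point count).
#' @export
surfaceMass <- function(surface) {
    sum(surface@values) * surface@cellSize^2
}

#' Candidate kernel bandwidths
#'
#' The bandwidth set over which the inhomogeneous models are fitted. The
#' default is a geometric ladder {12.5, 25, 50, 100, 200} m spanning
#' within-cluster to plot-quarter scales. An explicit list passes through
#' sorted and deduplicated; alternatively give `min`, `max` and `count` for
#' a geometric sequence.
#'
#' @param values explicit bandwidths (m), optional.
#' @param min,max,count geometric-grid specification, optional.
#' @return sorted numeric vector of distinct positive bandwidths.
#' @examples
#' bandwidthGrid()
#' bandwidthGrid(min = 10, max = 160, count = 5)
#' @export
bandwidthGrid <- function(values = NULL, min = NULL, max = NULL,
                          count = NULL) {
    out <- if (!is.null(values)) {
        sort(unique(as.numeric(values)))
    } else if (!is.null(min)) {
        stopifnot(!is.null(max), !is.null(count), count >= 1)
        exp(seq(log(min), log(max), length.out = count))
    } else {
        c(12.5, 25, 50, 100, 200)
    }
    if (any(out <= 0)) stop("bandwidths must be positive")
    out
}

#' Write an intensity surface as a plain-text ASCII grid
#'
#' ESRI ASCII-grid-style: a header (ncols, nrows, xllcorner, yllcorner,
#' cellsize, NODATA_value) followed by rows of values from the top (largest
#' y) down.
#'
#' @param surface an [IntensitySurface-class].
#' @param path output path.
#' @export
writeAsciiGrid <- function(surface, path) {
    v <- surface@values
    hdr <- c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
             "xllcorner 0", "yllcorner 0",
             paste("cellsize", surface@cellSize), "NODATA_value -9999")
    rows <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1L,
                  function(z) paste(signif(z, 7), collapse = " "))
    writeLines(c(hdr, rows), path)
    invisible(path)
}
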