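# Pairwise summaries shared by every K estimator: inter-point distances and
# translation edge-correction weights for the unordered pairs i < j. Computed
# once per pattern and reused across bandwidths and fitting grids.
.pairData <- function(pattern) {
    x <- pattern@x; y <- pattern@y
    n <- length(x)
    w <- pattern@window
    area <- windowArea(w)
    if (n < 2L)
        return(list(n = n, area = area, i = integer(0), j = integer(0),
                    d = numeric(0), wTrans = numeric(0), ord = integer(0)))
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- ij[, 1L]; j <- ij[, 2L]
    dx <- abs(x[i] - x[j]); dy <- abs(y[i] - y[j])
    d <- sqrt(dx^2 + dy^2)
    # translation weight: area / area of the window overlapped with itself
    # shifted by the pair's displacement (exact for rectangles)
    wTrans <- area / ((w@width - dx) * (w@height - dy))
    list(n = n, area = area, i = i, j = j, d = d, wTrans = wTrans,
         ord = order(d))
}

# Sum, for each r in `rs`, of `weights` over pairs with d <= r (pairs sorted
# once, cumulative sums queried by binary search).
.cumPairSum <- function(pd, weights, rs) {
    if (!length(pd$d)) return(numeric(length(rs)))
    cs <- cumsum(weights[pd$ord])
    idx <- findInterval(rs, pd$d[pd$ord])
    out <- numeric(length(rs))
    out[idx > 0L] <- cs[idx[idx > 0L]]
    out
}

.checkRGrid <- function(r, window) {
    if (any(r < 0) || is.unsorted(r, strictly = TRUE))
        stop("r grid must be non-negative and strictly increasing")
    diag <- sqrt(window@width^2 + window@height^2)
    if (max(r) > diag)
        stop(sprintf("r = %g exceeds the window diagonal (%.1f m)",
                     max(r), diag))
}

#' Default distance grid for aggregation profiles
#'
#' Distances every 10 m from 10 to 250 m. The profile grid starts at 10 m
#' because the aggregation statistic K(r)/(pi r^2) is undefined at r = 0.
#'
#' @param by grid step (m).
#' @param rmax largest distance (m).
#' @return numeric vector of distances.
#' @export
profileGrid <- function(by = 10, rmax = 250) seq(by, rmax, by = by)

#' Ripley's K function for a homogeneous pattern
#'
#' Estimates K(r) = (area / (n(n-1))) * sum over ordered pairs i != j of
#' 1(d_ij <= r) e_ij, where e_ij is 1 (`correction = "none"`) or the
#' translation edge-correction weight
#' area / ((width - |dx|)(height - |dy|)) (`correction = "translation"`,
#' the default: unbiased on rectangles without isotropic-weight geometry).
#' Under complete spatial randomness E K(r) = pi r^2. Duplicate points
#' contribute pairs at distance 0; self-pairs are excluded.
#'
#' @param pattern a [PointPattern-class] with at least 2 points.
#' @param r distance grid (m), strictly increasing.
#' @param correction "translation" (default) or "none".
#' @return a [KEstimate-class].
#' @examples
#' pp <- PointPattern(c(2, 2, 8), c(2, 3, 8), Window(10, 10))
#' estimateK(pp, r = c(1.5, 5), correction = "none")@K
#' @export
estimateK <- function(pattern, r = profileGrid(),
                      correction = c("translation", "none")) {
    correction <- match.arg(correction)
    if (npoints(pattern) < 2L) stop("degenerate pattern: need n >= 2")
    .checkRGrid(r, pattern@window)
    pd <- .pairData(pattern)
    wts <- if (correction == "translation") pd$wTrans else rep(1, length(pd$d))
    # each unordered pair stands for two ordered pairs
    K <- (pd$area / (pd$n * (pd$n - 1))) * 2 * .cumPairSum(pd, wts, r)
    new("KEstimate", r = r, K = K, correction = correction,
        kind = "homogeneous")
}

#' Inhomogeneous (intensity-reweighted) K function
#'
#' Estimates K_inhom(r) = (1/area) * sum over ordered pairs i != j of
#' 1(d_ij <= r) e_ij / (lambda_i lambda_j). Each point's intensity can be
#' supplied directly (numeric vector), looked up from an
#' [IntensitySurface-class], or estimated from the pattern itself by giving a
#' kernel `bandwidth` — in which case the leave-one-out kernel estimate is
#' used at each data point (its own kernel contribution subtracted), which
#' removes the dominant positive bias of plugging in a self-inclusive
#' estimate. With a constant surface lambda = n/area the estimator equals
#' (n-1)/n times [estimateK()] under the same correction.
#'
#' @param pattern a [PointPattern-class] with at least 2 points.
#' @param lambda per-point intensities: numeric vector of length n, an
#'   [IntensitySurface-class], or NULL to use `bandwidth`.
#' @param r distance grid (m).
#' @param correction "translation" or "none".
#' @param bandwidth Gaussian kernel bandwidth (m) used when `lambda` is NULL.
#' @return a [KEstimate-class] with kind "inhomogeneous".
#' @export
estimateKinhom <- function(pattern, lambda = NULL, r = profileGrid(),
                           correction = c("translation", "none"),
                           bandwidth = NULL) {
    correction <- match.arg(correction)
    if (npoints(pattern) < 2L) stop("degenerate pattern: need n >= 2")
    .checkRGrid(r, pattern@window)
    lam <- .resolveLambda(pattern, lambda, bandwidth)
    pd <- .pairData(pattern)
    base <- if (correction == "translation") pd$wTrans else rep(1, length(pd$d))
    wts <- base / (lam[pd$i] * lam[pd$j])
    K <- (1 / pd$area) * 2 * .cumPairSum(pd, wts, r)
    new("KEstimate", r = r, K = K, correction = correction,
        kind = "inhomogeneous")
}

.resolveLambda <- function(pattern, lambda, bandwidth) {
    n <- npoints(pattern)
    lam <- if (is.null(lambda)) {
        if (is.null(bandwidth))
            stop("supply per-point lambda, an IntensitySurface, or a bandwidth")
        lambdaAtPoints(pattern, bandwidth, leaveOneOut = TRUE)
    } else if (is(lambda, "IntensitySurface")) {
        evalSurface(lambda, pattern@x, pattern@y)
    } else {
        if (length(lambda) == 1L) rep(lambda, n) else as.numeric(lambda)
    }
    if (length(lam) != n) stop("lambda must have one value per point")
    if (any(!is.finite(lam)) || any(lam <= 0))
        stop("intensity must be strictly positive at every data point")
    lam
}

#' Per-group mean and standard error of the aggregation statistic
#'
#' Averages the aggregation statistic K(r)/(pi r^2) across the species of
#' each group at every distance of a shared grid, with SE = sd / sqrt(group
#' size) across species. Groups of size 1 report SE = 0 with a warning.
#'
#' @param estimates named list of [KEstimate-class], one per species, all on
#'   the same r grid.
#' @param groups named character vector mapping species to group labels.
#' @return data.frame with columns group, r, mean, se, n.
#' @export
groupAggregationProfile <- function(estimates, groups) {
    if (!length(estimates))
        return(data.frame(group = character(0), r = numeric(0),
                          mean = numeric(0), se = numeric(0), n = integer(0)))
    unknown <- setdiff(names(estimates), names(groups))
    if (length(unknown))
        stop("species missing from groups: ", paste(unknown, collapse = ", "))
    r0 <- estimates[[1L]]@r
    same <- vapply(estimates, function(e)
        length(e@r) == length(r0) && all(e@r == r0), logical(1))
    if (!all(same)) stop("all estimates must share the same r grid")
    agg <- vapply(estimates, aggregationIndex, numeric(length(r0)))
    agg <- matrix(agg, nrow = length(r0))
    grp <- groups[names(estimates)]
    out <- do.call(rbind, lapply(unique(grp), function(g) {
        cols <- which(grp == g)
        m <- rowMeans(agg[, cols, drop = FALSE])
        if (length(cols) == 1L) {
            warning("group '", g, "' has a single species; SE set to 0")
            s <- rep(0, length(r0))
        } else {
            s <- apply(agg[, cols, drop = FALSE], 1L, sd) / sqrt(length(cols))
        }
        data.frame(group = g, r = r0, mean = m, se = s, n = length(cols))
    }))
    rownames(out) <- NULL
    out
}

#' Export group aggregation profiles as CSV
#' @param profiles data.frame from [groupAggregationProfile()].
#' @param path output path.
#' @export
writeProfiles <- function(profiles, path) {
    write.csv(profiles, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
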