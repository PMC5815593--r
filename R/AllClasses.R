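#' @import methods
#' @importFrom stats dist dnorm optim pnorm rnorm runif rpois rlnorm sd var
#'   kruskal.test wilcox.test r2dtable quantile setNames aggregate pchisq
#' @importFrom utils read.csv write.csv
NULL

#' Rectangular observation window
#'
#' An axis-aligned rectangle with origin fixed at (0, 0), the sampling frame
#' for a stem map. The default dimensions follow the 50-ha forest-dynamics
#' plot convention: 1000 m x 500 m.
#'
#' @slot width plot width in metres (x extent).
#' @slot height plot height in metres (y extent).
#' @export
setClass("Window", representation(width = "numeric", height = "numeric"))

setValidity("Window", function(object) {
    if (length(object@width) != 1L || length(object@height) != 1L)
        return("width and height must be scalars")
    if (!is.finite(object@width) || !is.finite(object@height))
        return("window dimensions must be finite")
    if (object@width <= 0 || object@height <= 0)
        return("window dimensions must be positive")
    TRUE
})

#' @param width,height window dimensions in metres.
#' @rdname Window-class
#' @examples
#' win <- Window(1000, 500)
#' windowArea(win)
#' @export
Window <- function(width = 1000, height = 500) {
    new("Window", width = as.numeric(width), height = as.numeric(height))
}

#' Planar point pattern of one species
#'
#' Mapped stem coordinates of a single species inside a rectangular window.
#' Coordinates are continuous, in metres, window-relative with origin (0, 0);
#' duplicate coordinates are permitted (real censuses contain multiple stems
#' at identical map positions).
#'
#' @slot x,y point coordinates in metres.
#' @slot window a [Window-class].
#' @slot speciesId species label.
#' @export
setClass("PointPattern",
    representation(x = "numeric", y = "numeric", window = "Window",
                   speciesId = "character"))

setValidity("PointPattern", function(object) {
    if (length(object@x) != length(object@y))
        return("x and y must have equal length")
    if (anyNA(object@x) || anyNA(object@y))
        return("coordinates must not contain NA")
    w <- object@window
    if (length(object@x) &&
        (min(object@x) < 0 || max(object@x) > w@width ||
         min(object@y) < 0 || max(object@y) > w@height))
        return("all points must lie inside the window")
    TRUE
})

#' @param x,y numeric coordinate vectors (metres).
#' @param window a [Window-class].
#' @param speciesId species label.
#' @rdname PointPattern-class
#' @export
PointPattern <- function(x, y, window, speciesId = "sp") {
    new("PointPattern", x = as.numeric(x), y = as.numeric(y), window = window,
        speciesId = as.character(speciesId)[1L])
}

#' Gridded nonparametric intensity estimate
#'
#' A raster of estimated point density lambda(x, y), in points per square
#' metre, together with the Gaussian kernel bandwidth that produced it.
#' Cell (i, j) covers x in [(j-1), j] * cellSize and y likewise; values are
#' stored with rows indexing y and columns indexing x.
#'
#' @slot values matrix of intensity values (rows = y cells, cols = x cells).
#' @slot cellSize raster cell edge length (m).
#' @slot bandwidth Gaussian kernel standard deviation (m); NA for surfaces
#'   not produced by kernel smoothing (e.g. parametric trend surfaces).
#' @slot window the [Window-class] the raster covers.
#' @export
setClass("IntensitySurface",
    representation(values = "matrix", cellSize = "numeric",
                   bandwidth = "numeric", window = "Window"))

setValidity("IntensitySurface", function(object) {
    if (any(!is.finite(object@values)))
        return("intensity values must be finite")
    if (any(object@values < 0))
        return("intensity must be non-negative")
    if (object@cellSize <= 0)
        return("cellSize must be positive")
    w <- object@window
    nc <- ncol(object@values); nr <- nrow(object@values)
    if (abs(nc * object@cellSize - w@width) > object@cellSize ||
        abs(nr * object@cellSize - w@height) > object@cellSize)
        return("raster extent does not cover the window")
    TRUE
})

#' Empirical K-function estimate
#'
#' Ripley's K evaluated on a distance grid, either homogeneous or
#' intensity-reweighted (inhomogeneous), plus the dimensionless aggregation
#' statistic K(r) / (pi r^2) (1 under complete spatial randomness, > 1 for
#' clustering at scale r).
#'
#' @slot r distance grid (m), strictly increasing, r >= 0.
#' @slot K estimated K values (m^2).
#' @slot correction edge-correction label ("none" or "translation").
#' @slot kind "homogeneous" or "inhomogeneous".
#' @export
setClass("KEstimate",
    representation(r = "numeric", K = "numeric", correction = "character",
                   kind = "character"))

setValidity("KEstimate", function(object) {
    if (length(object@r) != length(object@K))
        return("r and K must have equal length")
    if (any(object@r < 0) || is.unsorted(object@r, strictly = TRUE))
        return("r must be non-negative and strictly increasing")
    if (any(object@K < -1e-9))
        return("K must be non-negative")
    if (!object@correction %in% c("none", "translation"))
        return("unknown correction")
    if (!object@kind %in% c("homogeneous", "inhomogeneous"))
        return("kind must be homogeneous or inhomogeneous")
    TRUE
})

#' One fitted candidate point-process model
#'
#' The result of fitting one member of the candidate set {IPP, HPCP, IPCP}
#' to a species pattern: the model class, its parameters, the minimum-contrast
#' discrepancy D, the parameter count k charged to the model, and the
#' residual-based AIC. For cluster models, `kappa` is the parent intensity
#' (parents / m^2), `sigma` the Gaussian offspring-displacement standard
#' deviation (m; mean cluster diameter is reported as 2 sigma) and `mu` the
#' mean number of offspring per parent. For inhomogeneous models `bandwidth`
#' is the kernel bandwidth (m) of the intensity surface, charged as one free
#' parameter.
#'
#' @slot modelClass one of "IPP", "HPCP", "IPCP".
#' @slot kappa,sigma,mu Thomas-process parameters (NA for IPP).
#' @slot bandwidth kernel bandwidth in metres (NA for HPCP).
#' @slot D minimum-contrast discrepancy (sum of squared transformed-K
#'   residuals over the fitting grid).
#' @slot k number of free parameters charged in the AIC.
#' @slot AIC the information-criterion score.
#' @slot converged logical; FALSE flags an optimiser failure.
#' @export
setClass("ModelFit",
    representation(modelClass = "character", kappa = "numeric",
                   sigma = "numeric", mu = "numeric", bandwidth = "numeric",
                   D = "numeric", k = "numeric", AIC = "numeric",
                   converged = "logical"))

setValidity("ModelFit", function(object) {
    if (!object@modelClass %in% c("IPP", "HPCP", "IPCP"))
        return("modelClass must be IPP, HPCP or IPCP")
    if (object@modelClass == "IPP" && !is.na(object@sigma))
        return("IPP carries no cluster parameters")
    if (object@modelClass == "HPCP" && !is.na(object@bandwidth))
        return("HPCP carries no bandwidth")
    if (is.finite(object@D) && object@D < 0)
        return("discrepancy must be non-negative")
    TRUE
})

#' Model-selection result for one species
#'
#' All candidate fits for a species together with the index of the minimum-AIC
#' fit. Ties are broken toward the less complex class (IPP < HPCP < IPCP by
#' parameter count).
#'
#' @slot speciesId species label.
#' @slot fits list of [ModelFit-class] candidates.
#' @slot bestIndex index of the selected fit within `fits`.
#' @export
setClass("ModelSelection",
    representation(speciesId = "character", fits = "list",
                   bestIndex = "integer"))

setValidity("ModelSelection", function(object) {
    if (!all(vapply(object@fits, is, logical(1), class2 = "ModelFit")))
        return("fits must all be ModelFit objects")
    if (length(object@fits)) {
        if (object@bestIndex < 1L || object@bestIndex > length(object@fits))
            return("bestIndex out of range")
    }
    TRUE
})
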