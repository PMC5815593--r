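#' @rdname Window-class
setMethod("windowArea", "Window", function(object) object@width * object@height)

#' @describeIn PointPattern-class number of points.
setMethod("npoints", "PointPattern", function(object) length(object@x))

#' @describeIn PointPattern-class overall intensity n / area (points per m^2).
setMethod("intensity", "PointPattern",
    function(object) length(object@x) / windowArea(object@window))

#' @describeIn PointPattern-class coordinates as an n x 2 matrix.
setMethod("coords", "PointPattern",
    function(object) cbind(x = object@x, y = object@y))

#' @describeIn PointPattern-class species label.
setMethod("speciesId", "PointPattern", function(object) object@speciesId)

#' @describeIn IntensitySurface-class raster of intensity values.
#' @param object an IntensitySurface
#' @export
intensityValues <- function(object) {
    stopifnot(is(object, "IntensitySurface"))
    object@values
}

#' @describeIn IntensitySurface-class kernel bandwidth (m).
setMethod("bandwidth", "IntensitySurface", function(object) object@bandwidth)

#' @describeIn ModelFit-class bandwidth charged to the fit (NA for HPCP).
setMethod("bandwidth", "ModelFit", function(object) object@bandwidth)

#' @describeIn KEstimate-class the aggregation statistic K(r) / (pi r^2).
setMethod("aggregationIndex", "KEstimate",
    function(object) object@K / (pi * object@r^2))

#' @describeIn ModelSelection-class the minimum-AIC candidate fit.
setMethod("bestFit", "ModelSelection",
    function(object) object@fits[[object@bestIndex]])

#' @describeIn ModelSelection-class class label of the selected fit.
setMethod("modelClass", "ModelSelection",
    function(object) object@fits[[object@bestIndex]]@modelClass)

#' @describeIn ModelFit-class class label of the fit.
setMethod("modelClass", "ModelFit", function(object) object@modelClass)

#' @describeIn ModelSelection-class species label.
setMethod("speciesId", "ModelSelection", function(object) object@speciesId)

setMethod("show", "Window", function(object) {
    cat(sprintf("Window: %g m x %g m (%.1f ha)\n",
        object@width, object@height, windowArea(object) / 1e4))
})

setMethod("show", "PointPattern", function(object) {
    cat(sprintf(
        "PointPattern '%s': %d points in %g x %g m window (lambda = %.3g /m^2)\n",
        object@speciesId, npoints(object), object@window@width,
        object@window@height, intensity(object)))
})

setMethod("show", "IntensitySurface", function(object) {
    cat(sprintf(
        "IntensitySurface: %d x %d cells of %g m, bandwidth %s m, range [%.3g, %.3g]\n",
        nrow(object@values), ncol(object@values), object@cellSize,
        format(object@bandwidth), min(object@values), max(object@values)))
})

setMethod("show", "KEstimate", function(object) {
    cat(sprintf("KEstimate (%s, %s correction): %d distances in [%g, %g] m\n",
        object@kind, object@correction, length(object@r),
        min(object@r), max(object@r)))
})

setMethod("show", "ModelFit", function(object) {
    cat(sprintf("ModelFit %s: ", object@modelClass))
    if (object@modelClass != "IPP")
        cat(sprintf("kappa = %.3g, sigma = %.2f m (cluster size %.1f m), ",
            object@kappa, object@sigma, 2 * object@sigma))
    if (object@modelClass != "HPCP")
        cat(sprintf("bandwidth = %g m, ", object@bandwidth))
    cat(sprintf("D = %.4g, k = %d, AIC = %.2f%s\n", object@D,
        as.integer(object@k), object@AIC,
        if (object@converged) "" else " [NOT CONVERGED]"))
})

setMethod("show", "ModelSelection", function(object) {
    cat(sprintf("ModelSelection '%s': %d candidates, best = %s\n",
        object@speciesId, length(object@fits), modelClass(object)))
    show(bestFit(object))
})
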