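#' @rdname Window-class
#' @param object a Window
#' @export
setGeneric("windowArea", function(object) standardGeneric("windowArea"))

#' Number of points
#' @param object a PointPattern
#' @export
setGeneric("npoints", function(object) standardGeneric("npoints"))

#' Overall (homogeneous) intensity n / area
#' @param object a PointPattern or IntensitySurface
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' Coordinates as a two-column matrix
#' @param object a PointPattern
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' Species label
#' @param object a PointPattern or ModelSelection
#' @export
setGeneric("speciesId", function(object) standardGeneric("speciesId"))

#' Kernel bandwidth (m)
#' @param object an IntensitySurface or ModelFit
#' @export
setGeneric("bandwidth", function(object) standardGeneric("bandwidth"))

#' Aggregation statistic K(r) / (pi r^2)
#'
#' Dimensionless clustering index: 1 under complete spatial randomness,
#' greater than 1 when the pattern is aggregated at scale r, below 1 when it
#' is more regular than random. Undefined (NaN) at r = 0.
#' @param object a KEstimate
#' @export
setGeneric("aggregationIndex",
    function(object) standardGeneric("aggregationIndex"))

#' Selected (minimum-AIC) fit
#' @param object a ModelSelection
#' @export
setGeneric("bestFit", function(object) standardGeneric("bestFit"))

#' Best-fitting model class label
#' @param object a ModelSelection or ModelFit
#' @export
setGeneric("modelClass", function(object) standardGeneric("modelClass"))
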