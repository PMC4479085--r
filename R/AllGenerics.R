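#' Adiabaticity ratio of a parameter set
#'
#' kappa = dG / dP compares the lifetime of the open gene state with the
#' protein lifetime; kappa << 0.01 is the slow (non-adiabatic) regime,
#' kappa >> 1 the fast (adiabatic) one.  For any other object this falls
#' back to the base condition-number estimator of the same name.
#'
#' @param z a [GeneNetworkParams-class]
#' @param ... ignored for parameter sets
#' @return the ratio dG / dP
#' @export
setGeneric("kappa")

#' @rdname kappa
#' @export
setMethod("kappa", "GeneNetworkParams", function(z, ...) z@dG / z@dP)

#' @export
setGeneric("steadyState", function(object, ...) standardGeneric("steadyState"))

#' @export
setGeneric("meanFirstPassage",
           function(object, ...) standardGeneric("meanFirstPassage"))

#' @export
setGeneric("landscape", function(object, ...) standardGeneric("landscape"))

#' @export
setGeneric("rates", function(object) standardGeneric("rates"))

#' @export
setGeneric("mixtureDensity",
           function(object, ...) standardGeneric("mixtureDensity"))
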