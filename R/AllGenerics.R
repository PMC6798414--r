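#' Accessor generics
#'
#' Small accessor family for the package's S4 containers, so user code never
#' touches slots directly.
#'
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("kineticCurves", function(object) standardGeneric("kineticCurves"))

#' @rdname accessors
#' @export
setGeneric("curveRoles", function(object) standardGeneric("curveRoles"))

#' @rdname accessors
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))

#' @rdname accessors
#' @export
setGeneric("proportions", function(object) standardGeneric("proportions"))

#' @rdname accessors
#' @export
setGeneric("trueProportions", function(object) standardGeneric("trueProportions"))

#' @rdname accessors
#' @export
setGeneric("tumourMask", function(object) standardGeneric("tumourMask"))

#' @rdname accessors
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))

#' @rdname accessors
#' @export
setGeneric("exemplars", function(object) standardGeneric("exemplars"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("moduleAssignments", function(object) standardGeneric("moduleAssignments"))

#' @rdname accessors
#' @export
setGeneric("moduleEigengenes", function(object) standardGeneric("moduleEigengenes"))

#' @rdname accessors
#' @export
setGeneric("signatureGenes", function(object) standardGeneric("signatureGenes"))

#' @rdname accessors
#' @export
setGeneric("signatureCoefficients", function(object) standardGeneric("signatureCoefficients"))

#' @rdname accessors
#' @export
setMethod("kineticCurves", "KineticCurveSet", function(object) object@curves)

#' @rdname accessors
#' @export
setMethod("curveRoles", "KineticCurveSet", function(object) object@roles)

#' @rdname accessors
#' @export
setMethod("timePoints", "KineticCurveSet", function(object) object@timepoints)

#' @rdname accessors
#' @export
setMethod("kineticCurves", "CompartmentModel", function(object) object@A)

#' @rdname accessors
#' @export
setMethod("curveRoles", "CompartmentModel", function(object) object@roles)

#' @rdname accessors
#' @export
setMethod("timePoints", "CompartmentModel", function(object) object@timepoints)

#' @rdname accessors
#' @export
setMethod("proportions", "CompartmentModel", function(object) object@K)

#' @rdname accessors
#' @export
setMethod("trueProportions", "SyntheticTumour", function(object) object@trueK)

#' @rdname accessors
#' @export
setMethod("tumourMask", "SyntheticTumour", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("imageData", "SyntheticTumour", function(object) object@image)

#' @rdname accessors
#' @export
setMethod("kineticCurves", "SyntheticTumour", function(object) object@trueCurves@curves)

#' @rdname accessors
#' @export
setMethod("exemplars", "ExemplarSet", function(object) object@exemplars)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ExemplarSet", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("moduleAssignments", "ModuleSet", function(object) object@assignments)

#' @rdname accessors
#' @export
setMethod("moduleEigengenes", "ModuleSet", function(object) object@eigengenes)

#' @rdname accessors
#' @export
setMethod("signatureGenes", "GeneSignature", function(object) object@genes)

#' @rdname accessors
#' @export
setMethod("signatureCoefficients", "GeneSignature", function(object) object@coefficients)
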