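#' Accessor generics
#'
#' Small accessor family for the S4 classes; slot access from user code is
#' discouraged.
#'
#' @param x an object of the documented classes
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @rdname accessors
#' @export
setGeneric("netCharge", function(x) standardGeneric("netCharge"))
#' @rdname accessors
#' @export
setGeneric("trainingScores", function(x) standardGeneric("trainingScores"))
#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))
#' @rdname accessors
#' @export
setGeneric("componentLoadings", function(x) standardGeneric("componentLoadings"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("clusterCentroids", function(x) standardGeneric("clusterCentroids"))
#' @rdname accessors
#' @export
setGeneric("modelCoefficients", function(x) standardGeneric("modelCoefficients"))
#' @rdname accessors
#' @export
setGeneric("modelStats", function(x) standardGeneric("modelStats"))
#' @rdname accessors
#' @export
setGeneric("chemSpace", function(x) standardGeneric("chemSpace"))
#' @rdname accessors
#' @export
setGeneric("clusterModel", function(x) standardGeneric("clusterModel"))

#' @rdname accessors
#' @export
setMethod("atoms", "MolecularGraph", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("bonds", "MolecularGraph", function(x) x@bonds)
#' @rdname accessors
#' @export
setMethod("netCharge", "MolecularGraph", function(x) x@netCharge)
#' @rdname accessors
#' @export
setMethod("trainingScores", "ChemSpaceModel", function(x) x@trainingScores)
#' @rdname accessors
#' @export
setMethod("eigenvalues", "ChemSpaceModel", function(x) x@eigenvalues)
#' @rdname accessors
#' @export
setMethod("explainedVariance", "ChemSpaceModel", function(x) x@explainedFraction)
#' @rdname accessors
#' @export
setMethod("componentLoadings", "ChemSpaceModel", function(x) x@loadings)
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterModel", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("clusterCentroids", "ClusterModel", function(x) x@centroids)
#' @rdname accessors
#' @export
setMethod("modelCoefficients", "QSPRModel", function(x) x@coefficients)
#' @rdname accessors
#' @export
setMethod("modelStats", "QSPRModel", function(x) x@stats)
#' @rdname accessors
#' @export
setMethod("chemSpace", "ModelBundle", function(x) x@chemspace)
#' @rdname accessors
#' @export
setMethod("clusterModel", "ModelBundle", function(x) x@clusters)
#' @rdname accessors
#' @export
setMethod("trainingScores", "ModelBundle", function(x) x@chemspace@trainingScores)
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ModelBundle", function(x) x@clusters@labels)
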