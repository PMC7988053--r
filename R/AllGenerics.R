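#' @rdname DMPSet-class
#' @param x a package object.
#' @export
setGeneric("dmpRecords", function(x) standardGeneric("dmpRecords"))

#' @rdname DMPSet-class
#' @export
setGeneric("comparisonName", function(x) standardGeneric("comparisonName"))

#' @rdname DMPSet-class
#' @export
setGeneric("nTested", function(x) standardGeneric("nTested"))

#' @rdname DMPSet-class
#' @export
setGeneric("isAnnotated", function(x) standardGeneric("isAnnotated"))

#' @rdname BetaSet-class
#' @param x a package object.
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname BetaSet-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname BetaSet-class
#' @export
setGeneric("probeManifest", function(x) standardGeneric("probeManifest"))

#' @rdname StudyDesign-class
#' @param x a package object.
#' @export
setGeneric("comparisonTable", function(x) standardGeneric("comparisonTable"))

#' @rdname PatientDMRSet-class
#' @param x a package object.
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname PatientDMRSet-class
#' @export
setGeneric("dmrRegions", function(x) standardGeneric("dmrRegions"))

#' @rdname SyntheticTruth-class
#' @param x a package object.
#' @export
setGeneric("plantedDMPs", function(x) standardGeneric("plantedDMPs"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("plantedDEGs", function(x) standardGeneric("plantedDEGs"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("patientSignal", function(x) standardGeneric("patientSignal"))
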