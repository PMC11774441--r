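#' @rdname RadiomicExperiment-accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname RadiomicExperiment-accessors
#' @export
setGeneric("acquisitionParameters",
           function(x) standardGeneric("acquisitionParameters"))

#' @rdname RadiomicExperiment-accessors
#' @export
setGeneric("acquisitionSchema",
           function(x) standardGeneric("acquisitionSchema"))

#' @rdname RadiomicExperiment-accessors
#' @export
setGeneric("subgroups", function(x) standardGeneric("subgroups"))

#' @rdname RadiomicExperiment-accessors
#' @export
setGeneric("malignancyLabels",
           function(x) standardGeneric("malignancyLabels"))

#' @rdname RadiomicExperiment-accessors
#' @export
setGeneric("scanIds", function(x) standardGeneric("scanIds"))

#' @rdname IndependenceReport-accessors
#' @export
setGeneric("independentFeatures",
           function(x) standardGeneric("independentFeatures"))

#' @rdname IndependenceReport-accessors
#' @export
setGeneric("failureCounts", function(x) standardGeneric("failureCounts"))

#' @rdname HarmonizationPlan-accessors
#' @export
setGeneric("parameterOrder", function(x) standardGeneric("parameterOrder"))

#' @rdname HarmonizationPlan-accessors
#' @export
setGeneric("exclusionLog", function(x) standardGeneric("exclusionLog"))

#' @rdname PredictiveModel-accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
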