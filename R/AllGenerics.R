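#' @include AllClasses.R
NULL

#' @export
setGeneric("segIds", function(x) standardGeneric("segIds"))
#' @export
setGeneric("segLengths", function(x) standardGeneric("segLengths"))
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))
#' @export
setGeneric("centromereId", function(x) standardGeneric("centromereId"))
#' @export
setGeneric("markerId", function(x) standardGeneric("markerId"))
#' @export
setGeneric("segGenes", function(x) standardGeneric("segGenes"))
#' @export
setGeneric("segArm", function(x) standardGeneric("segArm"))

#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @export
setGeneric("structureWord", function(x) standardGeneric("structureWord"))
#' @export
setGeneric("canonicalForm", function(x, map = NULL) standardGeneric("canonicalForm"))
#' @export
setGeneric("retainedFraction",
           function(x, map, weighting = c("bp", "segments"))
             standardGeneric("retainedFraction"))

#' @export
setGeneric("strains", function(x) standardGeneric("strains"))
#' @export
setGeneric("strainIds", function(x) standardGeneric("strainIds"))
#' @export
setGeneric("eventKinds", function(x) standardGeneric("eventKinds"))
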