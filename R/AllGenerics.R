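#' @importFrom BiocGenerics counts
NULL

#' @export
setGeneric("conditions", function(x, ...) standardGeneric("conditions"))

#' @export
setGeneric("pathwayNames", function(x) standardGeneric("pathwayNames"))

#' @export
setGeneric("members", function(x, pathway) standardGeneric("members"))

#' @export
setGeneric("pathwayEdges", function(x, pathway) standardGeneric("pathwayEdges"))

#' @export
setGeneric("deStatus", function(x) standardGeneric("deStatus"))

#' @export
setGeneric("deStatus<-", function(x, value) standardGeneric("deStatus<-"))

#' @export
setGeneric("degrees", function(x) standardGeneric("degrees"))

#' @export
setGeneric("isHub", function(x) standardGeneric("isHub"))

#' @export
setGeneric("singletons", function(x) standardGeneric("singletons"))

#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @export
setGeneric("homologPairs", function(x) standardGeneric("homologPairs"))
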