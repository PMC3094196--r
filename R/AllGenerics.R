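#' @include AllClasses.R
NULL

#' @export
setGeneric("scoreGenome", function(table, dictionary, ...)
  standardGeneric("scoreGenome"))

#' @export
setGeneric("klBits", function(x, ...) standardGeneric("klBits"))

#' @export
setGeneric("shannonBits", function(x, ...) standardGeneric("shannonBits"))

#' @export
setGeneric("relevanceScores", function(x) standardGeneric("relevanceScores"))

#' @export
setGeneric("contextName", function(x) standardGeneric("contextName"))

#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @export
setGeneric("setUniverse", function(x) standardGeneric("setUniverse"))

#' @export
setGeneric("overlapDistribution", function(collection)
  standardGeneric("overlapDistribution"))

#' @export
setGeneric("centralityProfile", function(graph, ...)
  standardGeneric("centralityProfile"))

#' @export
setGeneric("tissueSubnetwork", function(graph, expressed, ...)
  standardGeneric("tissueSubnetwork"))

#' @export
setGeneric("quantileNormalize", function(x, ...)
  standardGeneric("quantileNormalize"))

#' @export
setGeneric("detectionFilter", function(study, alpha = 0.01,
                                       minSamples = NULL, ...)
  standardGeneric("detectionFilter"))
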