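# Generics for class-dispatched operations.

#' @export
setGeneric("nTips", function(x) standardGeneric("nTips"))

#' @export
setGeneric("tipLabels", function(x) standardGeneric("tipLabels"))

#' @export
setGeneric("nodeTimes", function(x) standardGeneric("nodeTimes"))

#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @export
setGeneric("rootTime", function(x) standardGeneric("rootTime"))

#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @export
setGeneric("sitePatterns", function(x) standardGeneric("sitePatterns"))

#' @export
setGeneric("posteriorSummary", function(object, ...)
  standardGeneric("posteriorSummary"))

#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))

#' @export
setGeneric("particleWeights", function(x) standardGeneric("particleWeights"))

#' @export
setGeneric("modelState", function(x, i) standardGeneric("modelState"))

#' @export
setGeneric("logEvidence", function(x) standardGeneric("logEvidence"))
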