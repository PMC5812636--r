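# Generics for accessors. Slot access from user code is discouraged; these
# are the stable surface.

#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))
#' @export
setGeneric("channelType", function(x) standardGeneric("channelType"))
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))
#' @export
setGeneric("cytoplasm", function(x) standardGeneric("cytoplasm"))
#' @export
setGeneric("nucleus", function(x) standardGeneric("nucleus"))
#' @export
setGeneric("wellId", function(x) standardGeneric("wellId"))
#' @export
setGeneric("sceneDay", function(x) standardGeneric("sceneDay"))
#' @export
setGeneric("sceneCondition", function(x) standardGeneric("sceneCondition"))
#' @export
setGeneric("fieldIndex", function(x) standardGeneric("fieldIndex"))
#' @export
setGeneric("fiberLabels", function(x) standardGeneric("fiberLabels"))
#' @export
setGeneric("fiberTable", function(x) standardGeneric("fiberTable"))
#' @export
setGeneric("nucleusIds", function(x) standardGeneric("nucleusIds"))
#' @export
setGeneric("nFibers", function(x) standardGeneric("nFibers"))
#' @export
setGeneric("totalNuclei", function(x) standardGeneric("totalNuclei"))
#' @export
setGeneric("fusedNuclei", function(x) standardGeneric("fusedNuclei"))
#' @export
setGeneric("fusionIndexPct", function(x) standardGeneric("fusionIndexPct"))
#' @export
setGeneric("nFusedFibers", function(x) standardGeneric("nFusedFibers"))
#' @export
setGeneric("fiberAreasPx", function(x) standardGeneric("fiberAreasPx"))
#' @export
setGeneric("contrastValue", function(x) standardGeneric("contrastValue"))
#' @export
setGeneric("drugDays", function(x) standardGeneric("drugDays"))
#' @export
setGeneric("trueNuclei", function(x) standardGeneric("trueNuclei"))
#' @export
setGeneric("trueFiberMasks", function(x) standardGeneric("trueFiberMasks"))
#' @export
setGeneric("trueFusionIndexPct",
           function(x) standardGeneric("trueFusionIndexPct"))
#' @export
setGeneric("courseValues", function(x) standardGeneric("courseValues"))
#' @export
setGeneric("courseDays", function(x) standardGeneric("courseDays"))
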