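#' Accessors
#'
#' Accessor methods for the package's S4 classes.
#'
#' @param x an object of the documented class.
#' @return the slot value.
#' @name accessors
#' @aliases pixels bitDepth channelType pixelSizeUm cytoplasm nucleus wellId
#'   sceneDay sceneCondition fieldIndex fiberLabels fiberTable nucleusIds
#'   nFibers totalNuclei fusedNuclei fusionIndexPct nFusedFibers fiberAreasPx
#'   contrastValue drugDays trueNuclei trueFiberMasks trueFusionIndexPct
#'   courseValues courseDays
NULL

#' @rdname accessors
setMethod("pixels", "Image2D", function(x) x@pixels)
#' @rdname accessors
setMethod("bitDepth", "Image2D", function(x) x@bitDepth)
#' @rdname accessors
setMethod("channelType", "Image2D", function(x) x@channel)
#' @rdname accessors
setMethod("pixelSizeUm", "Image2D", function(x) x@pixelSizeUm)

#' @rdname accessors
setMethod("cytoplasm", "Scene", function(x) x@cytoplasm)
#' @rdname accessors
setMethod("nucleus", "Scene", function(x) x@nucleus)
#' @rdname accessors
setMethod("wellId", "Scene", function(x) x@wellId)
#' @rdname accessors
setMethod("sceneDay", "Scene", function(x) x@day)
#' @rdname accessors
setMethod("sceneCondition", "Scene", function(x) x@condition)
#' @rdname accessors
setMethod("fieldIndex", "Scene", function(x) x@fieldIndex)

#' @rdname accessors
setMethod("fiberLabels", "FiberSet", function(x) x@labels)
#' @rdname accessors
setMethod("fiberTable", "FiberSet", function(x) x@regions)
#' @rdname accessors
setMethod("nucleusIds", "FiberSet", function(x) x@nucleusIds)
#' @rdname accessors
setMethod("nFibers", "FiberSet", function(x) nrow(x@regions))

#' @rdname accessors
setMethod("totalNuclei", "FusionResult", function(x) x@totalNuclei)
#' @rdname accessors
setMethod("fusedNuclei", "FusionResult", function(x) x@fusedNuclei)
#' @rdname accessors
setMethod("fusionIndexPct", "FusionResult", function(x) x@fusionIndexPct)
#' @rdname accessors
setMethod("nFusedFibers", "FusionResult", function(x) x@nFusedFibers)
#' @rdname accessors
setMethod("fiberAreasPx", "FusionResult", function(x) x@fiberAreasPx)

#' @rdname accessors
setMethod("contrastValue", "ContrastMeasurement", function(x) x@contrast)

#' @rdname accessors
setMethod("drugDays", "ExposureSchedule", function(x) x@drugDays)

#' @rdname accessors
setMethod("trueNuclei", "GroundTruth", function(x) x@nuclei)
#' @rdname accessors
setMethod("trueFiberMasks", "GroundTruth", function(x) x@fiberMasks)
#' @rdname accessors
setMethod("trueFusionIndexPct", "GroundTruth",
          function(x) x@trueFusionIndexPct)
#' @rdname accessors
setMethod("totalNuclei", "GroundTruth", function(x) x@trueNucleiCount)

#' @rdname accessors
setMethod("courseValues", "TimeCourse", function(x) x@values)
#' @rdname accessors
setMethod("courseDays", "TimeCourse", function(x) x@days)
#' @rdname accessors
setMethod("sceneCondition", "TimeCourse", function(x) x@condition)

setMethod("show", "Image2D", function(object) {
  cat(sprintf("Image2D: %d x %d px, %d-bit, channel '%s', %.3g um/px\n",
              ncol(object@pixels), nrow(object@pixels), object@bitDepth,
              object@channel, object@pixelSizeUm))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "Scene", function(object) {
  cat(sprintf(
    "Scene: well %s, day %d, condition '%s', field %d (%d x %d px)\n",
    object@wellId, object@day, object@condition, object@fieldIndex,
    ncol(object@cytoplasm@pixels), nrow(object@cytoplasm@pixels)))
})

setMethod("show", "FiberSet", function(object) {
  nAssigned <- sum(lengths(object@nucleusIds))
  cat(sprintf("FiberSet: %d region(s), %d assigned nuclei\n",
              nrow(object@regions), nAssigned))
  if (nrow(object@regions) > 0) {
    print(utils::head(cbind(object@regions,
                            n_nuclei = lengths(object@nucleusIds)), 10))
    if (nrow(object@regions) > 10) cat("  ...\n")
  }
})

setMethod("show", "FusionResult", function(object) {
  cat(sprintf(
    "FusionResult: %d nuclei, %d fused (%.1f%%), %d fused fiber(s)\n",
    object@totalNuclei, object@fusedNuclei, object@fusionIndexPct,
    object@nFusedFibers))
})

setMethod("show", "ContrastMeasurement", function(object) {
  cat(sprintf(
    "ContrastMeasurement: contrast %.3f (object mean %.1f over %d px, background mean %.1f over %d px)\n",
    object@contrast, object@meanObject, object@nObjectPx,
    object@meanBackground, object@nBackgroundPx))
})

setMethod("show", "ExposureSchedule", function(object) {
  dd <- if (length(object@drugDays)) paste(object@drugDays, collapse = ",")
        else "none"
  cat(sprintf(
    "ExposureSchedule '%s': drug days %s (differentiation from day %d)\n",
    object@name, dd, object@differentiationStartDay))
})

setMethod("show", "SimulationParams", function(object) {
  cat(sprintf("SimulationParams: %d x %d px, %s, seed %d\n",
              object@width, object@height, object@labelCombo, object@seed))
  cat(sprintf(
    "  growth %d -> %d nuclei (x%.2f/day); fusion rate %.2f/day to fMax %.2f, drug effect %.2f\n",
    object@nNucleiDay0, object@plateauNuclei, object@growthRate,
    object@fusionRate, object@fMax, object@drugEffect))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d nuclei, %d fiber mask(s), true fusion index %.1f%%\n",
    object@trueNucleiCount,
    length(unique(object@fiberMasks[object@fiberMasks > 0])),
    object@trueFusionIndexPct))
})

setMethod("show", "TimeCourse", function(object) {
  cat(sprintf("TimeCourse '%s': days %s, %d replicate rows\n",
              object@condition, paste(object@days, collapse = ","),
              nrow(object@values)))
  if (length(object@missingDays))
    cat("  missing days:", paste(object@missingDays, collapse = ","), "\n")
})
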