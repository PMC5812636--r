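#' @import methods
#' @importFrom stats rnorm rpois runif median sd aov pt qt setNames
#' @importFrom utils read.csv write.csv
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Single-channel 2-D fluorescence image
#'
#' Container for one single-plane grayscale acquisition. Intensities are
#' stored as the camera reported them (no rescaling), in a row x column
#' matrix; coordinates elsewhere in the package are 0-based with x =
#' column and y = row.
#'
#' @slot pixels numeric matrix of non-negative intensities, rows = y.
#' @slot bitDepth integer, 8 or 16; intensities must not exceed
#'   \code{2^bitDepth - 1}. Other depths are rejected rather than rescaled,
#'   because silent rescaling corrupts contrast measurements.
#' @slot channel \code{"cytoplasm"} or \code{"nucleus"}.
#' @slot pixelSizeUm micrometers per pixel (default 1).
#'
#' @seealso [Image2D()], [Scene-class]
#' @name Image2D-class
#' @rdname Image2D-class
#' @exportClass Image2D
setClass("Image2D",
  representation(
    pixels = "matrix",
    bitDepth = "integer",
    channel = "character",
    pixelSizeUm = "numeric"
  )
)

setValidity("Image2D", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 16L || ncol(p) < 16L)
    return("both image dimensions must be >= 16 pixels")
  if (!(object@bitDepth %in% c(8L, 16L)))
    return(sprintf("unsupported bit depth %d (only 8 and 16 are accepted)",
                   object@bitDepth))
  if (anyNA(p) || min(p) < 0 || max(p) > 2^object@bitDepth - 1)
    return(sprintf("intensities must lie in [0, %d]", 2^object@bitDepth - 1L))
  if (!(object@channel %in% c("cytoplasm", "nucleus")))
    return("channel must be 'cytoplasm' or 'nucleus'")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a positive scalar")
  TRUE
})

#' Construct an Image2D
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param bitDepth 8 or 16.
#' @param channel \code{"cytoplasm"} or \code{"nucleus"}.
#' @param pixelSizeUm micrometers per pixel.
#' @return an [Image2D-class] object.
#' @examples
#' img <- Image2D(matrix(0L, 32, 32), bitDepth = 16, channel = "nucleus")
#' dim(pixels(img))
#' @export
Image2D <- function(pixels, bitDepth = 16L, channel = c("cytoplasm", "nucleus"),
                    pixelSizeUm = 1.0) {
  channel <- match.arg(channel)
  newValidated("Image2D", pixels = pixels, bitDepth = as.integer(bitDepth),
      channel = channel, pixelSizeUm = as.numeric(pixelSizeUm))
}

#' Paired-channel field of view
#'
#' One field of view: a cytoplasm image and a nucleus image of identical
#' pixel dimensions, plus the well/day/condition metadata that places the
#' field in a plate experiment.
#'
#' @slot cytoplasm,nucleus [Image2D-class] objects of equal dimensions.
#' @slot wellId well identifier, e.g. \code{"A1"}.
#' @slot day integer day of the time course (day 0 = seeding).
#' @slot condition experimental condition label.
#' @slot fieldIndex 0-based index of the field within the well.
#' @name Scene-class
#' @rdname Scene-class
#' @exportClass Scene
setClass("Scene",
  representation(
    cytoplasm = "Image2D",
    nucleus = "Image2D",
    wellId = "character",
    day = "integer",
    condition = "character",
    fieldIndex = "integer"
  )
)

setValidity("Scene", function(object) {
  if (!identical(dim(object@cytoplasm@pixels), dim(object@nucleus@pixels)))
    return(sprintf(
      "cytoplasm (%s) and nucleus (%s) images must have identical dimensions",
      paste(dim(object@cytoplasm@pixels), collapse = "x"),
      paste(dim(object@nucleus@pixels), collapse = "x")))
  if (object@day < 0L) return("day must be >= 0")
  if (object@fieldIndex < 0L) return("fieldIndex must be >= 0")
  TRUE
})

#' Construct a Scene
#'
#' @param cytoplasm,nucleus [Image2D-class] objects with matching dimensions.
#' @param wellId,condition character metadata.
#' @param day integer day (>= 0).
#' @param fieldIndex 0-based field index within the well.
#' @return a [Scene-class] object.
#' @export
Scene <- function(cytoplasm, nucleus, wellId = "A1", day = 0L,
                  condition = "ND", fieldIndex = 0L) {
  newValidated("Scene", cytoplasm = cytoplasm, nucleus = nucleus,
      wellId = as.character(wellId), day = as.integer(day),
      condition = as.character(condition), fieldIndex = as.integer(fieldIndex))
}

#' Segmented myotube candidate regions of one scene
#'
#' Holds the labeled fiber mask of a scene together with per-region shape
#' descriptors and (after [assignNuclei()]) the ids of nuclei contained in
#' each region. A single labeled matrix guarantees that region masks are
#' pairwise disjoint.
#'
#' @slot labels integer matrix, 0 = background, k = pixels of region k.
#'   Labels are assigned in raster (row-major) order of each region's first
#'   pixel.
#' @slot regions data.frame with one row per region: \code{label},
#'   \code{area_px}, \code{major_axis_px}, \code{minor_axis_px},
#'   \code{elongation} (major/minor axis ratio, >= 1).
#' @slot nucleusIds list of integer vectors, one per region, ids of the
#'   nucleus detections whose rounded centroid falls inside the region
#'   (empty until [assignNuclei()] is run).
#' @name FiberSet-class
#' @rdname FiberSet-class
#' @exportClass FiberSet
setClass("FiberSet",
  representation(
    labels = "matrix",
    regions = "data.frame",
    nucleusIds = "list"
  )
)

setValidity("FiberSet", function(object) {
  r <- object@regions
  need <- c("label", "area_px", "major_axis_px", "minor_axis_px", "elongation")
  if (!all(need %in% names(r)))
    return(paste("regions must have columns", paste(need, collapse = ", ")))
  if (nrow(r) != length(object@nucleusIds))
    return("nucleusIds must have one element per region")
  if (nrow(r) > 0) {
    counts <- tabulate(object@labels[object@labels > 0L], nbins = max(r$label))
    if (!all(counts[r$label] == r$area_px))
      return("area_px must equal the pixel count of each label in the mask")
    if (any(r$elongation < 1 - 1e-9, na.rm = TRUE))
      return("elongation must be >= 1")
  }
  TRUE
})

FiberSet <- function(labels, regions, nucleusIds = NULL) {
  if (is.null(nucleusIds))
    nucleusIds <- rep(list(integer(0)), nrow(regions))
  new("FiberSet", labels = labels, regions = regions, nucleusIds = nucleusIds)
}

#' Fusion quantitation of one scene
#'
#' The per-field readout of the pipeline: total detected nuclei, nuclei
#' inside fused fibers, the fusion index, and a fiber-size summary. A fiber
#' counts as fused only when it holds at least three nuclei; two nuclei in
#' one region are ambiguous (fused or dividing) and contribute nothing.
#'
#' @slot totalNuclei total number of detected nuclei.
#' @slot fusedNuclei number of nuclei in regions with >= 3 assigned nuclei.
#' @slot fusionIndexPct 100 * fusedNuclei / totalNuclei.
#' @slot nFusedFibers number of regions with >= 3 assigned nuclei.
#' @slot fiberAreasPx integer areas (px) of the fused regions.
#' @name FusionResult-class
#' @rdname FusionResult-class
#' @exportClass FusionResult
setClass("FusionResult",
  representation(
    totalNuclei = "integer",
    fusedNuclei = "integer",
    fusionIndexPct = "numeric",
    nFusedFibers = "integer",
    fiberAreasPx = "integer"
  )
)

setValidity("FusionResult", function(object) {
  if (object@fusedNuclei > object@totalNuclei)
    return("fusedNuclei cannot exceed totalNuclei")
  if (object@totalNuclei > 0) {
    expect <- 100 * object@fusedNuclei / object@totalNuclei
    if (abs(object@fusionIndexPct - expect) > 1e-9)
      return("fusionIndexPct must equal 100 * fusedNuclei / totalNuclei")
  }
  if (length(object@fiberAreasPx) != object@nFusedFibers)
    return("fiberAreasPx must have one entry per fused fiber")
  TRUE
})

FusionResult <- function(totalNuclei, fusedNuclei, nFusedFibers, fiberAreasPx) {
  new("FusionResult",
      totalNuclei = as.integer(totalNuclei),
      fusedNuclei = as.integer(fusedNuclei),
      fusionIndexPct = if (totalNuclei > 0) 100 * fusedNuclei / totalNuclei
                       else NA_real_,
      nFusedFibers = as.integer(nFusedFibers),
      fiberAreasPx = as.integer(fiberAreasPx))
}

#' Object-contrast measurement
#'
#' Contrast of one marked object against a marked background region:
#' \code{(S - bgd) / bgd}, where \code{S} is the mean pixel intensity over
#' the object pixels and \code{bgd} the mean over the background pixels.
#'
#' @slot contrast dimensionless contrast value.
#' @slot meanObject mean intensity over the object pixels.
#' @slot meanBackground mean intensity over the background pixels.
#' @slot nObjectPx,nBackgroundPx pixel counts of the two regions.
#' @name ContrastMeasurement-class
#' @rdname ContrastMeasurement-class
#' @exportClass ContrastMeasurement
setClass("ContrastMeasurement",
  representation(
    contrast = "numeric",
    meanObject = "numeric",
    meanBackground = "numeric",
    nObjectPx = "integer",
    nBackgroundPx = "integer"
  )
)

setValidity("ContrastMeasurement", function(object) {
  if (object@nObjectPx < 1L || object@nBackgroundPx < 1L)
    return("object and background regions must each contain >= 1 pixel")
  if (object@meanBackground <= 0)
    return("mean background intensity must be > 0")
  expect <- (object@meanObject - object@meanBackground) / object@meanBackground
  if (abs(object@contrast - expect) > 1e-9)
    return("contrast must equal (meanObject - meanBackground)/meanBackground")
  TRUE
})

#' Drug-exposure schedule over a differentiation time course
#'
#' Encodes when a drug is present during the culture period. The four named
#' schedules follow the standard plate design: no drug (ND), continuous
#' exposure over days 3-10, early exposure on days 3-5, and late exposure
#' on days 7-9, with differentiation medium starting on day 3.
#'
#' @slot name schedule name.
#' @slot drugDays integer days on which the drug is present.
#' @slot differentiationStartDay day differentiation medium starts
#'   (default 3); fusion cannot begin before it.
#' @name ExposureSchedule-class
#' @rdname ExposureSchedule-class
#' @exportClass ExposureSchedule
setClass("ExposureSchedule",
  representation(
    name = "character",
    drugDays = "integer",
    differentiationStartDay = "integer"
  )
)

setValidity("ExposureSchedule", function(object) {
  d <- object@drugDays
  ok <- switch(object@name,
    ND = length(d) == 0L,
    continuous = length(d) > 0L && all(d >= 3L & d <= 10L),
    early = identical(sort(d), 3:5),
    late = identical(sort(d), 7:9),
    TRUE)
  if (!ok)
    return(sprintf("drugDays inconsistent with named schedule '%s'",
                   object@name))
  if (any(d < 0L)) return("drugDays must be >= 0")
  TRUE
})

#' Construct an ExposureSchedule
#'
#' @param name one of \code{"ND"}, \code{"continuous"}, \code{"early"},
#'   \code{"late"}, or a custom name (then \code{drugDays} is required).
#' @param drugDays integer days with drug present; filled automatically for
#'   the four named schedules (ND: none; continuous: 3-10; early: 3-5;
#'   late: 7-9).
#' @param differentiationStartDay day the differentiation medium starts.
#' @return an [ExposureSchedule-class] object.
#' @examples
#' exposureSchedule("early")
#' exposureSchedule("pulse", drugDays = c(4, 6))
#' @export
exposureSchedule <- function(name, drugDays = NULL,
                             differentiationStartDay = 3L) {
  if (is.null(drugDays)) {
    drugDays <- switch(name,
      ND = integer(0), continuous = 3:10, early = 3:5, late = 7:9,
      stopValidation("custom schedule '%s' requires explicit drugDays", name))
  }
  newValidated("ExposureSchedule", name = name, drugDays = as.integer(sort(drugDays)),
      differentiationStartDay = as.integer(differentiationStartDay))
}

#' Simulator parameters
#'
#' Full parameterization of the synthetic double-labeled culture: scene
#' geometry, proliferation and fusion dynamics, drug response, label-combo
#' channel amplitudes, scaffold background and camera noise. Given
#' identical parameters and seed, simulator output is bit-identical.
#'
#' See [simulationParams()] for defaults and units.
#'
#' @name SimulationParams-class
#' @rdname SimulationParams-class
#' @exportClass SimulationParams
setClass("SimulationParams",
  representation(
    width = "integer", height = "integer",
    nNucleiDay0 = "integer", growthRate = "numeric",
    plateauNuclei = "integer",
    fusionRate = "numeric", fMax = "numeric", drugEffect = "numeric",
    labelCombo = "character", channelGains = "numeric",
    autofluorescenceLevel = "numeric", noiseGaussianSd = "numeric",
    nucleusRadiusPx = "numeric", fiberWidthPx = "numeric",
    nucleusSpacingPx = "numeric", fiberNucleiRange = "integer",
    twoNucleusFiberRate = "numeric",
    bitDepth = "integer", seed = "integer"
  )
)

setValidity("SimulationParams", function(object) {
  if (object@width < 64L || object@height < 64L)
    return("scene must be at least 64 x 64 pixels")
  if (object@fMax < 0 || object@fMax > 1) return("fMax must lie in [0, 1]")
  if (object@drugEffect < 0 || object@drugEffect > 1)
    return("drugEffect must lie in [0, 1]")
  if (object@fusionRate < 0) return("fusionRate must be >= 0")
  if (object@growthRate < 1) return("growthRate must be >= 1")
  if (!all(object@channelGains > 0) ||
      !identical(sort(names(object@channelGains)), c("cytoplasm", "nucleus")))
    return("channelGains must be positive and named cytoplasm/nucleus")
  if (object@autofluorescenceLevel < 0 || object@noiseGaussianSd < 0)
    return("background level and noise sd must be >= 0")
  if (object@nucleusRadiusPx <= 0 || object@fiberWidthPx <= 0)
    return("nucleusRadiusPx and fiberWidthPx must be > 0")
  if (object@twoNucleusFiberRate < 0 || object@twoNucleusFiberRate > 1)
    return("twoNucleusFiberRate must lie in [0, 1]")
  if (!(object@labelCombo %in% c("cGFP+nmCherry", "cmCherry+nGFP")))
    return("labelCombo must be 'cGFP+nmCherry' or 'cmCherry+nGFP'")
  if (!(object@bitDepth %in% c(8L, 16L))) return("bitDepth must be 8 or 16")
  TRUE
})

#' Construct simulator parameters
#'
#' Defaults describe a field of a well-plate culture imaged at roughly 1
#' um/px equivalent scale: ~40 nuclei at day 0 growing geometrically to a
#' confluent plateau, fusion following saturating first-order kinetics
#' after the switch to differentiation medium, and fluorophore amplitudes
#' chosen per label combination so that the cytoplasmic GFP + nuclear
#' mCherry combination has the higher cytoplasm signal-to-background.
#'
#' @param width,height scene size in pixels.
#' @param nNucleiDay0 nuclei per field at day 0.
#' @param growthRate per-day proliferation factor until the plateau.
#' @param plateauNuclei nuclei cap (confluence).
#' @param fusionRate first-order rate (per day) at which the fused fraction
#'   approaches \code{fMax} once differentiation starts.
#' @param fMax asymptotic fused fraction in [0, 1].
#' @param drugEffect multiplier in [0, 1] applied to \code{fusionRate} on
#'   drug days (1 = no effect, 0 = fusion fully blocked).
#' @param labelCombo \code{"cGFP+nmCherry"} or \code{"cmCherry+nGFP"}.
#' @param channelGains named numeric (cytoplasm, nucleus) object amplitudes
#'   above background, in camera counts; defaults depend on
#'   \code{labelCombo}.
#' @param autofluorescenceLevel mean background level in counts (raise it
#'   to emulate an autofluorescent collagen scaffold).
#' @param noiseGaussianSd additive Gaussian read-noise sd (counts); Poisson
#'   shot noise is always applied to signal + background first.
#' @param nucleusRadiusPx apparent nucleus radius; the rendered Gaussian
#'   spot has sigma = 0.6 * radius.
#' @param fiberWidthPx myotube width.
#' @param nucleusSpacingPx spacing of nuclei along a fiber axis.
#' @param fiberNucleiRange inclusive range of nuclei per fused fiber.
#' @param twoNucleusFiberRate fraction of non-fused nuclei paired into
#'   ambiguous two-nucleus fibers (counted not fused, by the >= 3 rule).
#' @param bitDepth camera bit depth (8 or 16).
#' @param seed integer master seed.
#' @return a [SimulationParams-class] object.
#' @export
simulationParams <- function(width = 384L, height = 384L,
                             nNucleiDay0 = 40L, growthRate = 1.35,
                             plateauNuclei = 130L,
                             fusionRate = 0.35, fMax = 0.6, drugEffect = 1,
                             labelCombo = c("cGFP+nmCherry", "cmCherry+nGFP"),
                             channelGains = NULL,
                             autofluorescenceLevel = 150,
                             noiseGaussianSd = 5,
                             nucleusRadiusPx = 3, fiberWidthPx = 7,
                             nucleusSpacingPx = 11,
                             fiberNucleiRange = c(3L, 7L),
                             twoNucleusFiberRate = 0.1,
                             bitDepth = 16L, seed = 1L) {
  labelCombo <- match.arg(labelCombo)
  if (is.null(channelGains)) {
    channelGains <- if (labelCombo == "cGFP+nmCherry")
      c(cytoplasm = 1600, nucleus = 3200)
    else
      c(cytoplasm = 700, nucleus = 2600)
  }
  newValidated("SimulationParams",
      width = as.integer(width), height = as.integer(height),
      nNucleiDay0 = as.integer(nNucleiDay0), growthRate = growthRate,
      plateauNuclei = as.integer(plateauNuclei),
      fusionRate = fusionRate, fMax = fMax, drugEffect = drugEffect,
      labelCombo = labelCombo, channelGains = channelGains,
      autofluorescenceLevel = autofluorescenceLevel,
      noiseGaussianSd = noiseGaussianSd,
      nucleusRadiusPx = nucleusRadiusPx, fiberWidthPx = fiberWidthPx,
      nucleusSpacingPx = nucleusSpacingPx,
      fiberNucleiRange = as.integer(fiberNucleiRange),
      twoNucleusFiberRate = twoNucleusFiberRate,
      bitDepth = as.integer(bitDepth), seed = as.integer(seed))
}

#' Simulator ground truth for one scene
#'
#' True nucleus centroids with fiber membership and the labeled true fiber
#' mask, emitted alongside every simulated scene so detection, segmentation
#' and the fusion index can be validated exactly.
#'
#' @slot nuclei data.frame: \code{id}, \code{x}, \code{y} (0-based centroid),
#'   \code{fiber} (label of the containing fiber, \code{NA} if
#'   mononucleated).
#' @slot fiberMasks labeled integer matrix of true fiber masks (0 =
#'   background).
#' @slot trueFusionIndexPct fusion index recomputable from the memberships
#'   under the >= 3 nuclei rule.
#' @slot trueNucleiCount number of true nuclei.
#' @name GroundTruth-class
#' @rdname GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    nuclei = "data.frame",
    fiberMasks = "matrix",
    trueFusionIndexPct = "numeric",
    trueNucleiCount = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  n <- object@nuclei
  if (!all(c("id", "x", "y", "fiber") %in% names(n)))
    return("nuclei must have columns id, x, y, fiber")
  if (nrow(n) != object@trueNucleiCount)
    return("trueNucleiCount must equal nrow(nuclei)")
  labs <- unique(object@fiberMasks[object@fiberMasks > 0L])
  if (!all(n$fiber[!is.na(n$fiber)] %in% labs))
    return("nucleus fiber memberships must reference existing fiber labels")
  if (nrow(n) > 0) {
    memb <- table(n$fiber[!is.na(n$fiber)])
    fused <- sum(memb[memb >= 3])
    expect <- 100 * fused / nrow(n)
    if (abs(object@trueFusionIndexPct - expect) > 1e-9)
      return("trueFusionIndexPct inconsistent with memberships (>= 3 rule)")
  }
  TRUE
})

#' Nucleus-detection configuration
#'
#' @param sigmaPx expected nucleus scale (sigma of the matched
#'   Laplacian-of-Gaussian blob filter), pixels.
#' @param relThreshold detection threshold relative to the maximum of the
#'   filtered image, in (0, 1); relative thresholding makes detection
#'   invariant to overall intensity scale.
#' @param minSeparationPx minimum distance between accepted peaks.
#' @param borderMarginPx margin near the image border inside which
#'   detections are dropped (truncated spots bias centroids); defaults to
#'   \code{2 * sigmaPx}.
#' @return a \code{DetectionConfig} object.
#' @name DetectionConfig-class
#' @rdname DetectionConfig-class
#' @exportClass DetectionConfig
setClass("DetectionConfig",
  representation(
    sigmaPx = "numeric", relThreshold = "numeric",
    minSeparationPx = "numeric", borderMarginPx = "numeric"
  )
)

setValidity("DetectionConfig", function(object) {
  if (object@sigmaPx <= 0) return("sigmaPx must be > 0")
  if (object@relThreshold <= 0 || object@relThreshold >= 1)
    return("relThreshold must lie strictly between 0 and 1")
  if (object@minSeparationPx < 1) return("minSeparationPx must be >= 1")
  if (object@borderMarginPx < 0) return("borderMarginPx must be >= 0")
  TRUE
})

#' @rdname DetectionConfig-class
#' @export
detectionConfig <- function(sigmaPx = 2.0, relThreshold = 0.15,
                            minSeparationPx = 5, borderMarginPx = 2 * sigmaPx) {
  newValidated("DetectionConfig", sigmaPx = sigmaPx, relThreshold = relThreshold,
      minSeparationPx = minSeparationPx, borderMarginPx = borderMarginPx)
}

#' Fiber-segmentation configuration
#'
#' @param backgroundRadiusPx scale (sigma) of the smoothed background
#'   estimate subtracted before thresholding; a large radius flattens
#'   scaffold autofluorescence without touching fiber-scale structure.
#' @param thresholdMethod \code{"otsu"} (default) or \code{"fixed"}.
#' @param fixedThreshold intensity threshold applied to the
#'   background-subtracted image when \code{thresholdMethod = "fixed"}.
#' @param minAreaPx minimum region area kept, pixels.
#' @param minElongation minimum major/minor axis ratio for a region to be
#'   classified as a fiber; round mononucleated cells have elongation near
#'   1 and are discarded.
#' @param closingRadiusPx radius of the morphological closing applied after
#'   thresholding.
#' @return a \code{SegmentationConfig} object.
#' @name SegmentationConfig-class
#' @rdname SegmentationConfig-class
#' @exportClass SegmentationConfig
setClass("SegmentationConfig",
  representation(
    backgroundRadiusPx = "numeric", thresholdMethod = "character",
    fixedThreshold = "numericOrNULL", minAreaPx = "integer",
    minElongation = "numeric", closingRadiusPx = "numeric"
  )
)

setValidity("SegmentationConfig", function(object) {
  if (!(object@thresholdMethod %in% c("otsu", "fixed")))
    return("thresholdMethod must be 'otsu' or 'fixed'")
  if (object@thresholdMethod == "fixed" && is.null(object@fixedThreshold))
    return("fixed threshold method requires fixedThreshold")
  if (object@minAreaPx < 1L) return("minAreaPx must be >= 1")
  if (object@minElongation < 1) return("minElongation must be >= 1")
  if (object@backgroundRadiusPx <= 0) return("backgroundRadiusPx must be > 0")
  TRUE
})

#' @rdname SegmentationConfig-class
#' @export
segmentationConfig <- function(backgroundRadiusPx = 50,
                               thresholdMethod = c("otsu", "fixed"),
                               fixedThreshold = NULL,
                               minAreaPx = 120L, minElongation = 3,
                               closingRadiusPx = 2) {
  thresholdMethod <- match.arg(thresholdMethod)
  newValidated("SegmentationConfig",
      backgroundRadiusPx = backgroundRadiusPx,
      thresholdMethod = thresholdMethod,
      fixedThreshold = fixedThreshold,
      minAreaPx = as.integer(minAreaPx), minElongation = minElongation,
      closingRadiusPx = closingRadiusPx)
}

#' Per-condition time course of replicate measurements
#'
#' Well-level replicate values of the fusion index and nuclei count over
#' the imaged days of one condition. Fields of a well are pooled by mean
#' before entering; wells are the replicate unit for statistics.
#'
#' @slot condition condition label.
#' @slot days ordered integer days with data.
#' @slot values data.frame: \code{day}, \code{well_id},
#'   \code{fusion_index_pct}, \code{total_nuclei} (one row per well per
#'   day).
#' @slot missingDays days present in the manifest but lacking results
#'   (reported, never imputed).
#' @name TimeCourse-class
#' @rdname TimeCourse-class
#' @exportClass TimeCourse
setClass("TimeCourse",
  representation(
    condition = "character",
    days = "integer",
    values = "data.frame",
    missingDays = "integer"
  )
)

setValidity("TimeCourse", function(object) {
  if (is.unsorted(object@days, strictly = TRUE))
    return("days must be strictly increasing")
  need <- c("day", "well_id", "fusion_index_pct", "total_nuclei")
  if (!all(need %in% names(object@values)))
    return(paste("values must have columns", paste(need, collapse = ", ")))
  if (length(object@days) > 0 &&
      !all(table(object@values$day) >= 1))
    return("each day must carry at least one replicate")
  TRUE
})
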