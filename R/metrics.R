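# Fusion quantitation: nucleus-to-fiber assignment, fusion index, fiber
# size summary, and object contrast.

#' Assign nucleus detections to fiber regions
#'
#' A nucleus belongs to the region whose mask contains its rounded centroid
#' pixel (nuclei are points; containment, not overlap fraction, is the
#' rule). Masks are disjoint, so each nucleus is assigned at most once;
#' nuclei whose centroid lies on background remain unassigned. Sub-pixel
#' centroids within half a pixel of the border are clamped to the edge
#' pixel; centroids outside the grid raise a validation error.
#'
#' @param detections data.frame from [detectNuclei()] (columns \code{id},
#'   \code{x}, \code{y}).
#' @param fibers a [FiberSet-class].
#' @return the [FiberSet-class] with \code{nucleusIds} populated.
#' @export
assignNuclei <- function(detections, fibers) {
  stopifnot(is(fibers, "FiberSet"))
  labels <- fibers@labels
  h <- nrow(labels); w <- ncol(labels)
  ids <- rep(list(integer(0)), nrow(fibers@regions))
  if (nrow(detections) > 0) {
    if (any(detections$x < 0 | detections$x >= w |
            detections$y < 0 | detections$y >= h))
      stopValidation("nucleus centroid outside the image grid")
    col <- pmin(w - 1L, pmax(0L, round(detections$x))) + 1L
    row <- pmin(h - 1L, pmax(0L, round(detections$y))) + 1L
    lab <- labels[cbind(row, col)]
    for (k in which(lab > 0L))
      ids[[lab[k]]] <- c(ids[[lab[k]]], as.integer(detections$id[k]))
  }
  fibers@nucleusIds <- ids
  validObject(fibers)
  fibers
}

#' Fusion index of one scene
#'
#' The fusion index is the percentage of all detected nuclei that sit in
#' fused fibers, where a fiber counts as fused only with
#' \code{minNucleiFused} (default 3) or more assigned nuclei. Regions
#' holding one or two nuclei contribute nothing: two nuclei in one region
#' cannot be distinguished from a dividing cell. A scene with zero nuclei
#' has no defined index and raises an error rather than returning 0.
#'
#' @param detections data.frame of nucleus detections.
#' @param fibers a [FiberSet-class] with \code{nucleusIds} populated (see
#'   [assignNuclei()]).
#' @param minNucleiFused minimum nuclei for a region to count as fused.
#' @return a [FusionResult-class].
#' @examples
#' # 10 nuclei, one fiber holding 3 of them -> 30%
#' @export
fusionIndex <- function(detections, fibers, minNucleiFused = 3L) {
  stopifnot(is(fibers, "FiberSet"))
  total <- nrow(detections)
  if (total == 0L)
    stopValidation(
      "fusion index undefined: no nuclei detected in this scene")
  counts <- lengths(fibers@nucleusIds)
  fusedIdx <- which(counts >= minNucleiFused)
  FusionResult(
    totalNuclei = total,
    fusedNuclei = sum(counts[fusedIdx]),
    nFusedFibers = length(fusedIdx),
    fiberAreasPx = fibers@regions$area_px[fusedIdx])
}

#' Object contrast against a marked background
#'
#' Computes \code{(S - bgd) / bgd} where \code{S} is the mean intensity
#' over the object pixels and \code{bgd} the mean over the background
#' pixels. The measure is invariant under multiplying the image by a
#' positive constant and deliberately not invariant under adding an
#' offset.
#'
#' @param img an [Image2D-class].
#' @param objectPx,backgroundPx pixel sets: either logical masks of the
#'   image dimensions or two-column matrices of 0-based (x, y) coordinates.
#'   The sets must be non-empty, inside the grid, and disjoint.
#' @return a [ContrastMeasurement-class].
#' @examples
#' px <- matrix(50, 32, 32); px[10:20, 10:20] <- 200
#' img <- Image2D(px, 16, "cytoplasm")
#' obj <- px == 200
#' contrastValue(objectContrast(img, obj, !obj))  # (200 - 50)/50 = 3
#' @export
objectContrast <- function(img, objectPx, backgroundPx) {
  stopifnot(is(img, "Image2D"))
  px <- img@pixels
  toIdx <- function(set, what) {
    if (is.matrix(set) && !is.logical(set) && ncol(set) == 2) {
      x <- set[, 1]; y <- set[, 2]
      if (any(x < 0 | x > ncol(px) - 1 | y < 0 | y > nrow(px) - 1))
        stopValidation("%s pixel set extends outside the image grid", what)
      (round(x)) * nrow(px) + round(y) + 1
    } else if (is.logical(set) || all(set %in% c(0, 1))) {
      if (!identical(dim(set), dim(px)))
        stopDimension("%s mask dimensions differ from the image", what)
      which(set > 0)
    } else stopValidation("%s must be a logical mask or (x, y) matrix", what)
  }
  oi <- toIdx(objectPx, "object")
  bi <- toIdx(backgroundPx, "background")
  if (length(oi) < 1 || length(bi) < 1)
    stopValidation("object and background pixel sets must be non-empty")
  if (length(intersect(oi, bi)) > 0)
    stopValidation("object and background pixel sets overlap")
  s <- mean(px[oi])
  bgd <- mean(px[bi])
  if (bgd == 0)
    stopValidation(
      "contrast undefined: mean background intensity is zero (division by zero)")
  new("ContrastMeasurement",
      contrast = (s - bgd) / bgd, meanObject = s, meanBackground = bgd,
      nObjectPx = length(oi), nBackgroundPx = length(bi))
}

#' Full per-scene quantitation
#'
#' Composition of the pipeline on one scene: [detectNuclei()] on the
#' nucleus channel, [segmentFibers()] on the cytoplasm channel,
#' [assignNuclei()], and [fusionIndex()]. Deterministic for fixed input and
#' configurations; errors from a stage are re-signalled with the stage name
#' attached.
#'
#' @param scene a [Scene-class].
#' @param detCfg a [DetectionConfig-class].
#' @param segCfg a [SegmentationConfig-class].
#' @return a [FusionResult-class].
#' @export
sceneMetrics <- function(scene, detCfg = detectionConfig(),
                         segCfg = segmentationConfig()) {
  stopifnot(is(scene, "Scene"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(class = class(e),
                     list(message = sprintf("[%s] %s", name,
                                            conditionMessage(e)),
                          call = conditionCall(e))))
    })
  }
  det <- stage("detect_nuclei", detectNuclei(scene@nucleus, detCfg))
  fib <- stage("segment_fibers", segmentFibers(scene@cytoplasm, segCfg))
  fib <- stage("assign_nuclei", assignNuclei(det, fib))
  stage("fusion_index", fusionIndex(det, fib))
}
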