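# Myotube segmentation from the cytoplasm channel: background subtraction,
# thresholding, morphological cleanup, connected components, and a shape
# filter keeping only elongated regions.

# connected components with 8-connectivity: EBImage::bwlabel is
# 4-connected, so labels touching only diagonally are merged afterwards
# (union-find over diagonal neighbor label pairs)
label8 <- function(mask) {
  labEB <- EBImage::bwlabel(asEB(mask * 1))
  labels <- matrix(as.integer(fromEB(labEB)), nrow(mask), ncol(mask))
  n <- max(labels)
  if (n < 2L) return(labels)
  h <- nrow(labels); w <- ncol(labels)
  a <- labels[-h, -w]; b <- labels[-1, -1]   # down-right diagonal
  c1 <- labels[-h, -1]; d <- labels[-1, -w]  # down-left diagonal
  pairs <- rbind(cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]),
                 cbind(c1[c1 > 0 & d > 0 & c1 != d],
                       d[c1 > 0 & d > 0 & c1 != d]))
  if (nrow(pairs) == 0L) return(labels)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  labels[labels > 0L] <- root[labels[labels > 0L]]
  labels
}

#' Segment myotube candidate regions
#'
#' Pipeline: a large-radius Gaussian-smoothed background estimate is
#' subtracted (flattening scaffold autofluorescence), the residual is
#' thresholded (Otsu by default), the mask is morphologically closed and
#' hole-filled, connected components (8-connectivity) are extracted, and
#' components smaller than \code{minAreaPx} or with major/minor axis ratio
#' below \code{minElongation} are discarded -- round mononucleated cell
#' bodies fail the elongation filter while myotubes pass. Because the
#' threshold is applied to the background-subtracted residual, adding a
#' constant to every pixel leaves the segmentation unchanged.
#'
#' @param cytoImg an [Image2D-class] (cytoplasm channel).
#' @param cfg a [SegmentationConfig-class].
#' @return a [FiberSet-class]; labels are assigned in raster order of each
#'   region's first pixel.
#' @examples
#' sim <- simulateScene(simulationParams(seed = 3), day = 7)
#' fib <- segmentFibers(cytoplasm(sim$scene), segmentationConfig())
#' fiberTable(fib)
#' @export
segmentFibers <- function(cytoImg, cfg = segmentationConfig()) {
  stopifnot(is(cytoImg, "Image2D"), is(cfg, "SegmentationConfig"))
  validObject(cfg)
  px <- cytoImg@pixels
  h <- nrow(px); w <- ncol(px)
  emptySet <- FiberSet(matrix(0L, h, w), data.frame(
    label = integer(0), area_px = integer(0), major_axis_px = numeric(0),
    minor_axis_px = numeric(0), elongation = numeric(0)))

  # Gaussian kernel must fit inside the image; cap the radius for small
  # fields of view
  bgSigma <- min(cfg@backgroundRadiusPx, (min(h, w) - 1) / 7)
  bg <- fromEB(EBImage::gblur(asEB(px), sigma = bgSigma))
  sub <- pmax(px - bg, 0)
  if (max(sub) <= 0) return(emptySet)

  thr <- if (cfg@thresholdMethod == "otsu") {
    maxv <- 2^cytoImg@bitDepth - 1
    EBImage::otsu(asEB(sub / maxv), range = c(0, 1), levels = 256) * maxv
  } else {
    cfg@fixedThreshold
  }
  mask <- sub > thr
  if (!any(mask)) return(emptySet)

  if (cfg@closingRadiusPx > 0) {
    brush <- EBImage::makeBrush(2L * ceiling(cfg@closingRadiusPx) + 1L, "disc")
    mask <- fromEB(EBImage::closing(asEB(mask * 1), brush)) > 0
  }
  mask <- fromEB(EBImage::fillHull(asEB(mask * 1))) > 0
  labels <- relabelRaster(label8(mask))

  nlab <- max(labels)
  if (nlab == 0L) return(emptySet)
  areas <- tabulate(labels[labels > 0L], nbins = nlab)
  mom <- EBImage::computeFeatures.moment(asEB(labels))
  mom <- matrix(mom, ncol = ncol(mom), dimnames = list(NULL, colnames(mom)))
  major <- mom[, "m.majoraxis"]
  ecc <- pmin(mom[, "m.eccentricity"], 1)
  minor <- major * sqrt(pmax(1 - ecc^2, 0))
  elong <- ifelse(minor > 0, major / minor, Inf)

  keep <- which(areas >= cfg@minAreaPx & elong >= cfg@minElongation)
  if (length(keep) == 0L) return(emptySet)
  # labels are already in raster order; keeping ascending order preserves it
  newOf <- integer(nlab)
  newOf[keep] <- seq_along(keep)
  kept <- matrix(0L, h, w)
  pos <- labels > 0L
  kept[pos] <- newOf[labels[pos]]
  regions <- data.frame(
    label = seq_along(keep),
    area_px = as.integer(areas[keep]),
    major_axis_px = as.numeric(major[keep]),
    minor_axis_px = as.numeric(minor[keep]),
    elongation = as.numeric(elong[keep]))
  FiberSet(kept, regions)
}

#' Intersection-over-union of a region and a reference mask
#'
#' @param mask,truthMask logical (or 0/1) matrices on the same grid.
#' @return IoU in [0, 1]; 0 when both masks are empty.
#' @export
maskIoU <- function(mask, truthMask) {
  if (!identical(dim(mask), dim(truthMask)))
    stopDimension("mask dimensions differ: %s vs %s",
                  paste(dim(mask), collapse = "x"),
                  paste(dim(truthMask), collapse = "x"))
  a <- mask > 0; b <- truthMask > 0
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Best-matching IoU for every ground-truth fiber
#'
#' For each labeled region of a ground-truth mask, reports the maximum IoU
#' achieved by any segmented region (0 when nothing overlaps).
#'
#' @param fibers a [FiberSet-class].
#' @param truthMasks labeled integer matrix of true fiber masks.
#' @return numeric vector named by truth label.
#' @export
fiberRecoveryIoU <- function(fibers, truthMasks) {
  labs <- sort(unique(truthMasks[truthMasks > 0L]))
  segLabels <- fiberLabels(fibers)
  out <- setNames(numeric(length(labs)), labs)
  for (i in seq_along(labs)) {
    tm <- truthMasks == labs[i]
    cand <- unique(segLabels[tm & segLabels > 0L])
    best <- 0
    for (l in cand) best <- max(best, maskIoU(segLabels == l, tm))
    out[i] <- best
  }
  out
}
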