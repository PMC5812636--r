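# Nucleus detection: scale-matched (Laplacian-of-Gaussian) blob filtering
# followed by thresholded local maxima with minimum-separation suppression
# and sub-pixel (parabolic) centroid refinement.

# negated, zero-mean, scale-normalized LoG kernel: bright blobs of scale
# sigma give a positive peak; zero mean makes the response ignore constant
# offsets.
logKernel <- function(sigma) {
  r <- ceiling(3.5 * sigma)
  xs <- -r:r
  g <- outer(xs, xs, function(x, y) {
    rr <- x^2 + y^2
    -(rr - 2 * sigma^2) / sigma^2 * exp(-rr / (2 * sigma^2))
  })
  g - mean(g)
}

blobResponse <- function(px, sigma) {
  fromEB(EBImage::filter2(asEB(px), logKernel(sigma), boundary = "replicate"))
}

#' Detect nuclei as sub-pixel blob centroids
#'
#' Filters the nucleus channel with a Laplacian-of-Gaussian kernel matched
#' to the expected nucleus scale, keeps local maxima above a threshold
#' relative to the filtered-image maximum, greedily suppresses peaks closer
#' than the minimum separation (strongest response wins), drops detections
#' within the border margin, and refines each centroid by a 3-point
#' parabolic fit per axis. Relative thresholding makes the detection set
#' invariant to multiplying the image by any positive constant; a blank
#' image yields no detections.
#'
#' @param nucleusImg an [Image2D-class] (nucleus channel).
#' @param cfg a [DetectionConfig-class].
#' @return data.frame with one row per detection: \code{id} (assigned in
#'   raster order of the centroid), \code{x}, \code{y} (0-based sub-pixel
#'   coordinates), \code{intensity} (image value at the peak pixel).
#' @examples
#' sim <- simulateScene(simulationParams(seed = 3), day = 5)
#' det <- detectNuclei(nucleus(sim$scene), detectionConfig())
#' nrow(det)
#' @export
detectNuclei <- function(nucleusImg, cfg = detectionConfig()) {
  stopifnot(is(nucleusImg, "Image2D"), is(cfg, "DetectionConfig"))
  validObject(cfg)
  px <- nucleusImg@pixels
  h <- nrow(px); w <- ncol(px)
  resp <- blobResponse(px, cfg@sigmaPx)
  mx <- max(resp)
  empty <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      intensity = numeric(0))
  # a constant image has zero blob response up to FFT round-off; the floor
  # scales with the image so detection stays intensity-scale invariant
  if (mx <= 1e-6 * max(px)) return(empty)
  thr <- cfg@relThreshold * mx

  # local maxima within a (2k+1)^2 window via grayscale dilation
  k <- max(1L, floor(cfg@minSeparationPx / 2))
  brush <- matrix(1L, 2L * k + 1L, 2L * k + 1L)
  localMax <- fromEB(EBImage::dilate(asEB(resp), brush))
  cand <- which(resp >= thr & resp >= localMax - 1e-12, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)

  # greedy minimum-separation suppression, strongest first; ties broken by
  # raster order for determinism
  vals <- resp[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  ky <- numeric(0); kx <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    cy <- cand[i, 1]; cx <- cand[i, 2]
    if (length(kx) == 0 ||
        min((kx - cx)^2 + (ky - cy)^2) >= cfg@minSeparationPx^2) {
      keep[i] <- TRUE
      kx <- c(kx, cx); ky <- c(ky, cy)
    }
  }
  cand <- cand[keep, , drop = FALSE]

  # sub-pixel refinement: 1-D parabola through the peak and its neighbors
  refine <- function(m, r, c, along) {
    if (along == "x") {
      if (c <= 1 || c >= ncol(m)) return(0)
      f0 <- m[r, c - 1]; f1 <- m[r, c]; f2 <- m[r, c + 1]
    } else {
      if (r <= 1 || r >= nrow(m)) return(0)
      f0 <- m[r - 1, c]; f1 <- m[r, c]; f2 <- m[r + 1, c]
    }
    den <- f0 - 2 * f1 + f2
    if (den >= 0) return(0)
    max(-0.5, min(0.5, 0.5 * (f0 - f2) / den))
  }
  xs <- ys <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    xs[i] <- (c - 1L) + refine(resp, r, c, "x")
    ys[i] <- (r - 1L) + refine(resp, r, c, "y")
  }

  m <- cfg@borderMarginPx
  inb <- xs >= m & xs <= (w - 1 - m) & ys >= m & ys <= (h - 1 - m)
  xs <- xs[inb]; ys <- ys[inb]
  peaks <- cand[inb, , drop = FALSE]
  if (length(xs) == 0) return(empty)

  ord <- order(round(ys), round(xs))
  data.frame(id = seq_along(xs),
             x = xs[ord], y = ys[ord],
             intensity = px[peaks[ord, , drop = FALSE]])
}

#' Match detections to ground-truth nuclei
#'
#' One-to-one greedy nearest-neighbor matching under a distance cap: all
#' detection-truth pairs within \code{maxDistPx} are sorted by distance
#' (ties broken by lower truth id, then lower detection id) and accepted
#' greedily. Recall is TP/(TP+FN) and precision TP/(TP+FP); with no
#' detections precision is reported as 1 by convention and flagged via
#' \code{precisionDefined = FALSE}.
#'
#' @param detections data.frame with columns \code{x}, \code{y} (and
#'   optionally \code{id}) as returned by [detectNuclei()].
#' @param truthNuclei data.frame with columns \code{id}, \code{x}, \code{y}
#'   (e.g. \code{trueNuclei(groundTruth)}).
#' @param maxDistPx maximum matching distance (> 0).
#' @return list: \code{truePos}, \code{falsePos}, \code{falseNeg},
#'   \code{recall}, \code{precision}, \code{precisionDefined},
#'   \code{matches} (data.frame det_id / truth_id / dist).
#' @export
matchDetections <- function(detections, truthNuclei, maxDistPx = 3) {
  if (maxDistPx <= 0) stopValidation("maxDistPx must be > 0")
  nd <- nrow(detections); nt <- nrow(truthNuclei)
  detIds <- if ("id" %in% names(detections)) detections$id else seq_len(nd)
  truthIds <- if ("id" %in% names(truthNuclei)) truthNuclei$id
              else seq_len(nt)
  matches <- data.frame(det_id = integer(0), truth_id = integer(0),
                        dist = numeric(0))
  if (nd > 0 && nt > 0) {
    dd <- outer(detections$x, truthNuclei$x, "-")^2 +
      outer(detections$y, truthNuclei$y, "-")^2
    pairs <- which(dd <= maxDistPx^2, arr.ind = TRUE)
    if (nrow(pairs) > 0) {
      dist <- sqrt(dd[pairs])
      ord <- order(dist, truthIds[pairs[, 2]], detIds[pairs[, 1]])
      usedD <- logical(nd); usedT <- logical(nt)
      for (i in ord) {
        di <- pairs[i, 1]; ti <- pairs[i, 2]
        if (usedD[di] || usedT[ti]) next
        usedD[di] <- TRUE; usedT[ti] <- TRUE
        matches <- rbind(matches, data.frame(
          det_id = detIds[di], truth_id = truthIds[ti], dist = dist[i]))
      }
    }
  }
  tp <- nrow(matches)
  fp <- nd - tp
  fn <- nt - tp
  list(truePos = tp, falsePos = fp, falseNeg = fn,
       recall = if (nt > 0) tp / nt else 1,
       precision = if (nd > 0) tp / nd else 1,
       precisionDefined = nd > 0,
       matches = matches)
}
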