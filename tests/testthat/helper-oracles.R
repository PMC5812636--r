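# Independent oracles and fixture builders used across the suite. These
# deliberately recompute quantities by brute force (per-pixel scans, direct
# convolution) so they share no code path with the package internals they
# certify.

# Brute-force fusion index: for every labeled mask, scan its pixel list and
# count nuclei whose rounded centroid pixel appears in it; apply the >= 3
# rule. No use of FiberSet/assignNuclei internals.
oracleFusionIndex <- function(nuclei, labelMatrix, minNuclei = 3) {
  labs <- setdiff(sort(unique(as.vector(labelMatrix))), 0L)
  fused <- 0L
  for (lab in labs) {
    maskPx <- which(labelMatrix == lab, arr.ind = TRUE)
    count <- 0L
    for (i in seq_len(nrow(nuclei))) {
      r <- round(nuclei$y[i]) + 1L
      c <- round(nuclei$x[i]) + 1L
      if (any(maskPx[, 1] == r & maskPx[, 2] == c)) count <- count + 1L
    }
    if (count >= minNuclei) fused <- fused + count
  }
  100 * fused / nrow(nuclei)
}

# Brute-force nucleus-to-region assignment (exhaustive containment check),
# returns the region label per nucleus (0 = unassigned).
oracleAssign <- function(nuclei, labelMatrix) {
  out <- integer(nrow(nuclei))
  for (i in seq_len(nrow(nuclei))) {
    r <- round(nuclei$y[i]) + 1L
    c <- round(nuclei$x[i]) + 1L
    out[i] <- labelMatrix[r, c]
  }
  out
}

# Random ground-truth scene built directly from geometry (no rendering):
# disjoint axis-aligned rectangles as "fibers" plus point nuclei, some
# inside masks, some on background.
randomTruthScene <- function(seed, maxSide = 160L, maxNuclei = 60L,
                             maxFibers = 10L) {
  set.seed(seed)
  h <- sample(64:maxSide, 1)
  w <- sample(64:maxSide, 1)
  labels <- matrix(0L, h, w)
  nFib <- sample(0:maxFibers, 1)
  placed <- 0L
  for (k in seq_len(nFib)) {
    for (try in 1:20) {
      rh <- sample(4:12, 1); rw <- sample(10:40, 1)
      r0 <- sample(seq_len(h - rh), 1); c0 <- sample(seq_len(w - rw), 1)
      block <- labels[r0:(r0 + rh - 1), c0:(c0 + rw - 1)]
      if (all(block == 0L)) {
        labels[r0:(r0 + rh - 1), c0:(c0 + rw - 1)] <- placed + 1L
        placed <- placed + 1L
        break
      }
    }
  }
  n <- sample(5:maxNuclei, 1)
  nuclei <- data.frame(
    id = seq_len(n),
    x = runif(n, 0, w - 1),
    y = runif(n, 0, h - 1))
  list(labels = labels, nuclei = nuclei, width = w, height = h)
}

# Wrap a labeled matrix as a FiberSet (shape descriptors are filled with
# placeholder axes; only areas matter for fusion accounting).
fiberSetFromLabels <- function(labels) {
  labs <- setdiff(sort(unique(as.vector(labels))), 0L)
  regions <- data.frame(
    label = labs,
    area_px = vapply(labs, function(l) sum(labels == l), integer(1)),
    major_axis_px = rep(1, length(labs)),
    minor_axis_px = rep(1, length(labs)),
    elongation = rep(1, length(labs)))
  new("FiberSet", labels = labels, regions = regions,
      nucleusIds = rep(list(integer(0)), length(labs)))
}

# Direct (non-FFT) convolution of an image with the scale-matched blob
# kernel, replicate boundary, followed by brute-force peak enumeration:
# a peak is any pixel >= threshold that attains the maximum of its
# neighborhood box; peaks closer than minSep are merged greedily by
# descending response.
oracleBlobPeaks <- function(px, sigma, relThreshold, minSep) {
  r <- ceiling(3.5 * sigma)
  xs <- -r:r
  k <- outer(xs, xs, function(x, y) {
    rr <- x^2 + y^2
    -(rr - 2 * sigma^2) / sigma^2 * exp(-rr / (2 * sigma^2))
  })
  k <- k - mean(k)
  h <- nrow(px); w <- ncol(px)
  padIdx <- function(i, n) pmin(pmax(i, 1L), n)
  resp <- matrix(0, h, w)
  for (i in seq_len(h)) {
    rows <- padIdx(i + (-r:r), h)
    for (j in seq_len(w)) {
      cols <- padIdx(j + (-r:r), w)
      resp[i, j] <- sum(px[rows, cols] * k)
    }
  }
  thr <- relThreshold * max(resp)
  half <- max(1L, floor(minSep / 2))
  peaks <- NULL
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (resp[i, j] < thr) next
      nb <- resp[padIdx(i + (-half:half), h), padIdx(j + (-half:half), w)]
      if (resp[i, j] >= max(nb)) peaks <- rbind(peaks, c(i, j, resp[i, j]))
    }
  }
  if (is.null(peaks)) return(matrix(numeric(0), 0, 2))
  peaks <- peaks[order(-peaks[, 3]), , drop = FALSE]
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, 1:2]
    if (nrow(kept) == 0 ||
        min((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2) >= minSep^2)
      kept <- rbind(kept, p)
  }
  kept  # (row, col), 1-based
}

# Synthetic nucleus-channel image: Gaussian spots at given 0-based centers
# over a flat background, no noise.
spotImage <- function(w, h, centers, amp = 3000, sigma = 2, bg = 100,
                      bitDepth = 16L) {
  px <- matrix(bg, h, w)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    for (r in seq_len(h)) for (c in seq_len(w)) {
      d2 <- (c - 1 - cx)^2 + (r - 1 - cy)^2
      if (d2 < (6 * sigma)^2)
        px[r, c] <- px[r, c] + amp * exp(-d2 / (2 * sigma^2))
    }
  }
  Image2D(pmin(px, 2^bitDepth - 1), bitDepth, "nucleus")
}

# Tiny simulation parameter set for fast tests.
smallParams <- function(seed = 1L, ...) {
  simulationParams(width = 256L, height = 256L, nNucleiDay0 = 20L,
                   plateauNuclei = 60L, seed = seed, ...)
}

# TimeCourse fixture from a vector of replicate values on given days.
tcFixture <- function(cond, days, valuesByDay, nuclei = 100) {
  rows <- do.call(rbind, lapply(seq_along(days), function(i) {
    v <- valuesByDay[[i]]
    data.frame(day = days[i], well_id = paste0("W", seq_along(v)),
               fusion_index_pct = v, total_nuclei = nuclei,
               stringsAsFactors = FALSE)
  }))
  new("TimeCourse", condition = cond, days = as.integer(days),
      values = rows, missingDays = integer(0))
}
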