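# Synthetic double-labeled myoblast scenes with exact ground truth.
#
# A scene is built in three stages: (1) dynamics -- nuclei count grows
# geometrically to a plateau and the fused fraction follows saturating
# first-order kinetics modulated by the drug schedule; (2) geometry --
# fused nuclei are grouped into capsule-shaped fibers placed without
# overlap, the rest become round mononucleated cells; (3) rendering --
# Gaussian nucleus spots and filled cytoplasm bodies over an
# autofluorescent background, with Poisson shot noise plus Gaussian read
# noise applied last.

#' Fused-fraction trajectory under an exposure schedule
#'
#' The fused fraction f follows df/dt = fusionRate * effect(t) * (fMax - f)
#' with f = 0 until differentiation starts, where effect(t) = drugEffect on
#' drug days and 1 otherwise. Each one-day step is integrated exactly
#' (piecewise-constant effect), so the trajectory is monotone
#' non-decreasing and saturates at fMax.
#'
#' @param params a [SimulationParams-class].
#' @param schedule an [ExposureSchedule-class].
#' @param days integer days at which to report f (ascending).
#' @return data.frame with columns \code{day} and \code{fused_fraction}.
#' @examples
#' p <- simulationParams()
#' fusedFractionCourse(p, exposureSchedule("ND"), 0:10)
#' @export
fusedFractionCourse <- function(params, schedule, days) {
  stopifnot(is(params, "SimulationParams"), is(schedule, "ExposureSchedule"))
  if (is.unsorted(days)) stopValidation("days must be sorted ascending")
  if (any(days < 0)) stopValidation("days must be >= 0")
  start <- schedule@differentiationStartDay
  maxDay <- max(days)
  f <- numeric(maxDay + 1L)  # f[d + 1] = fused fraction at day d
  for (d in seq_len(maxDay)) {
    dPrev <- d - 1L
    if (dPrev < start) { f[d + 1L] <- 0; next }
    eff <- if (dPrev %in% schedule@drugDays) params@drugEffect else 1
    f[d + 1L] <- params@fMax -
      (params@fMax - f[d]) * exp(-params@fusionRate * eff)
  }
  data.frame(day = as.integer(days), fused_fraction = f[days + 1L])
}

#' Nuclei count trajectory (geometric growth to a plateau)
#'
#' @param params a [SimulationParams-class].
#' @param days integer days.
#' @return integer vector of nuclei counts per day.
#' @export
nucleiCountCourse <- function(params, days) {
  as.integer(round(pmin(params@plateauNuclei,
                        params@nNucleiDay0 * params@growthRate^days)))
}

# distance between two 2-D segments (used for overlap rejection)
segSegDist <- function(p1, q1, p2, q2) {
  ptSeg <- function(p, a, b) {
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
    sqrt(sum((p - (a + t * ab))^2))
  }
  segInt <- function(a, b, c, d) {
    ccw <- function(p, q, r) (q[1]-p[1])*(r[2]-p[2]) - (q[2]-p[2])*(r[1]-p[1])
    d1 <- ccw(c, d, a); d2 <- ccw(c, d, b)
    d3 <- ccw(a, b, c); d4 <- ccw(a, b, d)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (segInt(p1, q1, p2, q2)) return(0)
  min(ptSeg(p1, p2, q2), ptSeg(q1, p2, q2), ptSeg(p2, p1, q1),
      ptSeg(q2, p1, q1))
}

# paint a capsule (segment of half-length hl, radius rad around (cx, cy)
# at angle theta) into a labeled matrix; returns the updated matrix
paintCapsule <- function(labels, cx, cy, theta, hl, rad, label) {
  h <- nrow(labels); w <- ncol(labels)
  ux <- cos(theta); uy <- sin(theta)
  ex <- abs(ux) * hl + rad + 1; ey <- abs(uy) * hl + rad + 1
  x0 <- max(0L, floor(cx - ex)); x1 <- min(w - 1L, ceiling(cx + ex))
  y0 <- max(0L, floor(cy - ey)); y1 <- min(h - 1L, ceiling(cy + ey))
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  gy <- matrix(ys, length(ys), length(xs))
  rx <- gx - cx; ry <- gy - cy
  t <- pmax(-hl, pmin(hl, rx * ux + ry * uy))
  d2 <- (rx - t * ux)^2 + (ry - t * uy)^2
  sub <- labels[ys + 1L, xs + 1L, drop = FALSE]
  sub[d2 <= rad^2] <- label
  labels[ys + 1L, xs + 1L] <- sub
  labels
}

paintDisc <- function(mask, cx, cy, rad) {
  paintCapsule(mask, cx, cy, 0, 0, rad, 1L)
}

# additive Gaussian spot, local window only
addSpot <- function(img, cx, cy, amp, sigma) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * sigma)
  x0 <- max(0L, floor(cx - r)); x1 <- min(w - 1L, ceiling(cx + r))
  y0 <- max(0L, floor(cy - r)); y1 <- min(h - 1L, ceiling(cy + r))
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  gy <- matrix(ys, length(ys), length(xs))
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] +
    amp * exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * sigma^2))
  img
}

# split nFused nuclei into fiber sizes >= 3 within the configured range
fiberSizes <- function(nFused, range) {
  sizes <- integer(0)
  rem <- nFused
  while (rem >= 3L) {
    s <- if (range[1] == range[2]) range[1]
         else sample(seq(range[1], range[2]), 1L)
    s <- min(s, rem)
    if (rem - s < 3L) s <- rem  # absorb a remainder of 1-2 nuclei
    sizes <- c(sizes, s)
    rem <- rem - s
  }
  sizes
}

#' Simulate one double-labeled scene with ground truth
#'
#' Renders the nucleus channel as one Gaussian spot per nucleus and the
#' cytoplasm channel as elongated capsule fibers (length proportional to
#' their nuclei count) plus round mononucleated cell bodies, over an
#' autofluorescent background; Poisson shot noise and Gaussian read noise
#' are applied last. Identical parameters and seed give bit-identical
#' output.
#'
#' @param params a [SimulationParams-class].
#' @param day imaging day (>= 0); sets the nuclei count and, unless
#'   \code{fusedFraction} is given, the fused fraction via drug-free
#'   kinetics from \code{differentiationStartDay}.
#' @param fusedFraction optional override of the fused fraction in [0, 1]
#'   (used by [simulateTimecourse()] to impose schedule dynamics).
#' @param differentiationStartDay day fusion can begin (default 3).
#' @param streamSeed optional sub-stream seed (defaults to a hash of the
#'   master seed and the day).
#' @param wellFactor multiplier on the fused fraction's approach used to
#'   emulate well-to-well biological variability (default 1).
#' @return list with elements \code{scene} ([Scene-class]) and
#'   \code{groundTruth} ([GroundTruth-class]).
#' @examples
#' sim <- simulateScene(simulationParams(seed = 7), day = 7)
#' trueFusionIndexPct(sim$groundTruth)
#' @export
simulateScene <- function(params, day, fusedFraction = NULL,
                          differentiationStartDay = 3L, streamSeed = NULL,
                          wellFactor = 1) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  if (day < 0) stopValidation("day must be >= 0")
  if (is.null(fusedFraction)) {
    el <- max(0, day - differentiationStartDay)
    fusedFraction <- params@fMax * (1 - exp(-params@fusionRate * el))
  }
  if (fusedFraction < 0 || fusedFraction > 1)
    stopValidation("fusedFraction must lie in [0, 1]")
  if (is.null(streamSeed)) streamSeed <- deriveSeed(params@seed, "scene", day)

  withSeed(streamSeed, {
    w <- params@width; h <- params@height
    rad <- params@nucleusRadiusPx
    spotSigma <- 0.6 * rad
    fw <- params@fiberWidthPx
    spacing <- params@nucleusSpacingPx
    cellR <- 1.8 * rad
    margin <- ceiling(max(10, 3 * rad + 2))
    minNucSep <- 3 * rad

    n <- nucleiCountCourse(params, day)
    nFused <- round(fusedFraction * n)
    if (nFused == 1L || nFused == 2L) nFused <- 0L  # cannot form a >=3 fiber
    sizes <- sort(fiberSizes(nFused, params@fiberNucleiRange),
                  decreasing = TRUE)
    nMono <- n - sum(sizes)
    nPairs <- floor(params@twoNucleusFiberRate * nMono / 2)
    allSizes <- c(sizes, rep(2L, nPairs))
    nMono <- nMono - 2L * nPairs

    fiberMasks <- matrix(0L, h, w)
    segs <- list()   # placed fiber segments: (p, q, rad)
    nucX <- nucY <- numeric(0)
    nucFiber <- integer(0)
    nextLabel <- 1L

    for (k in allSizes) {
      hl <- k * spacing / 2  # segment half-length
      placed <- FALSE
      for (try in 1:80) {
        theta <- runif(1, 0, pi)
        ex <- abs(cos(theta)) * hl + fw / 2
        ey <- abs(sin(theta)) * hl + fw / 2
        if (w - 1 - 2 * (margin + ex) <= 0 || h - 1 - 2 * (margin + ey) <= 0)
          stopValidation("fiber of %d nuclei does not fit the scene", k)
        cx <- runif(1, margin + ex, w - 1 - margin - ex)
        cy <- runif(1, margin + ey, h - 1 - margin - ey)
        p <- c(cx - cos(theta) * hl, cy - sin(theta) * hl)
        q <- c(cx + cos(theta) * hl, cy + sin(theta) * hl)
        ok <- TRUE
        for (s in segs) {
          # keep an 8 px edge gap so distinct myotubes stay resolvable
          # after rendering blur and morphological cleanup
          if (segSegDist(p, q, s$p, s$q) < fw + 8) { ok <- FALSE; break }
        }
        if (!ok) next
        fiberMasks <- paintCapsule(fiberMasks, cx, cy, theta, hl, fw / 2,
                                   nextLabel)
        segs[[length(segs) + 1L]] <- list(p = p, q = q)
        # nuclei evenly along the axis, small jitter, clamped inside
        off <- (seq_len(k) - (k + 1) / 2) * spacing
        ja <- runif(k, -0.5, 0.5)  # axial jitter
        jp <- runif(k, -0.5, 0.5)  # perpendicular jitter
        nx <- cx + cos(theta) * (off + ja) - sin(theta) * jp
        ny <- cy + sin(theta) * (off + ja) + cos(theta) * jp
        nucX <- c(nucX, nx); nucY <- c(nucY, ny)
        nucFiber <- c(nucFiber, rep(nextLabel, k))
        nextLabel <- nextLabel + 1L
        placed <- TRUE
        break
      }
      if (!placed) next  # retry cap hit: drop this fiber, truth stays exact
    }

    cellMask <- matrix(0L, h, w)
    cellCenters <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nMono)) {
      for (try in 1:100) {
        cx <- runif(1, margin, w - 1 - margin)
        cy <- runif(1, margin, h - 1 - margin)
        ok <- TRUE
        for (s in segs) {
          if (segSegDist(c(cx, cy), c(cx, cy), s$p, s$q) <
              fw / 2 + cellR + 8) { ok <- FALSE; break }
        }
        if (ok && nrow(cellCenters) > 0) {
          d <- sqrt((cellCenters[, 1] - cx)^2 + (cellCenters[, 2] - cy)^2)
          # 6 px edge clearance keeps neighboring cells resolvable, so
          # aligned touching cells cannot mimic an elongated fiber
          if (min(d) < max(2 * cellR + 6, minNucSep)) ok <- FALSE
        }
        if (ok && length(nucX) > 0) {
          d <- sqrt((nucX - cx)^2 + (nucY - cy)^2)
          if (min(d) < minNucSep) ok <- FALSE
        }
        if (!ok) next
        cellMask <- paintDisc(cellMask, cx, cy, cellR)
        cellCenters <- rbind(cellCenters, c(cx, cy))
        nucX <- c(nucX, cx + runif(1, -0.8, 0.8))
        nucY <- c(nucY, cy + runif(1, -0.8, 0.8))
        nucFiber <- c(nucFiber, NA_integer_)
        break
      }
    }

    # ground truth before rendering noise
    nNuc <- length(nucX)
    ids <- seq_len(nNuc)
    memb <- table(nucFiber[!is.na(nucFiber)])
    fused <- if (length(memb)) sum(memb[memb >= 3]) else 0L
    truth <- new("GroundTruth",
                 nuclei = data.frame(id = ids, x = nucX, y = nucY,
                                     fiber = nucFiber),
                 fiberMasks = fiberMasks,
                 trueFusionIndexPct =
                   if (nNuc > 0) 100 * fused / nNuc else 0,
                 trueNucleiCount = as.integer(nNuc))

    # rendering
    bg <- params@autofluorescenceLevel
    gains <- params@channelGains
    body <- (fiberMasks > 0L) | (cellMask > 0L)
    soft <- fromEB(EBImage::gblur(asEB(body * 1.0), sigma = 1))
    cleanCyto <- bg + gains[["cytoplasm"]] * pmax(soft, 0)
    cleanNuc <- matrix(bg, h, w)
    for (i in ids)
      cleanNuc <- addSpot(cleanNuc, nucX[i], nucY[i], gains[["nucleus"]],
                          spotSigma)
    maxv <- 2^params@bitDepth - 1
    noisy <- function(clean) {
      v <- rpois(length(clean), pmax(clean, 0)) +
        rnorm(length(clean), 0, params@noiseGaussianSd)
      matrix(pmin(maxv, pmax(0, round(v))), h, w)
    }
    scene <- Scene(
      Image2D(noisy(cleanCyto), params@bitDepth, "cytoplasm"),
      Image2D(noisy(cleanNuc), params@bitDepth, "nucleus"),
      day = day)
    list(scene = scene, groundTruth = truth)
  })
}

#' Simulate a differentiation time course under a drug schedule
#'
#' Fused fractions follow [fusedFractionCourse()]; one scene is rendered
#' per requested day, each from its own seed sub-stream derived from the
#' master seed.
#'
#' @param params a [SimulationParams-class].
#' @param schedule an [ExposureSchedule-class].
#' @param days ascending integer days to image.
#' @param wellTag extra string mixed into the per-day sub-stream seeds (so
#'   wells get independent scenes).
#' @param rateFactor multiplier applied to \code{fusionRate} for this run
#'   (well-level biological variability; default 1).
#' @return a list with one element per day, each a list(scene, groundTruth);
#'   the fused-fraction trajectory is attached as attribute
#'   \code{"fusedFraction"}.
#' @export
simulateTimecourse <- function(params, schedule, days, wellTag = "W1",
                               rateFactor = 1) {
  if (is.unsorted(days)) stopValidation("days must be sorted ascending")
  p <- params
  p@fusionRate <- params@fusionRate * rateFactor
  course <- fusedFractionCourse(p, schedule, days)
  out <- vector("list", length(days))
  for (i in seq_along(days)) {
    out[[i]] <- simulateScene(
      params, days[i], fusedFraction = course$fused_fraction[i],
      differentiationStartDay = schedule@differentiationStartDay,
      streamSeed = deriveSeed(params@seed, wellTag, "day", days[i]))
  }
  names(out) <- paste0("day", days)
  attr(out, "fusedFraction") <- course
  out
}

#' Simulate a multi-condition plate experiment
#'
#' Generates \code{nWells} replicate wells per condition over the given
#' days, with per-well seeds derived deterministically from the master seed
#' (adding wells or conditions never perturbs existing ones). Well-to-well
#' biological variability is emulated by a lognormal factor on the fusion
#' rate with coefficient of variation \code{wellCv}.
#'
#' @param conditions named list; each element is a list with components
#'   \code{params} ([SimulationParams-class]) and \code{schedule}
#'   ([ExposureSchedule-class]). Names must be unique.
#' @param nWells replicate wells per condition (>= 1).
#' @param nFields fields imaged per well.
#' @param days ascending integer imaging days.
#' @param seed master seed for the plate.
#' @param outDir optional directory; when given, every scene is written as
#'   a bundle ([writeSceneBundle()]) and a \code{manifest.json} is emitted.
#' @param wellCv coefficient of variation of the per-well fusion-rate
#'   factor (default 0.08).
#' @return list with \code{manifest} (data.frame: scene_id, condition,
#'   well_id, day, field_index, path) and \code{scenes} (named list of
#'   list(scene, groundTruth)).
#' @export
simulatePlate <- function(conditions, nWells = 3L, nFields = 1L, days,
                          seed = 1L, outDir = NULL, wellCv = 0.08) {
  if (is.null(names(conditions)) || anyDuplicated(names(conditions)))
    stopValidation("conditions must be uniquely named")
  if (nWells < 1L) stopValidation("nWells must be >= 1")
  if (is.unsorted(days)) stopValidation("days must be sorted ascending")

  manifest <- NULL
  scenes <- list()
  for (cond in names(conditions)) {
    spec <- conditions[[cond]]
    stopifnot(is(spec$params, "SimulationParams"),
              is(spec$schedule, "ExposureSchedule"))
    for (wi in seq_len(nWells)) {
      wellName <- sprintf("%s-W%d", cond, wi)
      rateFactor <- if (wellCv > 0) {
        sdl <- sqrt(log(1 + wellCv^2))
        withSeed(deriveSeed(seed, cond, "wellfactor", wi),
                 exp(rnorm(1, -sdl^2 / 2, sdl)))
      } else 1
      p <- spec$params
      p@fusionRate <- p@fusionRate * rateFactor
      course <- fusedFractionCourse(p, spec$schedule, days)
      for (fi in seq_len(nFields) - 1L) {
        for (di in seq_along(days)) {
          d <- days[di]
          sid <- sprintf("%s_W%d_D%d_F%d", cond, wi, d, fi)
          sim <- simulateScene(
            spec$params, d, fusedFraction = course$fused_fraction[di],
            differentiationStartDay = spec$schedule@differentiationStartDay,
            streamSeed = deriveSeed(seed, cond, wi, d, fi))
          sc <- sim$scene
          sc@wellId <- wellName
          sc@condition <- cond
          sc@fieldIndex <- fi
          sim$scene <- sc
          scenes[[sid]] <- sim
          path <- NA_character_
          if (!is.null(outDir)) {
            path <- file.path(outDir, sid)
            writeSceneBundle(sc, path, sim$groundTruth)
          }
          manifest <- rbind(manifest, data.frame(
            scene_id = sid, condition = cond, well_id = wellName,
            day = d, field_index = fi, path = path,
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (!is.null(outDir))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
  list(manifest = manifest, scenes = scenes)
}
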