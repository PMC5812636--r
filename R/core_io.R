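# Readers/writers: grayscale TIFF images, scene bundles (two TIFFs + JSON
# sidecar), and per-scene result tables (CSV).

#' Read a single-plane grayscale TIFF as an Image2D
#'
#' Intensities are read bit-exactly (no rescaling). Multi-plane and RGB
#' files, and bit depths other than 8 or 16, are rejected.
#'
#' @param path TIFF file path.
#' @param channel \code{"cytoplasm"} or \code{"nucleus"}.
#' @param pixelSizeUm micrometers per pixel to attach (metadata only).
#' @return an [Image2D-class].
#' @export
readImage2D <- function(path, channel = c("cytoplasm", "nucleus"),
                        pixelSizeUm = 1.0) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stopIO("cannot read image: '%s' does not exist", path)
  planes <- tiff::readTIFF(path, as.is = TRUE, all = TRUE, info = TRUE)
  if (length(planes) != 1L)
    stopFormat("'%s' holds %d planes; expected a single-plane grayscale TIFF",
               path, length(planes))
  px <- planes[[1]]
  if (length(dim(px)) != 2L)
    stopFormat("'%s' is not single-channel grayscale (dims: %s)",
               path, paste(dim(px), collapse = "x"))
  bits <- attr(px, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(px) > 255) 16L else 8L
  if (!(bits %in% c(8L, 16L)))
    stopFormat("'%s' has unsupported bit depth %d (only 8/16; not rescaling)",
               path, bits)
  Image2D(matrix(as.numeric(px), nrow(px), ncol(px)),
          bitDepth = bits, channel = channel, pixelSizeUm = pixelSizeUm)
}

#' Write an Image2D as a grayscale TIFF (bit-exact round trip)
#'
#' @param img an [Image2D-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeImage2D <- function(img, path) {
  stopifnot(is(img, "Image2D"))
  maxv <- 2^img@bitDepth - 1
  tiff::writeTIFF(img@pixels / maxv, path,
                  bits.per.sample = as.integer(img@bitDepth))
  invisible(path)
}

#' Read a paired-channel scene from two TIFF files
#'
#' @param cytoPath,nucPath paths to the cytoplasm and nucleus channel TIFFs
#'   (equal dimensions required).
#' @param wellId,condition scene metadata.
#' @param day imaging day (integer >= 0).
#' @param fieldIndex 0-based field index.
#' @param pixelSizeUm micrometers per pixel.
#' @return a [Scene-class].
#' @examples
#' \dontrun{
#' sc <- readScene("A1_cyto.tif", "A1_nuc.tif", wellId = "A1", day = 3)
#' }
#' @export
readScene <- function(cytoPath, nucPath, wellId = "A1", day = 0L,
                      condition = "ND", fieldIndex = 0L, pixelSizeUm = 1.0) {
  cyto <- readImage2D(cytoPath, "cytoplasm", pixelSizeUm)
  nuc <- readImage2D(nucPath, "nucleus", pixelSizeUm)
  if (!identical(dim(cyto@pixels), dim(nuc@pixels)))
    stopDimension(
      "channel dimensions differ: '%s' is %s but '%s' is %s",
      cytoPath, paste(rev(dim(cyto@pixels)), collapse = "x"),
      nucPath, paste(rev(dim(nuc@pixels)), collapse = "x"))
  Scene(cyto, nuc, wellId = wellId, day = day, condition = condition,
        fieldIndex = fieldIndex)
}

#' Write a scene bundle (directory of two TIFFs + JSON sidecar)
#'
#' The bundle layout is inspectable with standard viewers: cytoplasm.tif,
#' nucleus.tif, scene.json (metadata), and, when ground truth is supplied,
#' truth.json plus a labeled fiber_masks.tif.
#'
#' @param scene a [Scene-class].
#' @param dir output directory (created if needed).
#' @param groundTruth optional [GroundTruth-class] to store alongside.
#' @return \code{dir}, invisibly.
#' @export
writeSceneBundle <- function(scene, dir, groundTruth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeImage2D(scene@cytoplasm, file.path(dir, "cytoplasm.tif"))
  writeImage2D(scene@nucleus, file.path(dir, "nucleus.tif"))
  meta <- list(well_id = scene@wellId, day = scene@day,
               condition = scene@condition, field_index = scene@fieldIndex,
               bit_depth = scene@cytoplasm@bitDepth,
               pixel_size_um = scene@cytoplasm@pixelSizeUm,
               has_ground_truth = !is.null(groundTruth))
  jsonlite::write_json(meta, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(groundTruth)) {
    stopifnot(is(groundTruth, "GroundTruth"))
    tr <- list(nuclei = groundTruth@nuclei,
               true_fusion_index_pct = groundTruth@trueFusionIndexPct,
               true_nuclei_count = groundTruth@trueNucleiCount)
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    # labeled mask as 16-bit TIFF; label count is far below 65535
    tiff::writeTIFF(groundTruth@fiberMasks / 65535,
                    file.path(dir, "fiber_masks.tif"), bits.per.sample = 16L)
  }
  invisible(dir)
}

#' Read a scene bundle written by [writeSceneBundle()]
#'
#' @param dir bundle directory.
#' @return a list with elements \code{scene} ([Scene-class]) and
#'   \code{groundTruth} ([GroundTruth-class] or \code{NULL}).
#' @export
readSceneBundle <- function(dir) {
  metaPath <- file.path(dir, "scene.json")
  if (!file.exists(metaPath))
    stopIO("'%s' is not a scene bundle (missing scene.json)", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  scene <- readScene(file.path(dir, "cytoplasm.tif"),
                     file.path(dir, "nucleus.tif"),
                     wellId = meta$well_id, day = meta$day,
                     condition = meta$condition,
                     fieldIndex = meta$field_index,
                     pixelSizeUm = meta$pixel_size_um)
  gt <- NULL
  if (isTRUE(meta$has_ground_truth)) {
    tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
    masks <- tiff::readTIFF(file.path(dir, "fiber_masks.tif"), as.is = TRUE)
    nuc <- as.data.frame(tr$nuclei)
    nuc$fiber <- as.integer(nuc$fiber)
    gt <- new("GroundTruth", nuclei = nuc,
              fiberMasks = matrix(as.integer(masks), nrow(masks), ncol(masks)),
              trueFusionIndexPct = tr$true_fusion_index_pct,
              trueNucleiCount = as.integer(tr$true_nuclei_count))
  }
  list(scene = scene, groundTruth = gt)
}

resultColumns <- c("well_id", "day", "condition", "field_index",
                   "total_nuclei", "fused_nuclei", "fusion_index_pct",
                   "n_fused_fibers", "mean_fiber_area_px")

#' Tabulate per-scene fusion results
#'
#' @param results list of [FusionResult-class] objects.
#' @param metadata data.frame with one row per result: \code{well_id},
#'   \code{day}, \code{condition}, \code{field_index}.
#' @return a data.frame with one row per (well, day, field) and a fixed
#'   column order.
#' @export
resultsTable <- function(results, metadata) {
  if (length(results) == 0L)
    stopValidation("no results to tabulate (empty input)")
  if (nrow(metadata) != length(results))
    stopValidation("metadata must have one row per result (%d vs %d)",
                   nrow(metadata), length(results))
  data.frame(
    well_id = as.character(metadata$well_id),
    day = as.integer(metadata$day),
    condition = as.character(metadata$condition),
    field_index = as.integer(metadata$field_index),
    total_nuclei = vapply(results, totalNuclei, integer(1),
                          USE.NAMES = FALSE),
    fused_nuclei = vapply(results, fusedNuclei, integer(1),
                          USE.NAMES = FALSE),
    fusion_index_pct = vapply(results, fusionIndexPct, numeric(1),
                              USE.NAMES = FALSE),
    n_fused_fibers = vapply(results, nFusedFibers, integer(1),
                            USE.NAMES = FALSE),
    mean_fiber_area_px = vapply(results, function(r) {
      if (length(r@fiberAreasPx)) mean(r@fiberAreasPx) else NA_real_
    }, numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Write / read a per-scene results table (CSV)
#'
#' Values are written at full double precision so that
#' \code{readResults(writeResults(x, f))} reproduces \code{x} exactly.
#'
#' @param tbl a results data.frame (from [resultsTable()] or with the same
#'   columns).
#' @param path CSV file path.
#' @return \code{path} invisibly (write) or the data.frame (read).
#' @export
writeResults <- function(tbl, path) {
  if (is.null(tbl) || nrow(tbl) == 0L)
    stopValidation("refusing to write an empty results table")
  missing <- setdiff(resultColumns, names(tbl))
  if (length(missing))
    stopValidation("results table lacks columns: %s",
                   paste(missing, collapse = ", "))
  write.csv(tbl[, resultColumns], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
  if (!file.exists(path)) stopIO("results file '%s' does not exist", path)
  read.csv(path, stringsAsFactors = FALSE)
}
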