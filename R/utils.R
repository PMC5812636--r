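# Internal helpers: classed conditions and coordinate conventions.
#
# Coordinate convention used throughout the package: 0-based, x = column,
# y = row, so a centroid (x, y) addresses matrix element [y + 1, x + 1].
# Masks are pixel-aligned logical/integer matrices in row (y) x column (x)
# orientation, matching what tiff::readTIFF() returns.

stopValidation <- function(msg, ..., class = character()) {
  stop(structure(
    class = c(class, "mfValidationError", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stopDimension <- function(msg, ...) {
  stopValidation(msg, ..., class = "mfDimensionError")
}

stopFormat <- function(msg, ...) {
  stopValidation(msg, ..., class = "mfFormatError")
}

# construct an S4 object, re-signalling validity failures as classed
# validation errors (so e.g. the CLI can map them to exit code 2)
newValidated <- function(Class, ...) {
  tryCatch(new(Class, ...),
           error = function(e) stopValidation("%s", conditionMessage(e)))
}

stopIO <- function(msg, ...) {
  stop(structure(
    class = c("mfIOError", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# EBImage stores images x-major (first dimension = columns); the package
# stores pixels as [row, col]. All EBImage calls go through these two.
asEB <- function(m) EBImage::Image(t(m))
fromEB <- function(img) t(EBImage::imageData(img))

# Deterministic 31-bit hash for deriving independent sub-stream seeds from
# a master seed, so adding wells/days/fields never perturbs existing ones.
deriveSeed <- function(master, ...) {
  parts <- paste(c(master, ...), collapse = "\r")
  h <- as.double(master %% 2147483647L)
  for (b in utf8ToInt(parts)) h <- (h * 31 + b) %% 2147483629
  as.integer(h %% 2147483647)
}

# Evaluate expr with a local RNG state (restores the caller's stream).
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# First pixel of each label in raster order (row-major scan), used to make
# label numbering deterministic and viewer-friendly.
relabelRaster <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) return(labels)
  w <- ncol(labels)
  firstIdx <- vapply(ids, function(l) {
    hit <- which(labels == l, arr.ind = TRUE)
    min((hit[, 1] - 1L) * w + (hit[, 2] - 1L))
  }, numeric(1))
  ord <- ids[order(firstIdx)]
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (k in seq_along(ord)) out[labels == ord[k]] <- k
  out
}
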