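test_that("nucleus assignment follows rounded-centroid containment", {
  labels <- matrix(0L, 32, 32)
  labels[9:13, 9:13] <- 1L  # covers pixel (10, 10) in 0-based coords
  fib <- fiberSetFromLabels(labels)
  det <- data.frame(id = 1:2, x = c(10.4, 25.0), y = c(10.4, 25.0))
  out <- assignNuclei(det, fib)
  expect_identical(nucleusIds(out)[[1]], 1L)  # (10.4, 10.4) rounds inside
  expect_identical(sum(lengths(nucleusIds(out))), 1L)  # other unassigned
  bad <- data.frame(id = 1L, x = 40, y = 2)
  expect_error(assignNuclei(bad, fib), class = "mfValidationError")
})

test_that("assignment equals the exhaustive containment oracle", {
  for (s in 1:5) {
    sc <- randomTruthScene(seed = 100 + s, maxFibers = 5)
    fib <- fiberSetFromLabels(sc$labels)
    out <- assignNuclei(sc$nuclei, fib)
    oracle <- oracleAssign(sc$nuclei, sc$labels)
    got <- integer(nrow(sc$nuclei))
    for (k in seq_along(nucleusIds(out)))
      got[match(nucleusIds(out)[[k]], sc$nuclei$id)] <-
        fiberTable(out)$label[k]
    expect_identical(got, oracle)
  }
})

test_that("fusion index applies the >= 3 nuclei rule", {
  labels <- matrix(0L, 64, 64)
  labels[5:10, 5:40] <- 1L
  fib <- fiberSetFromLabels(labels)
  # 10 nuclei, 3 inside the fiber -> 30%
  det <- data.frame(id = 1:10,
                    x = c(10, 20, 30, seq(5, 50, length.out = 7)),
                    y = c(7, 7, 7, rep(55, 7)))
  fr <- fusionIndex(det, assignNuclei(det, fib))
  expect_equal(fusionIndexPct(fr), 30)
  expect_identical(nFusedFibers(fr), 1L)
  # exactly 2 nuclei in the fiber -> ambiguous, counts as zero
  det2 <- det[-3, ]
  fr2 <- fusionIndex(det2, assignNuclei(det2, fib))
  expect_equal(fusionIndexPct(fr2), 0)
  expect_identical(fusedNuclei(fr2), 0L)
  # no nuclei at all: undefined, must raise (not silently 0 or NaN)
  expect_error(fusionIndex(det[0, ], fib), class = "mfValidationError")
})

test_that("pipeline fusion index equals brute-force recomputation exactly", {
  for (s in 1:10) {
    sc <- randomTruthScene(seed = 200 + s)
    fib <- fiberSetFromLabels(sc$labels)
    fr <- fusionIndex(sc$nuclei, assignNuclei(sc$nuclei, fib))
    expect_identical(fusionIndexPct(fr),
                     oracleFusionIndex(sc$nuclei, sc$labels))
  }
})

test_that("fusion index is permutation-invariant and monotone", {
  sc <- randomTruthScene(seed = 300, maxFibers = 8)
  fib <- fiberSetFromLabels(sc$labels)
  fr <- fusionIndex(sc$nuclei, assignNuclei(sc$nuclei, fib))
  perm <- sc$nuclei[sample(nrow(sc$nuclei)), ]
  frP <- fusionIndex(perm, assignNuclei(perm, fib))
  expect_identical(fusionIndexPct(fr), fusionIndexPct(frP))
  expect_true(fusionIndexPct(fr) >= 0 && fusionIndexPct(fr) <= 100)
  if (fusedNuclei(fr) > 0) {
    # an extra background nucleus strictly dilutes the index
    bgPix <- which(sc$labels == 0L, arr.ind = TRUE)[1, ]
    extra <- rbind(sc$nuclei,
                   data.frame(id = max(sc$nuclei$id) + 1L,
                              x = bgPix[2] - 1, y = bgPix[1] - 1))
    frE <- fusionIndex(extra, assignNuclei(extra, fib))
    expect_lt(fusionIndexPct(frE), fusionIndexPct(fr))
  }
})

test_that("object contrast matches its closed form", {
  px <- matrix(50, 64, 64)
  px[20:29, 20:29] <- 200
  img <- Image2D(px, 16L, "cytoplasm")
  obj <- px == 200
  expect_equal(contrastValue(objectContrast(img, obj, !obj)), 3.0)
  # equal means -> zero contrast
  flat <- Image2D(matrix(80, 64, 64), 16L, "cytoplasm")
  expect_equal(contrastValue(objectContrast(flat, obj, !obj)), 0)
  # explicit pixel sets: object {100, 200}, background {40, 60}
  px2 <- matrix(1, 32, 32)
  px2[1, 1] <- 100; px2[1, 2] <- 200; px2[2, 1] <- 40; px2[2, 2] <- 60
  img2 <- Image2D(px2, 16L, "cytoplasm")
  cm <- objectContrast(img2, cbind(c(0, 1), c(0, 0)), cbind(c(0, 1), c(1, 1)))
  expect_equal(cm@meanObject, 150)
  expect_equal(cm@meanBackground, 50)
  expect_equal(contrastValue(cm), 2.0)
})

test_that("contrast rejects empty, overlapping and zero-background input", {
  px <- matrix(0, 32, 32); px[5, 5] <- 10
  img <- Image2D(px, 16L, "cytoplasm")
  obj <- px > 0
  expect_error(objectContrast(img, obj, obj), "overlap",
               class = "mfValidationError")
  expect_error(objectContrast(img, obj, !obj), "zero",
               class = "mfValidationError")
  none <- matrix(FALSE, 32, 32)
  expect_error(objectContrast(img, none, !obj), class = "mfValidationError")
})

test_that("contrast is scale-invariant but not shift-invariant", {
  set.seed(77)
  for (i in 1:10) {
    px <- matrix(runif(32 * 32, 10, 1000), 32, 32)
    img <- Image2D(px, 16L, "cytoplasm")
    obj <- matrix(FALSE, 32, 32); obj[1:8, 1:8] <- TRUE
    bg <- matrix(FALSE, 32, 32); bg[20:32, 20:32] <- TRUE
    c0 <- contrastValue(objectContrast(img, obj, bg))
    cScaled <- contrastValue(objectContrast(
      Image2D(px * 3.7, 16L, "cytoplasm"), obj, bg))
    cShifted <- contrastValue(objectContrast(
      Image2D(px + 500, 16L, "cytoplasm"), obj, bg))
    expect_equal(cScaled, c0, tolerance = 1e-12)
    expect_false(isTRUE(all.equal(cShifted, c0)))
  }
})

test_that("sceneMetrics composes the stages deterministically", {
  sim <- simulateScene(smallParams(seed = 18), day = 7)
  a <- sceneMetrics(sim$scene)
  b <- sceneMetrics(sim$scene)
  expect_identical(fusionIndexPct(a), fusionIndexPct(b))
  expect_identical(totalNuclei(a), totalNuclei(b))
  # an unfused culture reads ~0%
  sim0 <- simulateScene(smallParams(seed = 19, fMax = 0), day = 7)
  expect_lt(fusionIndexPct(sceneMetrics(sim0$scene)), 1)
  # stage name is attached to propagated errors
  blankNuc <- Scene(cytoplasm(sim$scene),
                    Image2D(matrix(0, 256, 256), 16L, "nucleus"))
  expect_error(sceneMetrics(blankNuc), "fusion_index")
})
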