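test_that("identical parameters and seed give bit-identical scenes", {
  p <- smallParams(seed = 9)
  a <- simulateScene(p, day = 6)
  b <- simulateScene(p, day = 6)
  expect_identical(pixels(cytoplasm(a$scene)), pixels(cytoplasm(b$scene)))
  expect_identical(pixels(nucleus(a$scene)), pixels(nucleus(b$scene)))
  expect_identical(trueNuclei(a$groundTruth), trueNuclei(b$groundTruth))
  # a different seed changes the scene
  c <- simulateScene(smallParams(seed = 10), day = 6)
  expect_false(identical(pixels(nucleus(a$scene)), pixels(nucleus(c$scene))))
})

test_that("fMax = 0 yields zero fusion at any day", {
  p <- smallParams(seed = 3, fMax = 0)
  sim <- simulateScene(p, day = 8)
  expect_identical(trueFusionIndexPct(sim$groundTruth), 0)
  # ambiguous dividing-cell pairs may exist, but nothing reaches 3 nuclei
  memb <- table(trueNuclei(sim$groundTruth)$fiber)
  expect_true(all(memb < 3))
  # with ambiguous pairs disabled too, every nucleus is mononucleated
  sim2 <- simulateScene(smallParams(seed = 3, fMax = 0,
                                    twoNucleusFiberRate = 0), day = 8)
  expect_true(all(is.na(trueNuclei(sim2$groundTruth)$fiber)))
  expect_identical(max(trueFiberMasks(sim2$groundTruth)), 0L)
})

test_that("a forced single 3-nucleus fiber among 12 nuclei gives 25%", {
  p <- simulationParams(width = 256L, height = 256L, nNucleiDay0 = 12L,
                        growthRate = 1, plateauNuclei = 12L,
                        twoNucleusFiberRate = 0, seed = 4L)
  sim <- simulateScene(p, day = 5, fusedFraction = 3 / 12)
  gt <- sim$groundTruth
  expect_identical(totalNuclei(gt), 12L)
  memb <- table(trueNuclei(gt)$fiber)
  expect_identical(as.integer(memb), 3L)
  expect_equal(trueFusionIndexPct(gt), 25.0)
})

test_that("ground-truth fusion index always matches the >= 3 rule", {
  for (s in 1:5) {
    sim <- simulateScene(smallParams(seed = s), day = sample(0:10, 1))
    gt <- sim$groundTruth
    nuc <- trueNuclei(gt)
    memb <- table(nuc$fiber[!is.na(nuc$fiber)])
    fused <- if (length(memb)) sum(memb[memb >= 3]) else 0
    expect_equal(trueFusionIndexPct(gt), 100 * fused / nrow(nuc))
    expect_true(validObject(gt))
  }
})

test_that("two-nucleus fibers are rendered but never counted as fused", {
  p <- smallParams(seed = 7, twoNucleusFiberRate = 0.5)
  sim <- simulateScene(p, day = 7)
  nuc <- trueNuclei(sim$groundTruth)
  memb <- table(nuc$fiber[!is.na(nuc$fiber)])
  expect_true(any(memb == 2))  # ambiguous pairs exist at this rate
  fused <- sum(memb[memb >= 3])
  expect_equal(trueFusionIndexPct(sim$groundTruth),
               100 * fused / nrow(nuc))
})

test_that("fused fraction follows the schedule-modulated kinetics", {
  p <- simulationParams(fusionRate = 0.35, fMax = 0.6, drugEffect = 0)
  nd <- fusedFractionCourse(p, exposureSchedule("ND"), 0:10)
  cont <- fusedFractionCourse(p, exposureSchedule("continuous"), 0:10)
  late <- fusedFractionCourse(p, exposureSchedule("late"), 0:10)
  early <- fusedFractionCourse(p, exposureSchedule("early"), 0:10)

  # fully blocking drug over days 3-10 freezes f at its day-3 value (0)
  expect_true(all(cont$fused_fraction == cont$fused_fraction[4]))
  expect_equal(cont$fused_fraction[11], 0)
  # ND saturates below fMax and is strictly increasing after day 3
  expect_true(all(diff(nd$fused_fraction[4:11]) > 0))
  expect_lt(nd$fused_fraction[11], 0.6)
  # late exposure leaves days 3-7 identical to ND (drug starts day 7)
  expect_identical(late$fused_fraction[1:8], nd$fused_fraction[1:8])
  # closed form: f(day) = fMax (1 - exp(-rate * active days))
  expect_equal(nd$fused_fraction[11], 0.6 * (1 - exp(-0.35 * 7)))
  expect_equal(early$fused_fraction[11], 0.6 * (1 - exp(-0.35 * 4)))

  # monotone non-decreasing for any drug effect
  for (eff in c(0, 0.3, 0.7, 1)) {
    q <- simulationParams(drugEffect = eff)
    f <- fusedFractionCourse(q, exposureSchedule("continuous"), 0:10)
    expect_true(all(diff(f$fused_fraction) >= 0))
  }
  expect_error(fusedFractionCourse(p, exposureSchedule("ND"), c(5, 3)),
               class = "mfValidationError")
})

test_that("nuclei grow geometrically then plateau", {
  p <- simulationParams(nNucleiDay0 = 40L, growthRate = 1.35,
                        plateauNuclei = 130L)
  n <- nucleiCountCourse(p, 0:10)
  expect_identical(n[1], 40L)
  expect_identical(n[2], 54L)  # round(40 * 1.35)
  expect_true(all(diff(n) >= 0))
  expect_identical(n[11], 130L)
  sim <- simulateScene(p, day = 0)
  expect_identical(totalNuclei(sim$groundTruth), 40L)
})

test_that("scene background converges to the autofluorescence level", {
  p <- smallParams(seed = 2, autofluorescenceLevel = 400)
  sim <- simulateScene(p, day = 5)
  px <- pixels(nucleus(sim$scene))
  band <- c(px[1:4, ], px[253:256, ], px[, 1:4], px[, 253:256])
  se <- sqrt((400 + p@noiseGaussianSd^2) / length(band))
  expect_lt(abs(mean(band) - 400), 3 * se)
})

test_that("label combos order cytoplasm contrast as expected", {
  measured <- vapply(c("cGFP+nmCherry", "cmCherry+nGFP"), function(combo) {
    p <- smallParams(seed = 6, labelCombo = combo)
    sim <- simulateScene(p, day = 7)
    obj <- trueFiberMasks(sim$groundTruth) > 0
    # erode the background region away from soft fiber edges
    bg <- !(myofuse:::fromEB(EBImage::dilate(
      myofuse:::asEB(obj * 1), EBImage::makeBrush(9, "disc"))) > 0)
    contrastValue(objectContrast(cytoplasm(sim$scene), obj, bg))
  }, numeric(1))
  expect_gt(measured["cGFP+nmCherry"], measured["cmCherry+nGFP"])
})

test_that("simulatePlate writes a complete, reproducible bundle set", {
  p <- smallParams(seed = 1)
  conds <- list(
    ND = list(params = p, schedule = exposureSchedule("ND")),
    cont = list(params = p, schedule = exposureSchedule("continuous")))
  days <- c(3L, 7L)
  d1 <- withr::local_tempdir()
  plate1 <- simulatePlate(conds, nWells = 2, nFields = 2, days = days,
                          seed = 11, outDir = d1)
  expect_identical(nrow(plate1$manifest), 2L * 2L * 2L * 2L)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_true(all(file.exists(file.path(plate1$manifest$path, "scene.json"))))

  plate2 <- simulatePlate(conds, nWells = 2, nFields = 2, days = days,
                          seed = 11)
  expect_identical(plate1$manifest[, names(plate1$manifest) != "path"],
                   plate2$manifest[, names(plate2$manifest) != "path"])
  sid <- plate1$manifest$scene_id[1]
  expect_identical(pixels(nucleus(plate1$scenes[[sid]]$scene)),
                   pixels(nucleus(plate2$scenes[[sid]]$scene)))
  # fields of one well are independent but seed-derived
  f0 <- plate1$scenes[["ND_W1_D3_F0"]]$groundTruth
  f1 <- plate1$scenes[["ND_W1_D3_F1"]]$groundTruth
  expect_false(identical(trueNuclei(f0)$x, trueNuclei(f1)$x))

  expect_error(simulatePlate(setNames(conds, c("a", "a")), days = days),
               class = "mfValidationError")
  expect_error(simulatePlate(conds, nWells = 0, days = days),
               class = "mfValidationError")
})

test_that("adding a condition never perturbs existing wells", {
  p <- smallParams(seed = 1)
  base <- list(ND = list(params = p, schedule = exposureSchedule("ND")))
  more <- c(base, list(extra = list(params = p,
                                    schedule = exposureSchedule("early"))))
  p1 <- simulatePlate(base, nWells = 1, days = 5L, seed = 3)
  p2 <- simulatePlate(more, nWells = 1, days = 5L, seed = 3)
  expect_identical(pixels(nucleus(p1$scenes[["ND_W1_D5_F0"]]$scene)),
                   pixels(nucleus(p2$scenes[["ND_W1_D5_F0"]]$scene)))
})

test_that("parameter validation fires before any rendering", {
  expect_error(simulationParams(fMax = 1.5))
  expect_error(simulationParams(drugEffect = -0.1))
  expect_error(simulationParams(width = 32))
  expect_error(simulateScene(smallParams(), day = -1),
               class = "mfValidationError")
})
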