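mkResults <- function(manifest, values) {
  data.frame(well_id = manifest$well_id, day = manifest$day,
             condition = manifest$condition,
             field_index = manifest$field_index,
             total_nuclei = 100L, fused_nuclei = 0L,
             fusion_index_pct = values, n_fused_fibers = 0L,
             mean_fiber_area_px = NA_real_, stringsAsFactors = FALSE)
}

test_that("fields pool by mean into well-level replicates", {
  manifest <- data.frame(
    scene_id = c("a", "b"), condition = "ND", well_id = "ND-W1",
    day = 5L, field_index = 0:1, stringsAsFactors = FALSE)
  res <- mkResults(manifest, c(20, 30))
  tc <- aggregateResults(res, manifest)
  expect_length(tc, 1)
  expect_equal(courseValues(tc$ND)$fusion_index_pct, 25)
})

test_that("one time course per condition; missing days flagged, orphans error", {
  manifest <- expand.grid(condition = c("a", "b", "c", "d"),
                          well_id = "W1", day = c(3L, 5L), field_index = 0L,
                          stringsAsFactors = FALSE)
  manifest$well_id <- paste0(manifest$condition, "-W1")
  res <- mkResults(manifest, seq_len(nrow(manifest)))
  tcs <- aggregateResults(res, manifest)
  expect_length(tcs, 4)
  expect_named(tcs, c("a", "b", "c", "d"))

  # drop day-5 results of condition a: flagged missing, not imputed
  res2 <- res[!(res$condition == "a" & res$day == 5L), ]
  tcs2 <- aggregateResults(res2, manifest)
  expect_identical(tcs2$a@missingDays, 5L)
  expect_identical(courseDays(tcs2$a), 3L)

  # a result not present in the manifest is an error listing the orphan
  orphan <- res[1, ]; orphan$well_id <- "ghost"
  expect_error(aggregateResults(rbind(res, orphan), manifest), "ghost",
               class = "mfValidationError")
})

test_that("aggregate is invariant to input row order", {
  manifest <- expand.grid(condition = c("x", "y"), well_id = c("W1", "W2"),
                          day = c(3L, 7L), field_index = 0:1,
                          stringsAsFactors = FALSE)
  manifest$well_id <- paste0(manifest$condition, "-", manifest$well_id)
  manifest$scene_id <- seq_len(nrow(manifest))
  set.seed(5)
  res <- mkResults(manifest, runif(nrow(manifest), 0, 60))
  a <- aggregateResults(res, manifest)
  b <- aggregateResults(res[sample(nrow(res)), ], manifest)
  expect_equal(courseValues(a$x), courseValues(b$x))
  expect_equal(courseValues(a$y), courseValues(b$y))
})

test_that("ANOVA + Bonferroni comparison matches reference statistics", {
  set.seed(11)
  g <- list(a = rnorm(3, 10, 1), b = rnorm(3, 50, 1),
            c = rnorm(3, 10, 1), d = rnorm(3, 11, 1))
  tcs <- lapply(names(g), function(k) tcFixture(k, 10L, list(g[[k]])))
  cmp <- compareConditions(tcs, day = 10)

  # 4 groups -> 6 pairwise tests, each raw p multiplied by 6 (capped)
  expect_identical(nrow(cmp$pairwise), 6L)
  expect_equal(cmp$pairwise$p_adj,
               pmin(1, stats::p.adjust(cmp$pairwise$p_raw, "bonferroni",
                                       n = 6)))

  # raw pairwise p equals the reference pooled-variance t-test
  ref <- stats::t.test(g$a, g$b, var.equal = TRUE)$p.value
  row <- cmp$pairwise[cmp$pairwise$group1 == "a" & cmp$pairwise$group2 == "b", ]
  expect_equal(row$p_raw, ref, tolerance = 1e-12)
  expect_true(row$significant)  # means 10 vs 50 at sd 1, n = 3

  # ANOVA row equals stats::aov on the same layout
  vals <- unlist(g); cond <- factor(rep(names(g), each = 3))
  s <- summary(stats::aov(vals ~ cond))[[1]]
  expect_equal(cmp$anova$F, s[["F value"]][1], tolerance = 1e-12)
  expect_equal(cmp$anova$p, s[["Pr(>F)"]][1], tolerance = 1e-12)
})

test_that("degenerate comparisons are handled by policy", {
  # all groups identical constants: p = 1 everywhere, nothing flagged
  tcs <- lapply(c("a", "b", "c"), function(k)
    tcFixture(k, 10L, list(c(5, 5, 5))))
  cmp <- compareConditions(tcs, day = 10)
  expect_equal(cmp$anova$p, 1)
  expect_true(all(cmp$pairwise$p_adj == 1))
  expect_false(any(cmp$pairwise$significant))

  # fewer than 2 replicates is an explicit error
  one <- list(tcFixture("a", 10L, list(5)), tcFixture("b", 10L, list(c(1, 2))))
  expect_error(compareConditions(one, day = 10),
               class = "mfValidationError")
  expect_error(compareConditions(tcs[1], day = 10),
               class = "mfValidationError")
})

test_that("time to fractional maximum interpolates linearly", {
  tc <- tcFixture("ND", 1:4, list(0, 0, 50, 100))
  expect_equal(timeToFractionMax(tc, 0.9), 3.8)
  # constant course reaches its max on the first day
  flat <- tcFixture("ND", 1:4, list(30, 30, 30, 30))
  expect_equal(timeToFractionMax(flat, 0.9), 1)
  expect_error(timeToFractionMax(tc, 0), class = "mfValidationError")
  expect_error(timeToFractionMax(tc, 1.2), class = "mfValidationError")
})

test_that("a doubled fusion rate reaches near-maximal fusion earlier", {
  p <- simulationParams()
  nd <- fusedFractionCourse(p, exposureSchedule("ND"), 3:10)
  p2 <- p; p2@fusionRate <- 2 * p@fusionRate
  dox <- fusedFractionCourse(p2, exposureSchedule("ND"), 3:10)
  mk <- function(course, cond) tcFixture(
    cond, 3:10, as.list(100 * course$fused_fraction))
  expect_lt(timeToFractionMax(mk(dox, "DOX"), 0.9),
            timeToFractionMax(mk(nd, "ND"), 0.9))
})
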