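# Experiment-level aggregation and condition comparison: per-condition
# time courses (wells are the replicate unit; fields pool by mean), one-way
# ANOVA with Bonferroni-adjusted pairwise t-tests, and time-to-maximal-
# fusion summaries.

#' Aggregate per-scene results into per-condition time courses
#'
#' Field-level fusion results are averaged into well-level replicates (the
#' well is the replicate unit); one [TimeCourse-class] is produced per
#' condition. Results that cannot be reconciled with the manifest raise an
#' error listing the orphans; manifest days without any result are flagged
#' in \code{missingDays}, never imputed.
#'
#' @param results data.frame of per-scene results ([resultsTable()] /
#'   [readResults()] format).
#' @param manifest data.frame mapping scenes to (condition, well_id, day,
#'   field_index), e.g. from [simulatePlate()].
#' @return named list of [TimeCourse-class], one per condition (manifest
#'   order).
#' @export
aggregateResults <- function(results, manifest) {
  key <- function(d) paste(d$condition, d$well_id, d$day, d$field_index,
                           sep = "\r")
  orphans <- !(key(results) %in% key(manifest))
  if (any(orphans))
    stopValidation(
      "results not present in manifest: %s",
      paste(utils::head(paste(results$well_id[orphans], "day",
                              results$day[orphans]), 5), collapse = "; "))
  out <- list()
  for (cond in unique(manifest$condition)) {
    mc <- manifest[manifest$condition == cond, ]
    rc <- results[results$condition == cond, ]
    rows <- NULL
    for (wi in unique(mc$well_id)) {
      for (d in sort(unique(mc$day[mc$well_id == wi]))) {
        vals <- rc[rc$well_id == wi & rc$day == d, ]
        if (nrow(vals) == 0) next
        rows <- rbind(rows, data.frame(
          day = d, well_id = wi,
          fusion_index_pct = mean(vals$fusion_index_pct),
          total_nuclei = mean(vals$total_nuclei),
          stringsAsFactors = FALSE))
      }
    }
    allDays <- sort(unique(mc$day))
    haveDays <- if (is.null(rows)) integer(0) else sort(unique(rows$day))
    if (is.null(rows))
      rows <- data.frame(day = integer(0), well_id = character(0),
                         fusion_index_pct = numeric(0),
                         total_nuclei = numeric(0))
    out[[cond]] <- new("TimeCourse", condition = cond,
                       days = as.integer(haveDays), values = rows,
                       missingDays = as.integer(setdiff(allDays, haveDays)))
  }
  out
}

#' Compare conditions on one day (ANOVA + Bonferroni pairwise tests)
#'
#' One-way ANOVA across conditions on the chosen metric and day, followed
#' by all pairwise two-sample t-tests (pooled variance, the conventional
#' post-hoc) with Bonferroni adjustment: each raw p-value is multiplied by
#' the number of pairs and capped at 1. When every replicate in every group
#' is identical there is nothing to test; p-values are reported as 1 and no
#' pair is flagged.
#'
#' @param timecourses named list of [TimeCourse-class] (from
#'   [aggregateResults()]).
#' @param day day to compare.
#' @param metric \code{"fusion_index"} or \code{"nuclei_count"}.
#' @param alpha family-wise significance level (default 0.05).
#' @return list: \code{day}, \code{metric}, \code{groups} (replicate
#'   values), \code{anova} (data.frame F, df1, df2, p), \code{pairwise}
#'   (data.frame with group means, raw and adjusted p, significance flag),
#'   \code{alpha}.
#' @export
compareConditions <- function(timecourses, day,
                              metric = c("fusion_index", "nuclei_count"),
                              alpha = 0.05) {
  metric <- match.arg(metric)
  col <- if (metric == "fusion_index") "fusion_index_pct" else "total_nuclei"
  groups <- list()
  for (tc in timecourses) {
    v <- tc@values[tc@values$day == day, col]
    if (length(v) > 0) groups[[tc@condition]] <- v
  }
  if (length(groups) < 2)
    stopValidation("need >= 2 conditions with data on day %d", day)
  ns <- lengths(groups)
  if (any(ns < 2))
    stopValidation(
      "insufficient replication on day %d: %s has fewer than 2 replicates",
      day, paste(names(groups)[ns < 2], collapse = ", "))

  vals <- unlist(groups, use.names = FALSE)
  cond <- factor(rep(names(groups), ns), levels = names(groups))
  if (stats::var(vals) == 0) {
    anova <- data.frame(F = NA_real_, df1 = length(groups) - 1L,
                        df2 = length(vals) - length(groups), p = 1)
  } else {
    fit <- stats::aov(vals ~ cond)
    s <- summary(fit)[[1]]
    anova <- data.frame(F = s[["F value"]][1], df1 = s[["Df"]][1],
                        df2 = s[["Df"]][2], p = s[["Pr(>F)"]][1])
  }

  pairs <- utils::combn(names(groups), 2)
  nPairs <- ncol(pairs)
  pw <- NULL
  for (j in seq_len(nPairs)) {
    a <- groups[[pairs[1, j]]]; b <- groups[[pairs[2, j]]]
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
      (na + nb - 2)
    if (sp2 == 0) {
      p <- if (mean(a) == mean(b)) 1 else 0
      tstat <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
    } else {
      tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
      p <- 2 * stats::pt(-abs(tstat), df = na + nb - 2)
    }
    pw <- rbind(pw, data.frame(
      group1 = pairs[1, j], group2 = pairs[2, j],
      mean1 = mean(a), mean2 = mean(b), t = tstat,
      p_raw = p, p_adj = min(1, p * nPairs),
      stringsAsFactors = FALSE))
  }
  pw$significant <- pw$p_adj < alpha
  list(day = day, metric = metric, groups = groups, anova = anova,
       pairwise = pw, alpha = alpha)
}

#' Day at which a time course reaches a fraction of its maximal fusion
#'
#' Finds the earliest (linearly interpolated) day at which the mean fusion
#' index over replicates reaches \code{fraction} times its maximum over
#' the course. The maximum itself is attained somewhere, so the threshold
#' is always reached by the argmax day at the latest; a constant non-zero
#' course reaches it on its first day. Conditions that fuse faster report
#' smaller values ("arrive quicker" at their maximal fusion).
#'
#' @param tc a [TimeCourse-class].
#' @param fraction target fraction of the course maximum, in (0, 1].
#' @return interpolated day (numeric scalar).
#' @examples
#' # mean fusion 0, 0, 50, 100 on days 1:4 -> 0.9 * 100 = 90 is reached
#' # between days 3 and 4, at 3 + (90 - 50)/(100 - 50) = 3.8
#' @export
timeToFractionMax <- function(tc, fraction = 0.9) {
  stopifnot(is(tc, "TimeCourse"))
  if (fraction <= 0 || fraction > 1)
    stopValidation("fraction must lie in (0, 1]")
  if (length(tc@days) == 0) stopValidation("time course is empty")
  means <- vapply(tc@days, function(d)
    mean(tc@values$fusion_index_pct[tc@values$day == d]), numeric(1))
  target <- fraction * max(means)
  for (i in seq_along(tc@days)) {
    if (means[i] >= target) {
      if (i == 1 || means[i] == means[i - 1]) return(as.numeric(tc@days[i]))
      d0 <- tc@days[i - 1]; d1 <- tc@days[i]
      return(d0 + (target - means[i - 1]) / (means[i] - means[i - 1]) *
               (d1 - d0))
    }
  }
  as.numeric(tc@days[which.max(means)])  # unreachable; max is attained
}
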