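test_that("contrast construction averages electrode differences per hemisphere", {
  ch <- toyRecording(matrix(0, 2, 4), hemisphere = c("L", "L"))@channels
  vals <- rbind(c(0.5, 0.7), c(0.5, 0.5), c(0.1, 0.1), c(0.1, 0.3))
  cond <- c("remembered", "remembered", "forgotten", "forgotten")
  out <- buildContrast(vals, cond, c("remembered", "forgotten"), ch)
  # electrode diffs 0.4 and 0.4 -> subject value 0.4
  expect_equal(out$value, 0.4)
  expect_equal(out$n_electrodes, 2)
  # electrodes 0.2 and 0.6 average to 0.4
  vals2 <- rbind(c(0.2, 0.6), c(0, 0))
  out2 <- buildContrast(vals2, c("remembered", "forgotten"),
                        c("remembered", "forgotten"), ch)
  expect_equal(out2$value, 0.4)
  # equal condition means give zero
  vals3 <- rbind(c(1, 1), c(1, 1))
  out3 <- buildContrast(vals3, c("remembered", "forgotten"),
                        c("remembered", "forgotten"), ch)
  expect_equal(out3$value, 0)
  # an electrode with an empty condition is skipped with a warning
  vals4 <- rbind(c(NA, 0.5), c(0.1, 0.1))
  expect_warning(out4 <- buildContrast(vals4, c("remembered", "forgotten"),
                                       c("remembered", "forgotten"), ch),
                 "skipped")
  expect_equal(out4$n_electrodes, 1)
})

test_that("group t-test matches the closed form and rejects zero variance", {
  r <- groupTtest(c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(r$t, 0.3 / (sd(c(0.1, 0.2, 0.3, 0.4, 0.5)) / sqrt(5)))
  expect_equal(r$t, 4.2426, tolerance = 1e-4)
  expect_equal(r$dof, 4)
  r2 <- groupTtest(c(-1, 1))
  expect_equal(r2$t, 0)
  expect_equal(r2$p, 1)
  expect_error(groupTtest(c(1, 1, 1, 1)), "zero variance|constant")
  # paired and two-sample variants agree with stats::t.test
  x <- c(1, 2, 3, 5); y <- c(0, 2, 2, 3)
  expect_equal(groupTtest(x, y, "paired")$t,
               unname(t.test(x, y, paired = TRUE)$statistic))
  expect_equal(groupTtest(x, y, "two_sample")$t,
               unname(t.test(x, y, var.equal = TRUE)$statistic))
})

test_that("cluster permutation finds planted clusters and not null ones", {
  set.seed(10)
  # all-zero maps: no clusters
  z <- matrix(0, 8, 100)
  expect_length(clusterPermutation(z, c(10, 10), seed = 1)$clusters, 0)
  # planted contiguous 5x5 shift, d = 1.5, 12 subjects on a 20x20 map
  planted <- outer(6:10, 6:10, function(i, j) (j - 1) * 20 + i)
  hits <- 0; covered <- 0
  nRuns <- 25
  for (r in seq_len(nRuns)) {
    maps <- matrix(rnorm(12 * 400), 12, 400)
    maps[, planted] <- maps[, planted] + 1.5
    res <- clusterPermutation(maps, c(20, 20), nPerm = 500, seed = r)
    sig <- Filter(function(cl) cl$p < 0.05 && cl$mass > 0, res$clusters)
    if (length(sig)) {
      best <- sig[[which.max(vapply(sig, function(cl) abs(cl$mass), 0))]]
      if (length(intersect(best$bins, planted)) >= 0.5 * length(planted))
        hits <- hits + 1
    }
  }
  expect_gte(hits / nRuns, 0.9)
})

test_that("cluster mass sums member t values under same-sign adjacency", {
  set.seed(11)
  maps <- matrix(rnorm(10 * 36, sd = 0.1), 10, 36)
  maps[, c(8, 9, 14, 15)] <- maps[, c(8, 9, 14, 15)] + 3  # 2x2 block (6x6)
  res <- clusterPermutation(maps, c(6, 6), nPerm = 200, seed = 2)
  expect_gte(length(res$clusters), 1)
  cl <- res$clusters[[which.max(vapply(res$clusters,
                                       function(c) abs(c$mass), 0))]]
  expect_true(all(c(8, 9, 14, 15) %in% cl$bins))
  expect_equal(cl$mass, sum(res$t[cl$bins]))
  expect_true(all(res$t[cl$bins] > res$tCrit))
})

test_that("sign-flip thresholds are symmetric and near the parametric value", {
  set.seed(5)
  vals <- matrix(rnorm(20 * 20), 20, 20)
  th <- signflipMapThreshold(vals, nPerm = 1000, seed = 3)
  expect_lt(abs(th$lower + th$upper), 0.2)
  expect_equal(dim(th$null), c(1000, 20))
  tpar <- qt(0.975, 19)
  expect_lt(abs(th$upper - tpar) / tpar, 0.15)
  expect_lt(abs(-th$lower - tpar) / tpar, 0.15)
  # points with < 5 subjects are excluded
  vals2 <- vals; vals2[5:20, 1] <- NA
  th2 <- signflipMapThreshold(vals2, nPerm = 50, seed = 1)
  expect_equal(th2$excluded, 1L)
})

test_that("spatial aggregation averages within-radius electrodes per subject", {
  targets <- rbind(c(0, 0, 0), c(30, 0, 0))
  coords <- list(rbind(c(10, 0, 0), c(5, 0, 0)))
  effects <- list(c(0.2, 0.6))
  agg <- spatialAggregate(effects, coords, targets, radius = 12.5,
                          minSubjects = 1)
  expect_equal(agg$maps[1, 1], 0.4)        # both electrodes within 12.5 mm
  expect_true(is.na(agg$maps[1, 2]))       # 20+ mm away: unassigned
  # single electrode at 10 mm -> its own value; at 13 mm -> unassigned
  agg2 <- spatialAggregate(list(0.7), list(matrix(c(10, 0, 0), 1)),
                           rbind(c(0, 0, 0)), radius = 12.5, minSubjects = 1)
  expect_equal(agg2$maps[1, 1], 0.7)
  agg3 <- spatialAggregate(list(0.7), list(matrix(c(13, 0, 0), 1)),
                           rbind(c(0, 0, 0)), radius = 12.5, minSubjects = 1)
  expect_true(is.na(agg3$maps[1, 1]))
  expect_error(spatialAggregate(effects, coords, targets[0, , drop = FALSE]),
               "empty")
})

test_that("lateralization ANOVA matches a hand-computed balanced oracle", {
  # balanced 2x2 with tabulated values; oracle = explicit sums of squares
  d <- data.frame(
    value = c(1.1, 0.9, 1.0, 1.2, 0.2, 0.1, 0.3, 0.0,
              0.1, 0.3, 0.2, 0.0, 1.2, 1.0, 0.9, 1.1),
    hemisphere = rep(c("L", "R"), each = 8),
    contrast = rep(rep(c("memory", "navigation"), each = 4), 2))
  res <- lateralityAnova(d)
  cells <- tapply(d$value, list(d$hemisphere, d$contrast), mean)
  gm <- mean(d$value)
  ssInt <- 4 * sum((cells - outer(rowMeans(cells) - gm, colMeans(cells) - gm,
                                  `+`) - gm)^2)
  ssErr <- sum((d$value - ave(d$value,
                              paste(d$hemisphere, d$contrast)))^2)
  fOracle <- (ssInt / 1) / (ssErr / 12)
  expect_equal(res$F_interaction, fOracle, tolerance = 1e-8)
  expect_lt(res$p, 0.001)
  # equal cell means: interaction F ~ 0
  set.seed(6)
  d2 <- data.frame(value = rnorm(40, 1, 0.01),
                   hemisphere = rep(c("L", "R"), 20),
                   contrast = rep(c("memory", "navigation"), each = 20))
  expect_lt(lateralityAnova(d2)$F_interaction, 5)
  expect_error(lateralityAnova(d[1:5, ]), ">= 2 observations")
})

test_that("perfect crossover yields a large interaction", {
  set.seed(12)
  d <- data.frame(
    value = c(rnorm(10, 1, 0.05), rnorm(10, -1, 0.05),
              rnorm(10, -1, 0.05), rnorm(10, 1, 0.05)),
    hemisphere = rep(c("L", "L", "R", "R"), each = 10),
    contrast = rep(c("memory", "navigation", "memory", "navigation"),
                   each = 10))
  res <- lateralityAnova(d)
  expect_gt(res$F_interaction, 100)
  expect_lt(res$p, 0.001)
  # post-hoc cells recover the pattern
  expect_gt(res$posthoc$L.memory$t, 10)
  expect_lt(res$posthoc$R.memory$t, -10)
})

test_that("narrowband detection flags a planted bump and resists outliers", {
  f <- exp(seq(log(1), log(50), length.out = 30))
  exact <- 10 - 2 * log(f)
  resExact <- narrowbandDetect(exact, f)
  expect_length(resExact$flagged, 0)
  expect_equal(resExact$exponent, 2, tolerance = 1e-6)
  # Gaussian bump at 3 Hz, 3x the off-peak residual SD
  bump <- 0.8 * exp(-(log(f) - log(3))^2 / (2 * 0.08^2))
  res <- narrowbandDetect(exact + bump, f)
  expect_true(any(abs(res$flagged - 3) < 0.5))
  expect_lt(abs(res$exponent - 2) / 2, 0.1)
  # one extreme outlier moves the robust slope < 2%, OLS more
  out <- exact; out[25] <- out[25] + 8
  resOut <- narrowbandDetect(out, f)
  expect_lt(abs(resOut$slope - resExact$slope) / abs(resExact$slope), 0.02)
  olsShift <- abs(coef(lm(out ~ log(f)))[2] - (-2)) / 2
  expect_gt(olsShift, abs(resOut$slope - resExact$slope) / 2)
  expect_error(narrowbandDetect(c(exact[1:29], NA), f), "non-finite")
  expect_error(narrowbandDetect(exact[1:5], f[1:5]), ">= 10")
})

test_that("within-subject SEM removes between-subject offsets", {
  expect_equal(unname(withinSubjectSem(rbind(c(1, 2), c(3, 4)))), c(0, 0))
  # constant condition effect plus subject offsets -> SEM ~ 0
  set.seed(13)
  off <- rnorm(8, 0, 5)
  mat <- cbind(off + 1, off + 2, off + 3)
  expect_equal(unname(withinSubjectSem(mat)), c(0, 0, 0), tolerance = 1e-12)
  expect_error(withinSubjectSem(matrix(1:3, 1)), "2 subjects")
  expect_error(withinSubjectSem(rbind(c(1, NA), c(2, 3))), "complete")
})
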