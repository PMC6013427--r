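# independent brute-force oracle for the percentile-rank accuracy:
# enumerate every grid candidate explicitly and rank the observed error
bruteAccuracy <- function(true, resp, width = 100, height = 70, step = 1) {
  obs <- sqrt(sum((true - resp)^2))
  greater <- 0; equal <- 0; total <- 0
  for (cx in seq(0, width, by = step)) for (cy in seq(0, height, by = step)) {
    total <- total + 1
    if (abs(cx - resp[1]) < 1e-9 && abs(cy - resp[2]) < 1e-9) next
    e <- sqrt((cx - true[1])^2 + (cy - true[2])^2)
    if (e > obs + 1e-9) greater <- greater + 1
    else if (abs(e - obs) <= 1e-9) equal <- equal + 1
  }
  (greater + 0.5 * equal) / (total - 1)
}

test_that("accuracy is exactly 1 at zero error and ~0 at the worst corner", {
  a <- arenaConfig()
  for (p in list(c(50, 35), c(0, 0), c(17, 53), c(100, 70)))
    expect_identical(accuracyScore(p, p, a), 1)
  expect_equal(accuracyScore(c(50, 35), c(0, 0), a),
               bruteAccuracy(c(50, 35), c(0, 0)))
  expect_lt(accuracyScore(c(50, 35), c(0, 0), a), 0.001)
  # a unique worst response scores exactly 0
  expect_identical(accuracyScore(c(10, 10), c(100, 70), a), 0)
})

test_that("accuracy matches the brute-force grid oracle everywhere", {
  a <- arenaConfig()
  set.seed(42)
  cases <- list(c(50, 35, 0, 0), c(30, 20, 31, 22), c(0, 35, 99, 35),
                c(80, 60, 80.5, 60.5))
  for (i in 1:6)
    cases[[length(cases) + 1]] <- c(runif(1, 0, 100), runif(1, 0, 70),
                                    runif(1, 0, 100), runif(1, 0, 70))
  for (cs in cases) {
    expect_equal(accuracyScore(cs[1:2], cs[3:4], a),
                 bruteAccuracy(cs[1:2], cs[3:4]), tolerance = 1e-12)
  }
})

test_that("accuracy respects arena symmetry and radial monotonicity", {
  a <- arenaConfig()
  t0 <- c(30, 20); r0 <- c(55, 45)
  base <- accuracyScore(t0, r0, a)
  # reflection through either axis
  expect_equal(accuracyScore(c(100 - t0[1], t0[2]), c(100 - r0[1], r0[2]), a),
               base)
  expect_equal(accuracyScore(c(t0[1], 70 - t0[2]), c(r0[1], 70 - r0[2]), a),
               base)
  # moving radially away along a fixed ray decreases the score
  dir <- c(1, 0.5) / sqrt(1.25)
  accs <- sapply(seq(0, 30, by = 5), function(d)
    accuracyScore(t0, t0 + d * dir, a))
  expect_true(all(diff(accs) <= 0))
})

test_that("uniform responses give an approximately uniform accuracy score", {
  a <- arenaConfig()
  set.seed(7)
  n <- 2000
  tx <- runif(n, 0, 100); ty <- runif(n, 0, 70)
  rx <- runif(n, 0, 100); ry <- runif(n, 0, 70)
  accs <- vapply(seq_len(n), function(i)
    accuracyScore(c(tx[i], ty[i]), c(rx[i], ry[i]), a), 0)
  ks <- suppressWarnings(ks.test(accs, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("accuracy rejects out-of-arena points and degenerate grids", {
  a <- arenaConfig()
  expect_error(accuracyScore(c(-1, 10), c(5, 5), a), "outside")
  expect_error(accuracyScore(c(5, 5), c(101, 10), a), "outside")
  expect_error(accuracyScore(c(5, 5), c(6, 6), a, gridStep = 0), "positive")
})

test_that("median-split labeling follows the accuracy + confidence rule", {
  r <- data.frame(accuracy = c(0.9, 0.8, 0.6, 0.4),
                  confidence = c("Yes", "No", "Yes", "Maybe"))
  lab <- labelMemory(r)
  expect_equal(lab$median_accuracy, rep(0.7, 4))
  expect_equal(lab$label, c("remembered", "forgotten", "forgotten",
                            "forgotten"))
  # ties: nothing strictly exceeds the median
  r2 <- data.frame(accuracy = rep(0.5, 4), confidence = rep("Yes", 4))
  expect_true(all(labelMemory(r2)$label == "forgotten"))
  r3 <- data.frame(accuracy = c(0.9, 0.1), confidence = c("Yes", "Yes"))
  expect_equal(labelMemory(r3)$label, c("remembered", "forgotten"))
  expect_error(labelMemory(data.frame(accuracy = 0.5, confidence = "Yes")),
               "at least 2")
  r4 <- data.frame(accuracy = c(0.2, 0.8), confidence = c("Yes", NA))
  expect_error(labelMemory(r4), "confidence")
})

test_that("labeling yields near-balanced classes when confidence is high", {
  set.seed(3)
  for (i in 1:5) {
    n <- 41
    conf <- sample(c("Yes", "Maybe", "No"), n, TRUE, prob = c(0.5, 0.4, 0.1))
    r <- data.frame(accuracy = runif(n), confidence = conf)
    lab <- labelMemory(r)
    nRem <- sum(lab$label == "remembered")
    expect_lte(abs(nRem - (n - nRem)), sum(conf == "No") + 1)
  }
})

test_that("spatial binning splits the arena as specified", {
  a <- arenaConfig()
  b <- spatialBin(c(50, 35), a, 1)
  expect_equal(b$region, "inner")
  expect_equal(spatialBin(c(1, 1), a, 1)$region, "boundary")
  # inner rectangle is 1/sqrt(2)-scaled: ~70.71 x 49.50, half the area
  hw <- 100 / sqrt(2) / 2; hh <- 70 / sqrt(2) / 2
  expect_equal(2 * hw * 2 * hh / (100 * 70), 0.5)
  eps <- 1e-6
  expect_equal(spatialBin(c(50 + hw - eps, 35), a, 1)$region, "inner")
  expect_equal(spatialBin(c(50 + hw + 0.01, 35), a, 1)$region, "boundary")
  # near/far relative to the viewpoint end
  expect_equal(spatialBin(c(10, 35), a, 1)$half, "near")
  expect_equal(spatialBin(c(90, 35), a, 1)$half, "far")
  expect_equal(spatialBin(c(90, 35), a, 2)$half, "near")
})

test_that("points economy reproduces the payoff table", {
  expect_equal(scorePoints("Yes", TRUE), 200)
  expect_equal(scorePoints("Yes", FALSE), -350)
  expect_equal(scorePoints("Maybe", TRUE), 100)
  expect_equal(scorePoints("Maybe", FALSE), -50)
  expect_equal(scorePoints("No", TRUE), 50)
  expect_equal(scorePoints("No", FALSE), 0)
  expect_error(scorePoints("Sure", TRUE), "confidence")
})

test_that("behavioral summary aggregates a scored session", {
  s <- scoreSession(generateSession(taskConfig(nTrials = 4), seed = 11))
  bs <- behavioralSummary(s)
  expect_equal(bs$n, nrow(sessionResponses(s)))
  expect_true(bs$mean_accuracy > 0 && bs$mean_accuracy < 1)
  expect_true(all(names(bs$accuracy_by_region) %in% c("inner", "boundary")))
  # confidence tracks accuracy on average
  ac <- bs$accuracy_by_confidence
  if (all(c("Yes", "No") %in% names(ac))) expect_gt(ac["Yes"], ac["No"])
})
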