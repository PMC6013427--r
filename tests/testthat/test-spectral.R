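test_that("frequency grid is strictly log-spaced in 1-200 Hz", {
  g <- frequencyGrid()
  f <- gridFrequencies(g)
  expect_length(f, 50)
  expect_equal(f[1], 1)
  expect_equal(f[50], 200)
  r <- diff(log(f))
  expect_lt(max(abs(r - r[1])), 1e-9)
  expect_error(frequencyGrid(10, 0.5, 10), "1 Hz")
})

test_that("Morlet power scales quadratically and peaks at the signal frequency", {
  fs <- 500
  g <- frequencyGrid(12, 2, 64)
  f0 <- gridFrequencies(g)[6]
  t <- seq_len(4 * fs) / fs
  mkEp <- function(amp) toyEpochs(amp * sin(2 * pi * f0 * t), fs,
                                  bufferMs = 1000,
                                  windowMs = c(0, 2000))
  p1 <- powerValues(morletPower(mkEp(1), g, timeAverage = TRUE))
  p2 <- powerValues(morletPower(mkEp(2), g, timeAverage = TRUE))
  expect_equal(p2 / p1, array(4, dim(p1)), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(which.max(p1[1, 1, ]), 6L)
})

test_that("power of well-separated sinusoids is additive at their peaks", {
  fs <- 500
  g <- frequencyGrid(10, 2, 64)
  f <- gridFrequencies(g)
  fa <- f[3]; fb <- f[9]   # far apart on the log grid
  t <- seq_len(4 * fs) / fs
  ep <- function(x) toyEpochs(x, fs, bufferMs = 1000, windowMs = c(0, 2000))
  pa <- powerValues(morletPower(ep(sin(2 * pi * fa * t)), g, TRUE))[1, 1, ]
  pb <- powerValues(morletPower(ep(sin(2 * pi * fb * t)), g, TRUE))[1, 1, ]
  pab <- powerValues(morletPower(ep(sin(2 * pi * fa * t) +
                                      sin(2 * pi * fb * t)), g, TRUE))[1, 1, ]
  expect_lt(abs(pab[3] - (pa[3] + pb[3])) / pab[3], 0.05)
  expect_lt(abs(pab[9] - (pa[9] + pb[9])) / pab[9], 0.05)
})

test_that("trimmed power is insensitive to doubling the 3000-ms buffer", {
  fs <- 500
  set.seed(4)
  x <- thetaSME:::.powerlawNoise(14 * fs, fs, 2, 10)
  g <- frequencyGrid(8, 2, 64)
  # same analysis second, extracted with 3-s vs 6-s buffers (hand-built)
  nb3 <- 3 * fs; nb6 <- 2 * nb3
  seg3 <- x[(nb6 - nb3 + 1):(nb6 + nb3 + fs)]
  es3 <- toyEpochs(seg3, fs, windowMs = c(0, 1000), bufferMs = 3000)
  es6 <- toyEpochs(x[1:(2 * nb6 + fs)], fs, windowMs = c(0, 1000),
                   bufferMs = 6000)
  p3 <- powerValues(morletPower(es3, g, TRUE))[1, 1, ]
  p6 <- powerValues(morletPower(es6, g, TRUE))[1, 1, ]
  expect_true(all(abs(p3 - p6) / p6 < 0.01))
})

test_that("log/z transform matches the two-event closed form and group rules", {
  g <- frequencyGrid(3, 1, 4)
  # 4 events: two encoding (normalization), one baseline, one no_item
  vals <- array(1, c(4, 2, 3))
  vals[1, , ] <- exp(1); vals[2, , ] <- exp(3)
  vals[3, , ] <- exp(2); vals[4, , ] <- exp(5)
  pt <- new("PowerTensor", values = vals, scale = "raw",
            events = data.frame(type = c("encoding", "encoding",
                                         "baseline", "no_item"),
                                session = "0", trial = 1:4),
            channels = toyRecording(matrix(0, 2, 4))@channels,
            grid = g, timesMs = numeric(0), grouping = "none")
  z <- logAndZscore(pt)
  expect_equal(powerScale(z), "z")
  v <- powerValues(z)
  # normalization group = {1, 3, 2} log-powers: mean 2, sd 1
  expect_equal(v[1, 1, 1], -1)
  expect_equal(v[2, 1, 1], 1)
  expect_equal(v[3, 1, 1], 0)
  # no_item transformed with the same stats but excluded from them
  expect_equal(v[4, 1, 1], 3)
  # z over the normalization events has mean 0, sd 1
  expect_equal(mean(v[1:3, 1, 1]), 0, tolerance = 1e-9)
  expect_equal(sd(v[1:3, 1, 1]), 1, tolerance = 1e-9)
})

test_that("z-scoring errors on zero spread and flags zero power", {
  g <- frequencyGrid(3, 1, 4)
  vals <- array(2, c(3, 1, 3))
  pt <- new("PowerTensor", values = vals, scale = "raw",
            events = data.frame(type = rep("encoding", 3), session = "0"),
            channels = toyRecording(matrix(0, 1, 4))@channels,
            grid = g, timesMs = numeric(0), grouping = "none")
  expect_error(logAndZscore(pt), "zero standard deviation")
  vals2 <- vals; vals2[1, 1, 1] <- 0; vals2[2, , ] <- 1
  pt2 <- pt; pt2@values <- vals2
  expect_warning(logAndZscore(pt2), "non-positive")
})

test_that("z-scoring is invariant to a multiplicative raw-power constant", {
  g <- frequencyGrid(3, 1, 4)
  set.seed(8)
  vals <- array(exp(rnorm(5 * 2 * 3)), c(5, 2, 3))
  mk <- function(v) new("PowerTensor", values = v, scale = "raw",
                        events = data.frame(type = rep("encoding", 5),
                                            session = "0"),
                        channels = toyRecording(matrix(0, 2, 4))@channels,
                        grid = g, timesMs = numeric(0), grouping = "none")
  z1 <- powerValues(logAndZscore(mk(vals)))
  z2 <- powerValues(logAndZscore(mk(vals * 17)))
  expect_equal(z1, z2, tolerance = 1e-9)
})

test_that("band averaging selects the closed-interval grid frequencies", {
  g <- frequencyGrid()   # 50 in 1-200
  f <- gridFrequencies(g)
  nLow <- sum(f >= 1 & f <= 3)   # derived by grid enumeration
  set.seed(1)
  vals <- array(rnorm(4 * 1 * 50), c(4, 1, 50))
  pt <- toyZTensor(vals, g)
  bp <- bandPower(pt, "low_theta")
  manual <- apply(vals[, 1, f >= 1 & f <= 3, drop = FALSE], 1, mean)
  expect_equal(unname(bp[, 1]), manual)
  expect_gt(nLow, 1)
  # full-grid band equals the overall mean; zero tensor gives zero
  full <- bandPower(pt, c(1, 200))
  expect_equal(unname(full[, 1]), apply(vals[, 1, ], 1, mean))
  expect_true(all(bandPower(toyZTensor(array(0, c(2, 1, 50)), g),
                            "low_theta") == 0))
  expect_error(bandPower(pt, c(201, 300)), "no grid frequencies")
})

test_that("overlapping-window layouts reproduce the canonical bin counts", {
  expect_identical(windowCount(3500, 100, 50)$n, 69L)
  expect_identical(windowCount(6000, 500, 100)$n, 56L)
  expect_identical(windowCount(100, 100, 50)$n, 1L)
  w <- windowCount(3500, 100, 50)
  expect_equal(length(w$centers), 69)
  expect_equal(w$starts[1], 0)
  expect_equal(w$starts[69], 3400)
  expect_error(windowCount(100, 200, 50), "exceeds")
})

test_that("baseline normalization centres baselines and ignores shifts", {
  g <- frequencyGrid(3, 1, 4)
  set.seed(2)
  vals <- array(rnorm(6 * 2 * 3), c(6, 2, 3))
  types <- c("encoding", "encoding", "baseline", "baseline", "navigation",
             "no_item")
  pt <- toyZTensor(vals, g, types = types)
  bn <- baselineNormalize(pt)
  v <- powerValues(bn)
  expect_equal(apply(v[3:4, , , drop = FALSE], c(2, 3), mean),
               matrix(0, 2, 3), tolerance = 1e-12)
  # adding a constant pre-normalization leaves the output unchanged
  pt2 <- toyZTensor(vals + 5, g, types = types)
  expect_equal(powerValues(baselineNormalize(pt2)), v, tolerance = 1e-12)
  pt3 <- toyZTensor(vals, g, types = rep("encoding", 6))
  expect_error(baselineNormalize(pt3), "no baseline")
})

test_that("mean spectrum is linear in events and recovers the background slope", {
  g <- frequencyGrid(12, 1, 40)
  set.seed(3)
  vals <- array(exp(rnorm(4 * 1 * 12)), c(4, 1, 12))
  pt <- new("PowerTensor", values = vals, scale = "raw",
            events = data.frame(type = rep("encoding", 4), session = "0"),
            channels = toyRecording(matrix(0, 1, 4))@channels,
            grid = g, timesMs = numeric(0), grouping = "none")
  s1 <- meanSpectrum(pt, 1)
  expect_equal(unname(s1[1, ]), unname(log(vals[1, 1, ])))
  sAll <- meanSpectrum(pt, 1:4)
  sA <- meanSpectrum(pt, 1:2); sB <- meanSpectrum(pt, 3:4)
  expect_equal(sAll[1, ], (sA[1, ] + sB[1, ]) / 2, tolerance = 1e-12)
  expect_error(meanSpectrum(pt, integer(0)), "empty")
  # slope recovery on a gains-off synthetic recording
  nm <- neuralModel(burstAmp = 0, lineNoiseAmp = 0, hfaAmp = 0)
  sim <- simulateSubject(task = taskConfig(nTrials = 2), neural = nm,
                         montage = synthMontage(contactsPerProbe = 2),
                         seed = 12)
  rec <- bipolarReference(sim$recording)
  ptc <- eventPower(rec, sim$session, frequencyGrid(12, 2, 40))
  sp <- meanSpectrum(ptc, seq_len(nrow(eventInfo(ptc))), c(2, 40))
  fr <- attr(sp, "frequencies")
  slope <- coef(lm(sp[1, ] ~ log(fr)))[2]
  expect_lt(abs(slope - (-2)), 0.4)
})

test_that("continuous event power matches buffered epoch-wise power", {
  sim <- tinySim(seed = 6)
  rec <- bipolarReference(sim$recording)
  ev <- sessionEvents(sim$session)
  enc <- ev[ev$type == "encoding", ][1:2, ]
  g <- frequencyGrid(6, 2, 32)
  pc <- eventPower(rec, sim$session, g)
  rows <- which(sessionEvents(sim$session)$onset_ms %in% enc$onset_ms)
  es <- extractEpochs(rec, enc, c(0, 1500), 3000)
  pe <- morletPower(es, g, timeAverage = TRUE)
  expect_equal(powerValues(pc)[rows, , ], powerValues(pe)[, , ],
               tolerance = 0.02)
})
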