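mkFRA <- function(countsByLevel, levels = seq(10, by = 5,
                                              length.out = ncol(countsByLevel)),
                  calibration = NULL) {
  nf <- nrow(countsByLevel)
  g <- stimulusGrid(4000 * 2^seq(0, by = 0.1, length.out = nf), levels,
                    calibration)
  responseGrid(g, array(countsByLevel, c(dim(countsByLevel), 1L)))
}

test_that("spontaneous rate comes from the quietest row", {
  ## rows = frequencies, columns = levels; last column is quietest
  for (case in list(list(row = c(0, 0, 0, 0), mean = 0, sd = 0),
                    list(row = c(2, 2, 2, 2), mean = 2, sd = 0))) {
    fra <- mkFRA(cbind(5, case$row))
    sp <- estimateSpontaneous(fra)
    expect_equal(sp$mean, case$mean)
    expect_equal(sp$sd, case$sd)
    expect_equal(sp$nBins, 4L)
  }
  fra <- mkFRA(cbind(5, c(1, 2, 3, 6)))
  sp <- estimateSpontaneous(fra)
  expect_equal(sp$mean, 3)
  x <- c(1, 2, 3, 6)                       # hand summation oracle
  expect_equal(sp$sd, sqrt(sum((x - 3)^2) / 3))
})

test_that("excitatory mask uses a strict 2-SD criterion", {
  fra <- mkFRA(cbind(c(4, 4.5, 0, 2), c(2, 2, 2, 2)))
  mask <- excitatoryMask(fra, spont = list(mean = 2, sd = 1))
  expect_false(mask[1L, 1L])  # mean 4 is NOT above 2 + 2*1
  expect_true(mask[2L, 1L])   # mean 4.5 is

  ## zero spontaneous variance: any spiking above the mean counts
  fra0 <- mkFRA(cbind(c(1, 0, 2, 0), c(0, 0, 0, 0)))
  mask0 <- excitatoryMask(fra0)
  expect_identical(mask0[, 1L], c(TRUE, FALSE, TRUE, FALSE))

  ## raising the criterion never adds bins
  fra2 <- sampleTrials(expectedRateSurface(fraArchetype("V", cf = 4000),
                                           fraGrid(4000)),
                       fraGrid(4000), seed = 3)
  sp <- estimateSpontaneous(fra2)
  m2 <- excitatoryMask(fra2, sp, sdMultiplier = 2)
  m3 <- excitatoryMask(fra2, sp, sdMultiplier = 3)
  expect_true(all(m2 | !m3))
})

test_that("per-frequency thresholds take the quietest excitatory level", {
  mask <- rbind(c(TRUE, FALSE, TRUE, FALSE, TRUE),   # 10, 20, 30 dB attn
                rep(FALSE, 5))
  levels <- c(10, 15, 20, 25, 30)
  thr <- excitatoryThresholds(mask, levels)
  expect_equal(thr[1L], 30)       # largest attenuation = quietest
  expect_true(is.na(thr[2L]))
})

test_that("FTC fitting clamps degree and reproduces simple shapes", {
  x <- seq(-2, 2, 0.1)
  line <- 30 + 5 * x
  fit <- fitFTC(line, x, degree = 10)
  expect_lt(max(abs(evaluateFTC(fit, x) - line)), 1e-6)

  ## symmetric V: minimum at the vertex within half a frequency step
  v <- 30 + 20 * abs(x)
  ct <- extractCFThreshold(fitFTC(v, x, 10), referenceCF = 4000)
  expect_lt(abs(ct$cfOctave), 0.05)

  few <- c(30, 25, 22, 25, 30)
  expect_equal(fitFTC(few, x[1:5], degree = 10)$degree, 4L)
  expect_error(fitFTC(c(30, rep(NA, 40)), x[1:41]), "fallback")
})

test_that("CF extraction finds the FTC minimum with low-frequency ties", {
  x <- seq(-1, 1, 0.1)
  up <- fitFTC(40 + 10 * x, x, 1)
  ct <- extractCFThreshold(up, referenceCF = 4000)
  expect_equal(ct$cfOctave, -1, tolerance = 1e-6)

  ## parabola with vertex at 4 kHz, 30 dB
  par <- fitFTC(30 + 8 * x^2, x, 2)
  ct2 <- extractCFThreshold(par, referenceCF = 4000)
  expect_equal(ct2$cf, 4000, tolerance = 1e-4)
  expect_equal(ct2$threshold, 30, tolerance = 1e-6)
})

test_that("FRA area counts bins within the FTC classifier", {
  g <- fraGrid(4000)   # 51 x 17, calibration 100 -> SPL 10..90
  fra <- responseGrid(g, array(1, c(51, 17, 1)))
  present <- rep(TRUE, 51)
  constFit <- function(value) list(coeffs = value, center = 0, scale = 1,
                                   degree = 0L, span = c(-3, 2), rmse = 0)
  expect_equal(fraArea(fra, constFit(5), present), 51 * 17)   # 867
  expect_equal(fraArea(fra, constFit(95), present), 0)

  ## fallback area: strict spike criterion
  expect_equal(fraAreaFallback(mkFRA(matrix(0, 2, 2))), 0)
  expect_equal(fraAreaFallback(mkFRA(matrix(c(0, 1, 2, 3), 2, 2)), 1), 2)
  expect_error(fraAreaFallback(tinyGrid(), -1), ">= 0")
})

test_that("total spikes sums all bins and trials", {
  expect_equal(totalSpikes(tinyGrid()), 6)
  expect_equal(totalSpikes(mkFRA(matrix(0, 3, 2))), 0)
  g <- fraGrid(4000)
  s <- expectedRateSurface(fraArchetype("V", cf = 4000), g)
  TT <- sum(s$expected)
  obs <- totalSpikes(sampleTrials(s, g, seed = 9))
  expect_lt(abs(obs - TT), 3 * sqrt(TT))
})

test_that("noiseless analysis recovers the generative ground truth", {
  a <- fraArchetype("V", cf = 4000, minThreshold = 80, slopeLow = 28,
                    slopeHigh = 32)
  g <- fraGrid(4000)
  s <- expectedRateSurface(a, g)
  fra <- responseGrid(g, s$expected)

  ## the 2-SD mask equals the generative region exactly (sd = 0 row)
  mask <- excitatoryMask(fra)
  expect_identical(unname(mask), unname(s$mask))

  ## thresholds trace the contour within one 5-dB level step
  thr <- excitatoryThresholds(mask, soundLevels(g))
  x <- log2(toneFrequencies(g) / 4000)
  contour <- 80 - 28 * pmax(-x, 0) - 32 * pmax(x, 0)
  ok <- !is.na(thr)
  expect_true(all(abs(thr[ok] - contour[ok]) < 5))

  res <- analyzeFRA(fra)
  expect_equal(res@method, "polynomial")
  expect_lt(abs(log2(res@cf / 4000)), 0.05)
  expect_lt(abs(res@areaBins / sum(s$mask) - 1), 0.05)

  ## fallback area agrees within 10% on a clean V unit
  expect_lt(abs(fraAreaFallback(fra, 1) / res@areaBins - 1), 0.10)
})

test_that("mask cleaning drops isolated noise bins, keeps the region", {
  m <- matrix(FALSE, 51, 17)
  m[20:30, 5:15] <- TRUE
  m[1, 1] <- m[51, 17] <- m[3, 9] <- TRUE
  cm <- cleanMask(m)
  expect_equal(sum(cm), 11 * 11)
  expect_true(all(cm[20:30, 5:15]))
  expect_identical(cleanMask(matrix(FALSE, 3, 3)), matrix(FALSE, 3, 3))
})

test_that("explicit fallback method skips the polynomial path", {
  fra <- tinyGrid()
  res <- analyzeFRA(fra, method = "fallback", fallbackCriterion = 1)
  expect_equal(res@method, "fallback")
  expect_equal(res@areaBins, 2)   # bins holding 2 and 3
  expect_equal(res@totalSpikes, 6)
})
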