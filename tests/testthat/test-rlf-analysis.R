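test_that("per-level rate statistics use the stated conventions", {
  rlf <- rlfFromCounts(list(c(1, 2, 3), c(0, 0, 0), c(0, 0, 10)))
  st <- rlfRates(rlf)
  quiet <- which.max(st$level)
  expect_equal(st$mean[quiet], 2)
  expect_equal(st$median[quiet], 2)

  rlf0 <- rlfFromCounts(list(c(0, 0), c(0, 0)))
  expect_true(all(as.matrix(rlfRates(rlf0)[, -1]) == 0))

  x <- c(0, 0, 10, 10)
  rlf2 <- rlfFromCounts(list(x, x))
  st2 <- rlfRates(rlf2)
  expect_equal(st2$mean[1L], 5)
  expect_equal(st2$median[1L], 5)
  ## type-7 quantile oracle, by hand: q25 = 0, q75 = 10
  expect_equal(st2$iqr[1L], 10)
})

test_that("the 25% non-monotonicity rule is boundary-inclusive", {
  expect_true(classifyMonotonicity(c(0, 10, 40, 28)))    # 30% drop
  expect_false(classifyMonotonicity(c(0, 10, 40, 32)))   # 20% drop
  expect_true(classifyMonotonicity(c(0, 10, 40, 30)))    # exactly 25%
  ## tied maxima: best level is the quietest tied level
  expect_true(classifyMonotonicity(c(0, 40, 40, 28)))
  expect_false(classifyMonotonicity(c(0, 0, 0, 0)))      # flat, flagged
})

test_that("rule-based type labels follow the stated precedence", {
  lv <- seq(10, 90, 10)
  expect_equal(classifyRLF(seq(0, 8, length.out = 9), lv), "straight")
  sig <- c(0, 0.2, 1, 3, 5.4, 5.9, 6, 6, 6)
  expect_equal(classifyRLF(sig, lv), "saturating")
  expect_equal(classifyRLF(c(0, 1, 10, 40, 28, 26, 25, 24, 23), lv),
               "nonmonotonic")
  expect_equal(classifyRLF(rep(0.2, 9), lv), "flat")
  expect_equal(classifyRLF(c(0, 0, 0.1, 0.5, 1.2, 2.2, 3.6, 5.4, 7.5), lv),
               "monotonic")
  ## precedence: the 25% rule beats everything else
  expect_equal(classifyRLF(c(0, 10, 40, 28), c(10, 20, 30, 40)),
               "nonmonotonic")
})

test_that("half-maximum level interpolates the first crossing", {
  expect_equal(halfMaxLevel(seq(0, 100, length.out = 9), seq(0, 80, 10)), 40)
  expect_equal(halfMaxLevel(c(0, 1, 1, 1), c(0, 10, 20, 30)), 5)
  expect_equal(halfMaxLevel(c(2, 2, 2, 2), c(0, 10, 20, 30)), 0)
  expect_error(halfMaxLevel(c(0, 0), c(0, 10)), "undefined")
})

test_that("ROC areas equal the all-pairs oracle", {
  expect_equal(rocAUC(c(2, 2), c(2, 2)), 0.5)
  expect_equal(rocAUC(c(0, 0), c(5, 6)), 1.0)
  expect_equal(rocAUC(c(0, 1, 2), c(1, 2, 3)), 7 / 9)

  set.seed(99)
  for (i in 1:200) {
    lo <- rpois(sample(1:12, 1), runif(1, 0, 6))
    hi <- rpois(sample(1:12, 1), runif(1, 0, 6))
    expect_equal(rocAUC(lo, hi), bruteAUC(lo, hi))
    expect_equal(rocAUC(lo, hi), 1 - rocAUC(hi, lo))
    ## invariance under a strictly increasing transform
    expect_equal(rocAUC(lo^2 + lo, hi^2 + hi), rocAUC(lo, hi))
  }
  expect_error(rocAUC(numeric(0), 1), "non-empty")
})

test_that("the Discriminability Index sums |AUC - 0.5| over pairs", {
  rlf <- rlfFromCounts(list(c(0, 0), c(5, 6), c(5, 6)))
  d <- discriminabilityIndex(rlf)
  expect_equal(d$pairAUCs, c(1.0, 0.5))
  expect_equal(d$di, 0.5)
  expect_equal(d$sumAUC, 1.5)

  const <- rlfFromCounts(rep(list(c(3, 3, 3)), 9))
  expect_equal(discriminabilityIndex(const)$di, 0)

  ## 9 perfectly separated consecutive distributions: the maximum, 4.0
  sep <- rlfFromCounts(lapply(0:8, function(k) c(10 * k, 10 * k + 1)))
  expect_equal(discriminabilityIndex(sep)$di, 4.0)

  ## invariances: level-axis reversal and trial duplication
  set.seed(4)
  counts <- matrix(rpois(9 * 10, seq(1, 9)), nrow = 9)
  d0 <- discriminabilityIndex(counts)$di
  expect_equal(discriminabilityIndex(counts[9:1, ])$di, d0)
  expect_equal(discriminabilityIndex(cbind(counts, counts))$di, d0)
})

test_that("stronger level dependence raises, gain below 1 lowers, the DI", {
  ## expected DI is non-decreasing in RLF slope at fixed noise
  meanDI <- function(archetype, seeds) {
    mean(vapply(seeds, function(s)
      analyzeRLF(makeRLF(archetype, nTrials = 20, seed = s))@di, numeric(1)))
  }
  shallow <- rlfArchetype("straight", threshold = 10, maxRate = 2,
                          spontRate = 0.2)
  steep <- rlfArchetype("straight", threshold = 10, maxRate = 6,
                        spontRate = 0.2)
  expect_gt(meanDI(steep, 1:120), meanDI(shallow, 1:120))

  ## one-sided sign test across >= 50 paired replicates for gain 0.6
  ctl <- rlfArchetype("saturating", threshold = 25, dynamicRange = 30)
  dea <- applyDeactivation(ctl, deactivationEffect(gain = 0.6))
  drop <- vapply(1:60, function(s)
    analyzeRLF(makeRLF(ctl, 20, seed = s))@di -
      analyzeRLF(makeRLF(dea, 20, seed = s + 5000))@di, numeric(1))
  expect_lt(binom.test(sum(drop > 0), length(drop),
                       alternative = "greater")$p.value, 0.01)
})

test_that("noiseless archetypes reproduce their monotonicity labels", {
  set.seed(21)
  for (type in c("straight", "saturating", "monotonic", "nonmonotonic")) {
    for (k in 1:5) {
      a <- icresp:::.sampleRLFArchetype(type)
      mu <- rev(expectedRLFRates(a))   # quiet to loud
      expect_equal(classifyMonotonicity(mu), type == "nonmonotonic",
                   info = type)
    }
  }
})

test_that("full RLF analysis reports SPL coordinates and type", {
  rlf <- makeRLF(rlfArchetype("saturating", threshold = 25,
                              dynamicRange = 30, spontRate = 0.1),
                 nTrials = 200, seed = 12)
  m <- analyzeRLF(rlf)
  expect_equal(m@typeLabel, "saturating")
  expect_equal(m@levelCoordinate, "spl")
  ## true half-max of the expected curve: drive 0.5 at 25 + 15 dB SPL
  expect_lt(abs(m@halfMaxLevel - 40), 5)
  expect_length(m@pairAUCs, 8L)
  expect_true(all(m@pairAUCs >= 0 & m@pairAUCs <= 1))
  expect_lte(m@di, 4)
})
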