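test_that("expected rate surfaces follow the archetype geometry", {
  g <- fraGrid(4000)
  lv <- soundLevels(g)

  v <- fraArchetype("V", cf = 4000, minThreshold = 80)
  s <- expectedRateSurface(v, g)
  iCF <- which.min(abs(toneFrequencies(g) - 4000))
  expect_equal(s$expected[iCF, which(lv == 75)], v@drivenRate)  # louder
  expect_equal(s$expected[iCF, which(lv == 85)], v@spontRate)   # quieter

  cl <- fraArchetype("closed", cf = 4000, minThreshold = 80,
                     closedUpperBound = 50)
  sc <- expectedRateSurface(cl, g)
  expect_equal(sc$expected[iCF, which(lv == 45)], cl@spontRate)
  expect_equal(sc$expected[iCF, which(lv == 55)], cl@drivenRate)

  nw <- fraArchetype("narrow", cf = 4000, bandwidthCap = 0.3)
  sn <- expectedRateSurface(nw, g)
  expect_lte(sum(colSums(t(sn$mask)) > 0), 7)  # excitatory columns of 51

  expect_error(expectedRateSurface(fraArchetype("V", cf = 100), g),
               "does not cover")
})

test_that("deactivation transforms archetype parameters analytically", {
  cl <- fraArchetype("closed", cf = 4000, minThreshold = 80,
                     closedUpperBound = 55)
  expect_equal(applyDeactivation(cl, deactivationEffect()), cl)

  halved <- applyDeactivation(cl, deactivationEffect(gain = 0.5))
  expect_equal(halved@drivenRate, cl@drivenRate * 0.5)

  ## areaScale = 2 doubles the excitatory bin count (up to discretisation)
  g <- fraGrid(4000)
  doubled <- applyDeactivation(cl, deactivationEffect(areaScale = 2))
  n1 <- sum(expectedRateSurface(cl, g)$mask)
  n2 <- sum(expectedRateSurface(doubled, g)$mask)
  rows <- sum(soundLevels(g) >= 55 & soundLevels(g) <= 80)
  cols <- max(colSums(expectedRateSurface(doubled, g)$mask) > 0)
  expect_lte(abs(n2 - 2 * n1), rows + sum(cols))

  expect_error(applyDeactivation(fraArchetype("V"),
                                 deactivationEffect(areaScale = 2)),
               "V archetypes")
})

test_that("Poisson trial sampling is seeded and unbiased", {
  g1 <- stimulusGrid(1000, 10)
  zero <- sampleTrials(matrix(0, 1, 1), g1, nTrials = 100, seed = 1)
  expect_true(all(spikeCounts(zero) == 0))

  lam <- sampleTrials(matrix(5, 1, 1), g1, nTrials = 10000, seed = 2)
  expect_lt(abs(mean(spikeCounts(lam)) - 5), 3 * sqrt(5 / 10000))

  g <- fraGrid(4000)
  s <- expectedRateSurface(fraArchetype("V", cf = 4000), g)
  a <- sampleTrials(s, g, seed = 7)
  b <- sampleTrials(s, g, seed = 7)
  expect_identical(spikeCounts(a), spikeCounts(b))
  expect_false(identical(spikeCounts(a),
                         spikeCounts(sampleTrials(s, g, seed = 8))))
  expect_error(sampleTrials(s, g, nTrials = 0), ">= 1")
})

test_that("RLF archetype curves match their construction", {
  spl <- rev(100 - rlfLevels())   # quiet to loud

  nm <- rlfArchetype("nonmonotonic", threshold = 20, dynamicRange = 30,
                     bestLevel = 60, reductionFraction = 0.3,
                     maxRate = 5, spontRate = 0)
  mu <- rev(expectedRLFRates(nm))
  peak <- max(mu)
  expect_equal(mu[length(mu)], peak * (1 - 0.3))

  sat <- rlfArchetype("saturating", threshold = 25, dynamicRange = 30,
                      spontRate = 0)
  expect_true(all(diff(rev(expectedRLFRates(sat))) >= 0))

  st <- rlfArchetype("straight", threshold = 10, spontRate = 0)
  muS <- rev(expectedRLFRates(st))
  expect_lt(max(abs(diff(diff(muS)))), 1e-9)  # linear in dB

  expect_error(rlfArchetype("sigmoid"), "type")
  expect_error(makeRLF(sat, nTrials = 0), ">= 1")
})

test_that("population generation is deterministic with analytic truth", {
  expect_length(makePopulation(populationConfig(nV = 0, nNonV = 0,
                                                nRLF = 0))$triplets, 0)

  cfg <- populationConfig(nV = 4, nNonV = 4, nRLF = 5, nBoth = 2, seed = 11)
  p1 <- makePopulation(cfg)
  p2 <- makePopulation(cfg)
  expect_identical(p1$ledger, p2$ledger)
  expect_identical(spikeCounts(p1$triplets[[1L]]@fra$control),
                   spikeCounts(p2$triplets[[1L]]@fra$control))

  ## V units never have their area rescaled
  big <- makePopulation(populationConfig(nV = 10, nNonV = 10, nRLF = 0,
                                         nBoth = 0, seed = 3))
  expect_true(all(big$ledger$area_scale[big$ledger$fra_class == "V"] == 1))
  expect_true(any(big$ledger$area_scale[big$ledger$fra_class == "nonV"] != 1))

  ## recovery re-samples the control archetype: fresh noise, same surface
  tr <- big$triplets[[1L]]
  expect_false(identical(spikeCounts(tr@fra$control),
                         spikeCounts(tr@fra$recovery)))
  u <- big$archetypes[[1L]]
  g <- tr@fra$control@grid
  mu <- expectedRateSurface(u$control, g)$expected
  for (cond in c("control", "recovery")) {
    tot <- totalSpikes(tr@fra[[cond]])
    expect_lt(abs(tot - sum(mu)), 4 * sqrt(sum(mu)))
  }
})
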