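test_that("long-table reading validates and totals counts", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- expand.grid(frequency = c(1000, 2000), level = c(10, 15),
                     trial = 1)
  tab$count <- 0:3
  write.csv(tab, path, row.names = FALSE)
  rg <- readResponseGrid(path)
  expect_equal(totalSpikes(rg), 6)
  expect_equal(toneFrequencies(rg), c(1000, 2000))

  ## a missing cell is an error, never a silent zero
  write.csv(tab[-2L, ], path, row.names = FALSE)
  expect_error(readResponseGrid(path), "incomplete grid")

  ## malformed value names the offending line
  tab2 <- tab
  tab2$count <- as.character(tab2$count)
  tab2$count[3L] <- "two"
  write.csv(tab2, path, row.names = FALSE)
  expect_error(readResponseGrid(path), "malformed value.*line")

  ## negative and fractional counts rejected
  tab3 <- tab; tab3$count[1L] <- -1
  write.csv(tab3, path, row.names = FALSE)
  expect_error(readResponseGrid(path), "non-negative integers")
})

test_that("response grids round-trip bit-exactly", {
  g <- fraGrid(4000, calibration = NULL)
  counts <- array(rpois(51 * 17 * 2, 1), c(51, 17, 2))
  rg <- responseGrid(g, counts)
  for (ext in c(".tsv", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    writeResponseGrid(rg, path)
    back <- readResponseGrid(path)
    expect_identical(spikeCounts(back), spikeCounts(rg) * 1)
    expect_equal(soundLevels(back), soundLevels(rg))
  }
})

test_that("rate-level functions round-trip and validate trial structure", {
  rlf <- makeRLF(rlfArchetype("saturating"), nTrials = 20, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRateLevelFunction(rlf, path)
  back <- readRateLevelFunction(path, frequency = 4000, calibration = 100)
  expect_equal(spikeCounts(back), spikeCounts(rlf))

  ## unequal trials per level rejected
  tab <- expand.grid(level = c(10, 20), trial = 1:2)
  tab$count <- 1
  tab <- tab[-4L, ]
  write.table(tab, path, sep = "\t", row.names = FALSE)
  expect_error(readRateLevelFunction(path, 4000), "same trials")

  expect_error(rateLevelFunction(4000, c(10, 20),
                                 matrix(1, 2, 10), standardTrials = c(20, 50)),
               "not in the permitted set")
})

test_that("container validity rejects malformed objects", {
  expect_error(stimulusGrid(c(2000, 1000), c(10, 20)), "increasing")
  expect_error(stimulusGrid(c(1000, 2000), c(20, 10)), "increasing")
  g <- stimulusGrid(c(1000, 2000), c(10, 15))
  expect_error(responseGrid(g, array(-1, c(2, 2, 1))), "non-negative")
  expect_error(responseGrid(g, array(0, c(3, 2, 1))), "match the stimulus")
  expect_error(unitRecord("u1", 4000, fraClass = "W"), "fraClass")
  rg <- responseGrid(g, array(0:3, c(2, 2, 1)))
  expect_error(conditionTriplet(unitRecord("u1", 4000),
                                fra = list(deactivated = rg)),
               "control")
})

test_that("results tables round-trip with provenance sidecar", {
  path <- withr::local_tempfile(fileext = ".tsv")

  ## empty collection -> header-only table
  writeResults(list(), path)
  empty <- readResults(path)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("cf", "threshold", "area_bins", "total_spikes") %in%
                    names(empty)))

  fra <- noiselessFRA(fraArchetype("V", cf = 4000))
  res <- analyzeFRA(fra)
  writeResults(list(u1 = res), path, config = list(a = 1), seed = 42)
  tab <- readResults(path)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$cf, res@cf)
  expect_equal(tab$area_bins, res@areaBins)
  expect_equal(tab$total_spikes, res@totalSpikes)

  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 42)
  expect_equal(side$config_hash, configHash(list(a = 1)))

  ## identical config -> identical hash; different config -> different
  expect_identical(configHash(list(a = 1)), configHash(list(a = 1)))
  expect_false(identical(configHash(list(a = 1)), configHash(list(a = 2))))
})

test_that("unit metadata round-trips through JSON", {
  units <- list(unitRecord("u1", 4000),
                unitRecord("u2", 2500, fraClass = "nonV",
                           subtype = "closed", deactivationMethod = "MDP"))
  path <- withr::local_tempfile(fileext = ".json")
  writeUnitRecords(units, path)
  back <- readUnitRecords(path)
  expect_equal(back, units)
})
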