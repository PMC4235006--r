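## Shared fixtures, built in code.

## tiny 2 x 2 x 1 grid with counts 0,1,2,3 (column-major fill)
tinyGrid <- function() {
  g <- stimulusGrid(c(1000, 2000), c(10, 15))
  responseGrid(g, array(0:3, c(2, 2, 1)))
}

## noiseless ResponseGrid from an archetype (counts = expected rates)
noiselessFRA <- function(archetype, grid = fraGrid(archetype@cf)) {
  responseGrid(grid, expectedRateSurface(archetype, grid)$expected)
}

## brute-force ROC area: all ordered pairs, ties counted 1/2
bruteAUC <- function(lo, hi) {
  wins <- outer(lo, hi, function(a, b) (b > a) + 0.5 * (b == a))
  mean(wins)
}

## RateLevelFunction from a quiet-to-loud list of per-level trial counts
rlfFromCounts <- function(countsQuietToLoud, calibration = 100) {
  n <- length(countsQuietToLoud)
  levels <- seq(10, by = 10, length.out = n)       # attenuation, loud last
  counts <- do.call(rbind, rev(countsQuietToLoud)) # row 1 = loudest
  rateLevelFunction(4000, levels, counts, calibration)
}
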