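## Rate-level function analysis: per-level rate statistics, the 25%
## non-monotonicity rule, rule-based type labels, half-maximum level, and
## the ROC-based Discriminability Index (DI).
##
## All per-level vectors in this module are ordered from the QUIETEST to the
## LOUDEST level; `analyzeRLF()` handles the reordering from the stored
## attenuation axis.

#' Per-level rate statistics of an RLF
#'
#' Trial mean (authoritative for classification and half-max) plus median
#' and IQR (type-7 quantiles, for reporting), per level in the stored
#' (attenuation-ascending) order.
#'
#' @param rlf a [RateLevelFunction-class].
#' @return data frame with `level` (dB attenuation), `mean`, `median`,
#'   `iqr`.
#' @export
rlfRates <- function(rlf) {
  stopifnot(is(rlf, "RateLevelFunction"))
  data.frame(level = rlf@levels,
             mean = rowMeans(rlf@counts),
             median = apply(rlf@counts, 1L, stats::median),
             iqr = apply(rlf@counts, 1L, stats::IQR))
}

#' The 25% non-monotonicity rule
#'
#' An RLF is non-monotonic when firing at some level louder than the best
#' level drops by 25% or more from the maximum (the boundary counts). Under
#' tied maxima the best level is the quietest tied level, so louder tied
#' levels can still trigger the rule.
#'
#' @param rates per-level mean rates, quietest to loudest.
#' @param fraction required fractional reduction (default 0.25).
#' @return logical; `FALSE` (monotonic-flat) when the maximum rate is 0.
#' @examples
#' classifyMonotonicity(c(0, 10, 40, 28))  # 30% drop -> TRUE
#' classifyMonotonicity(c(0, 10, 40, 32))  # 20% drop -> FALSE
#' @export
classifyMonotonicity <- function(rates, fraction = 0.25) {
  if (length(rates) < 2L) stop("need >= 2 levels")
  mx <- max(rates)
  if (mx <= 0) return(FALSE)
  best <- which(rates == mx)[1L]       # quietest tied level
  if (best == length(rates)) return(FALSE)
  above <- rates[(best + 1L):length(rates)]
  min(above) / mx <= (1 - fraction) + 1e-12
}

#' Rule-based RLF type label
#'
#' One of five types, by precedence: `flat` (dynamic range below
#' `flatFloor` spikes/trial), `nonmonotonic` (the 25% rule), `saturating`
#' (the two or more loudest levels within `plateauTolerance` of the
#' maximum), `straight` (linear fit in dB explains >= `r2Straight` of the
#' variance), else `monotonic`. The threshold constants are named
#' configuration values, not recorded-data facts.
#'
#' @param rates per-level mean rates, quietest to loudest.
#' @param levels level axis in dB (same order); defaults to an equal-step
#'   axis, which leaves the linear-fit R^2 unchanged.
#' @param nonmonoFraction reduction fraction of the non-monotonicity rule.
#' @param plateauTolerance fractional tolerance of the saturation plateau.
#' @param r2Straight variance-explained bound of the straight label.
#' @param flatFloor dynamic-range floor, spikes/trial.
#' @return type label string.
#' @export
classifyRLF <- function(rates, levels = seq_along(rates),
                        nonmonoFraction = 0.25, plateauTolerance = 0.10,
                        r2Straight = 0.95, flatFloor = 1) {
  if (length(rates) < 3L) stop("need >= 3 levels")
  mx <- max(rates)
  if (mx <= 0 || diff(range(rates)) < flatFloor) return("flat")
  if (classifyMonotonicity(rates, nonmonoFraction)) return("nonmonotonic")
  nearMax <- rates >= (1 - plateauTolerance) * mx - 1e-12
  run <- 0L
  for (i in rev(seq_along(rates))) {
    if (nearMax[i]) run <- run + 1L else break
  }
  if (run >= 2L) return("saturating")
  fit <- stats::lm.fit(cbind(1, levels), rates)
  r2 <- 1 - sum(fit$residuals^2) / sum((rates - mean(rates))^2)
  if (r2 >= r2Straight) return("straight")
  "monotonic"
}

#' Half-maximum sound level of an RLF
#'
#' Rates are normalised to their maximum; the half-maximum level is the
#' first crossing of 0.5 from the quiet end, linearly interpolated between
#' adjacent sampled levels. When the quietest sampled level already reaches
#' half maximum, that level is returned.
#'
#' @param rates per-level mean rates, quietest to loudest.
#' @param levels level axis in dB, same order.
#' @return level in dB at the crossing.
#' @examples
#' halfMaxLevel(seq(0, 100, length.out = 9), seq(0, 80, 10))  # 40
#' @export
halfMaxLevel <- function(rates, levels) {
  stopifnot(length(rates) == length(levels), length(rates) >= 2L)
  mx <- max(rates)
  if (mx <= 0) stop("half-maximum level undefined: maximum rate is 0")
  norm <- rates / mx
  if (norm[1L] >= 0.5) return(levels[1L])
  i <- which(norm >= 0.5)[1L]
  levels[i - 1L] + (0.5 - norm[i - 1L]) / (norm[i] - norm[i - 1L]) *
    (levels[i] - levels[i - 1L])
}

#' ROC area between two spike-count distributions
#'
#' The probability that a random draw from `countsHi` exceeds one from
#' `countsLo`, ties counted 1/2 — computed through the rank-sum (U
#' statistic) identity, exactly equivalent to the all-pairs comparison.
#'
#' @param countsLo,countsHi trial spike counts of the two stimuli.
#' @return AUC in [0, 1].
#' @examples
#' rocAUC(c(0, 1, 2), c(1, 2, 3))  # 7/9
#' @export
rocAUC <- function(countsLo, countsHi) {
  nLo <- length(countsLo); nHi <- length(countsHi)
  if (nLo < 1L || nHi < 1L) stop("both samples must be non-empty")
  r <- rank(c(countsLo, countsHi))   # mid-ranks share ties equally
  u <- sum(r[(nLo + 1L):(nLo + nHi)]) - nHi * (nHi + 1) / 2
  u / (nLo * nHi)
}

#' Discriminability Index of an RLF
#'
#' For every adjacent level pair, quiet to loud, the ROC area between the
#' two trial-count distributions is computed; the DI is the summed absolute
#' deviation of those areas from 0.5, quantifying how well an ideal
#' observer could decode sound-level changes from firing along the RLF.
#' The plain summed AUC is retained as a diagnostic.
#'
#' @param rlf a [RateLevelFunction-class], or a levels x trials count
#'   matrix ordered quietest to loudest.
#' @return list with `pairAUCs` (quiet to loud), `di` and `sumAUC`.
#' @export
discriminabilityIndex <- function(rlf) {
  counts <- if (is(rlf, "RateLevelFunction"))
    rlf@counts[order(rlf@levels, decreasing = TRUE), , drop = FALSE]
  else rlf
  if (nrow(counts) < 2L) stop("need >= 2 levels")
  aucs <- vapply(seq_len(nrow(counts) - 1L), function(i)
    rocAUC(counts[i, ], counts[i + 1L, ]), numeric(1))
  list(pairAUCs = aucs, di = sum(abs(aucs - 0.5)), sumAUC = sum(aucs))
}

#' Full RLF analysis
#'
#' Classification (type label and the 25% rule), half-maximum level and
#' Discriminability Index of one rate-level function. Levels are reported
#' in dB SPL when the RLF carries a calibration, else in dB attenuation.
#'
#' @param rlf a [RateLevelFunction-class].
#' @param nonmonoFraction reduction fraction of the non-monotonicity rule.
#' @param plateauTolerance,r2Straight,flatFloor see [classifyRLF()].
#' @return an [RLFMetrics-class].
#' @export
analyzeRLF <- function(rlf, nonmonoFraction = 0.25, plateauTolerance = 0.10,
                       r2Straight = 0.95, flatFloor = 1) {
  stopifnot(is(rlf, "RateLevelFunction"))
  ord <- order(rlf@levels, decreasing = TRUE)  # quietest first
  counts <- rlf@counts[ord, , drop = FALSE]
  rates <- rowMeans(counts)
  calib <- rlf@calibration
  levelsOut <- if (is.null(calib)) rlf@levels[ord] else
    splFromAttenuation(rlf@levels[ord], calib)
  coord <- if (is.null(calib)) "attenuation" else "spl"

  mx <- max(rates)
  label <- classifyRLF(rates, levelsOut, nonmonoFraction, plateauTolerance,
                       r2Straight, flatFloor)
  nonmono <- classifyMonotonicity(rates, nonmonoFraction)
  best <- if (mx > 0) levelsOut[which(rates == mx)[1L]] else NA_real_
  halfMax <- if (mx > 0) halfMaxLevel(rates, levelsOut) else NA_real_
  dis <- discriminabilityIndex(counts)

  new("RLFMetrics", typeLabel = label, isNonmonotonic = nonmono,
      maxRate = mx, bestLevel = best, halfMaxLevel = halfMax,
      pairAUCs = dis$pairAUCs, di = dis$di, sumAUC = dis$sumAUC,
      levelCoordinate = coord)
}
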