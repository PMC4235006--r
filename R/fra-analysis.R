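## FRA metric extraction: spontaneous-rate estimate, 2-SD excitatory mask,
## per-frequency excitatory thresholds, polynomial frequency tuning curve
## (FTC), CF/threshold at its minimum, response area, total spikes.
##
## Sound levels are stored as dB attenuation; tuning-curve fitting and
## CF/threshold extraction work in a "threshold level" coordinate where
## smaller = more sensitive (dB SPL when a calibration exists, negated
## attenuation otherwise), so the FTC minimum is always the sensitivity peak.

#' Estimate the spontaneous rate of an FRA
#'
#' Mean and standard deviation of the per-presentation spike counts at the
#' quietest stimulation level (the highest attenuation row), pooled over all
#' frequencies and trials. No silence condition is used.
#'
#' @param fra a [ResponseGrid-class].
#' @return list with `mean`, `sd` (sample SD, 0 when only one value) and
#'   `nBins` (number of frequencies in the row).
#' @export
estimateSpontaneous <- function(fra) {
  stopifnot(is(fra, "ResponseGrid"))
  lev <- fra@grid@levels
  quietest <- which.max(lev)          # largest attenuation = quietest
  vals <- as.vector(fra@counts[, quietest, , drop = FALSE])
  s <- if (length(vals) > 1L) stats::sd(vals) else 0
  list(mean = mean(vals), sd = s, nBins = length(fra@grid@frequencies))
}

#' Excitatory-response mask of an FRA
#'
#' A bin is excitatory iff its mean count across trials strictly exceeds
#' `spont$mean + sdMultiplier * spont$sd`. With zero spontaneous variance
#' this means any firing above the spontaneous mean counts.
#'
#' @param fra a [ResponseGrid-class].
#' @param spont spontaneous estimate from [estimateSpontaneous()] (computed
#'   from `fra` when omitted).
#' @param sdMultiplier criterion multiplier (default 2).
#' @return logical frequency x level matrix.
#' @export
excitatoryMask <- function(fra, spont = estimateSpontaneous(fra),
                           sdMultiplier = 2) {
  meanCounts <- rowMeans(fra@counts, dims = 2L)
  meanCounts > spont$mean + sdMultiplier * spont$sd
}

#' Largest connected component of an excitatory mask
#'
#' With one presentation per bin, the 2-SD criterion flags a few percent of
#' purely spontaneous bins, which scatters spurious per-frequency
#' thresholds across the flanks and corrupts the tuning-curve fit. The
#' excitatory response area proper is the largest 8-connected
#' supra-criterion region; this filter keeps it and drops isolated noise
#' bins. It is the identity on a noiseless surface, whose region is a
#' single component.
#'
#' @param mask logical matrix from [excitatoryMask()].
#' @return logical matrix of the same shape.
#' @export
cleanMask <- function(mask) {
  if (!any(mask)) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  di <- rep(-1:1, times = 3)[-5]; dj <- rep(-1:1, each = 3)[-5]
  comp <- matrix(0L, nr, nc)
  cur <- 0L
  for (seed in which(mask)) {
    if (comp[seed] != 0L) next
    cur <- cur + 1L
    comp[seed] <- cur
    frontier <- seed
    while (length(frontier)) {       # breadth-first, one level per pass
      i <- (frontier - 1L) %% nr + 1L
      j <- (frontier - 1L) %/% nr + 1L
      ii <- rep(i, times = 8L) + rep(di, each = length(i))
      jj <- rep(j, times = 8L) + rep(dj, each = length(j))
      ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
      idx <- unique((jj[ok] - 1L) * nr + ii[ok])
      idx <- idx[mask[idx] & comp[idx] == 0L]
      comp[idx] <- cur
      frontier <- idx
    }
  }
  sizes <- tabulate(comp[mask], nbins = cur)
  mask & comp == which.max(sizes)
}

#' Per-frequency excitatory thresholds
#'
#' For each frequency, the quietest level (largest attenuation) whose bin is
#' excitatory; `NA` for frequencies with no excitatory bin.
#'
#' @param mask logical matrix from [excitatoryMask()].
#' @param levels the dB attenuation axis of the mask's columns.
#' @return numeric vector of dB attenuation thresholds (with `NA`s).
#' @export
excitatoryThresholds <- function(mask, levels) {
  stopifnot(ncol(mask) == length(levels))
  apply(mask, 1L, function(row) {
    hit <- which(row)
    if (!length(hit)) NA_real_ else max(levels[hit])
  })
}

#' Fit the excitatory frequency tuning curve
#'
#' Least-squares polynomial (requested degree 10, clamped to one less than
#' the number of present thresholds) through the per-frequency excitatory
#' thresholds, fitted on a centred and scaled octave abscissa. Frequencies
#' with absent thresholds are excluded from the fit.
#'
#' @param thresholds per-frequency threshold levels (lower = more
#'   sensitive), `NA` for absent frequencies.
#' @param octaves abscissa in octaves re the estimated CF, one per
#'   threshold.
#' @param degree requested polynomial degree (default 10).
#' @return list: `coeffs` (intercept first), `center`, `scale`, `degree`,
#'   `span` (octave range of present thresholds), `rmse`.
#' @export
fitFTC <- function(thresholds, octaves, degree = 10L) {
  stopifnot(length(thresholds) == length(octaves))
  present <- which(!is.na(thresholds))
  if (length(present) < 2L)
    stop("fewer than 2 present thresholds: use the fallback area method")
  x <- octaves[present]; y <- thresholds[present]
  degree <- max(1L, min(degree, length(present) - 1L))
  ctr <- mean(x); scl <- stats::sd(x)
  if (!is.finite(scl) || scl == 0) scl <- 1
  z <- (x - ctr) / scl
  X <- outer(z, 0:degree, `^`)
  fit <- stats::lm.fit(X, y)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  list(coeffs = unname(co), center = ctr, scale = scl, degree = degree,
       span = range(x), rmse = sqrt(mean(fit$residuals^2)))
}

#' Evaluate a fitted FTC
#' @param fit list from [fitFTC()].
#' @param octaves abscissa values, octaves re the estimated CF.
#' @return fitted threshold levels.
#' @export
evaluateFTC <- function(fit, octaves) {
  z <- (octaves - fit$center) / fit$scale
  drop(outer(z, seq_along(fit$coeffs) - 1L, `^`) %*% fit$coeffs)
}

#' CF and threshold from the FTC minimum
#'
#' Locates the global minimum of the fitted tuning curve over the octave
#' span of present thresholds by dense evaluation (>= 100 points per octave)
#' followed by local golden-section refinement; ties break toward the lower
#' frequency.
#'
#' @param fit list from [fitFTC()].
#' @param referenceCF the frequency (Hz) at octave 0.
#' @param pointsPerOctave dense-evaluation resolution (default 200).
#' @return list with `cf` (Hz), `cfOctave` and `threshold` (level at the
#'   minimum, same coordinate as the fitted thresholds).
#' @export
extractCFThreshold <- function(fit, referenceCF, pointsPerOctave = 200L) {
  span <- fit$span
  n <- max(2L, ceiling(diff(span) * pointsPerOctave) + 1L)
  xs <- seq(span[1L], span[2L], length.out = n)
  ys <- evaluateFTC(fit, xs)
  i <- which.min(ys)            # first index on ties -> lower frequency
  lo <- xs[max(1L, i - 1L)]; hi <- xs[min(n, i + 1L)]
  refine <- stats::optimize(function(x) evaluateFTC(fit, x),
                            lower = lo, upper = hi)
  best <- if (refine$objective < ys[i])
    c(refine$minimum, refine$objective) else c(xs[i], ys[i])
  list(cf = referenceCF * 2^best[1L], cfOctave = best[1L],
       threshold = best[2L])
}

#' FRA response area within the FTC classifier
#'
#' Counts the frequency-level bins at or above (louder than) the fitted
#' tuning curve at their frequency, restricted to frequencies whose
#' threshold was present.
#'
#' @param fra a [ResponseGrid-class].
#' @param fit list from [fitFTC()] (in the threshold-level coordinate
#'   implied by `calibration`).
#' @param present logical vector marking frequencies with present
#'   thresholds.
#' @param calibration maximum output in dB SPL, or `NULL` (negated
#'   attenuation coordinate).
#' @return integer bin count.
#' @export
fraArea <- function(fra, fit, present, calibration = fra@grid@calibration) {
  grid <- fra@grid
  x <- octavesRe(grid@frequencies, .gridReference(fra))
  fitted <- evaluateFTC(fit, x)
  binLevel <- if (is.null(calibration)) -grid@levels else
    calibration - grid@levels
  ## each bin stands for a level band of one grid step; it is inside the
  ## classifier when its band reaches the fitted curve (half-step rule,
  ## symmetric to sub-step fitting error)
  half <- if (length(grid@levels) > 1L)
    stats::median(diff(grid@levels)) / 2 else 0
  inside <- outer(fitted, binLevel, function(th, lv) lv + half >= th)
  sum(inside[present, , drop = FALSE])
}

## Octave-origin reference of a grid. The recovered CF in Hz is invariant
## to this choice (cf = ref * 2^x_min with x = log2(f/ref)); the geometric
## midpoint just keeps the fitted abscissa well centred.
.gridReference <- function(fra) {
  f <- fra@grid@frequencies
  sqrt(min(f) * max(f))
}

#' Fallback FRA area by spike-count criterion
#'
#' For FRAs the polynomial FTC does not reflect well, the area is the number
#' of bins whose summed spike count across trials strictly exceeds a
#' criterion (1 spike per bin as standard).
#'
#' @param fra a [ResponseGrid-class].
#' @param spikeCriterion integer criterion (default 1).
#' @return integer bin count.
#' @export
fraAreaFallback <- function(fra, spikeCriterion = 1L) {
  if (spikeCriterion < 0) stop("spikeCriterion must be >= 0")
  sums <- apply(fra@counts, c(1L, 2L), sum)
  sum(sums > spikeCriterion)
}

#' Full FRA analysis of one response grid
#'
#' Runs the complete chain: spontaneous estimate, excitatory mask,
#' per-frequency thresholds, polynomial FTC, CF/threshold at the FTC
#' minimum, area within the FTC, raw-mask bin count and total spikes. When
#' the polynomial path is unavailable (fewer than two present thresholds) or
#' disabled, the spike-criterion fallback provides the area.
#'
#' @param fra a [ResponseGrid-class].
#' @param sdMultiplier criterion multiplier for the excitatory mask.
#' @param degree requested FTC polynomial degree.
#' @param method `"auto"` (fallback only when the polynomial path fails),
#'   `"polynomial"`, or `"fallback"` (per-unit flag for FRAs the polynomial
#'   does not reflect).
#' @param fallbackCriterion spike criterion of the fallback area.
#' @param residualLimit optional RMS-residual limit (dB); an `"auto"` fit
#'   with a worse RMSE switches to the fallback area.
#' @param clean restrict the mask to its largest connected component
#'   before threshold extraction (default `TRUE`; see [cleanMask()]).
#' @return an [FTCResult-class].
#' @examples
#' a <- fraArchetype("V", cf = 4000)
#' g <- fraGrid(4000)
#' fra <- sampleTrials(expectedRateSurface(a, g), g, seed = 7)
#' analyzeFRA(fra)
#' @export
analyzeFRA <- function(fra, sdMultiplier = 2, degree = 10L,
                       method = c("auto", "polynomial", "fallback"),
                       fallbackCriterion = 1L, residualLimit = NULL,
                       clean = TRUE) {
  method <- match.arg(method)
  stopifnot(is(fra, "ResponseGrid"))
  grid <- fra@grid
  calib <- grid@calibration
  coord <- if (is.null(calib)) "attenuation" else "spl"

  spont <- estimateSpontaneous(fra)
  mask <- excitatoryMask(fra, spont, sdMultiplier)
  if (clean) mask <- cleanMask(mask)
  thrAttn <- excitatoryThresholds(mask, grid@levels)
  ## threshold-level coordinate: smaller = more sensitive
  thrLevel <- if (is.null(calib)) -thrAttn else calib - thrAttn
  x <- octavesRe(grid@frequencies, .gridReference(fra))
  present <- !is.na(thrAttn)

  useFallback <- method == "fallback"
  fit <- NULL; cfThr <- list(cf = NA_real_, threshold = NA_real_)
  if (!useFallback) {
    fit <- tryCatch(fitFTC(thrLevel, x, degree), error = function(e) NULL)
    if (is.null(fit)) {
      if (method == "polynomial")
        stop("fewer than 2 present thresholds: use method = 'fallback'")
      useFallback <- TRUE
    }
  }
  if (!is.null(fit)) {
    cfThr <- extractCFThreshold(fit, .gridReference(fra))
    if (!useFallback && method == "auto" && !is.null(residualLimit) &&
        fit$rmse > residualLimit)
      useFallback <- TRUE
  }

  area <- if (useFallback) fraAreaFallback(fra, fallbackCriterion)
          else fraArea(fra, fit, present, calib)
  threshold <- cfThr$threshold
  if (coord == "attenuation" && is.finite(threshold))
    threshold <- -threshold  # back to dB attenuation

  new("FTCResult",
      thresholds = thrAttn,
      fit = if (is.null(fit)) list() else fit,
      cf = cfThr$cf, threshold = threshold, levelCoordinate = coord,
      areaBins = as.numeric(area), maskBins = as.numeric(sum(mask)),
      totalSpikes = sum(fra@counts),
      method = if (useFallback) "fallback" else "polynomial")
}
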