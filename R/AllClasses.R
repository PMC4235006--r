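setClassUnion("numericOrNULL", c("numeric", "NULL"))

## ---------------------------------------------------------------------------
## Stimulus and response containers
## ---------------------------------------------------------------------------

#' StimulusGrid: the frequency x level stimulus coordinate system
#'
#' Tone frequencies (Hz, strictly increasing) crossed with sound levels in dB
#' attenuation re the maximum system output (strictly increasing; larger
#' attenuation = quieter). An optional calibration (maximum output in dB SPL)
#' makes dB SPL a derived view, `SPL = calibration - attenuation`.
#'
#' The standard FRA paradigm spans -3 to +2 octaves re the estimated CF in
#' 0.1-octave steps, at 10--90 dB attenuation in 5 dB steps; the RLF paradigm
#' uses a single frequency at 10--90 dB attenuation in 10 dB steps.
#'
#' @slot frequencies numeric, Hz, strictly increasing.
#' @slot levels numeric, dB attenuation, strictly increasing.
#' @slot calibration maximum output in dB SPL (scalar) or `NULL`.
#' @aliases toneFrequencies soundLevels calibration
#' @export
setClass("StimulusGrid",
         representation(frequencies = "numeric", levels = "numeric",
                        calibration = "numericOrNULL"))

setValidity("StimulusGrid", function(object) {
  msg <- character()
  f <- object@frequencies; l <- object@levels
  if (length(f) < 1L || any(!is.finite(f)) || any(f <= 0))
    msg <- c(msg, "frequencies must be finite and positive")
  if (length(f) > 1L && any(diff(f) <= 0))
    msg <- c(msg, "frequencies must be strictly increasing")
  if (length(l) < 1L || any(!is.finite(l)))
    msg <- c(msg, "levels must be finite")
  if (length(l) > 1L && any(diff(l) <= 0))
    msg <- c(msg, "levels (dB attenuation) must be strictly increasing")
  if (!is.null(object@calibration) && length(object@calibration) != 1L)
    msg <- c(msg, "calibration must be a single maximum-output dB SPL value")
  if (length(msg)) msg else TRUE
})

#' Construct a StimulusGrid
#'
#' @param frequencies tone frequencies in Hz, strictly increasing.
#' @param levels sound levels in dB attenuation, strictly increasing.
#' @param calibration optional maximum system output in dB SPL.
#' @return a [StimulusGrid-class].
#' @examples
#' fraGrid(cf = 4000)
#' @export
stimulusGrid <- function(frequencies, levels, calibration = NULL) {
  new("StimulusGrid", frequencies = as.numeric(frequencies),
      levels = as.numeric(levels), calibration = calibration)
}

#' Default FRA stimulus grid around an estimated CF
#'
#' -3 to +2 octaves re `cf` in 1/10-octave steps; 10--90 dB attenuation in
#' 5 dB steps (51 frequencies x 17 levels).
#'
#' @param cf estimated characteristic frequency, Hz.
#' @param octaves octave offsets re `cf` (default `seq(-3, 2, 0.1)`).
#' @param levels dB attenuation values (default `seq(10, 90, 5)`).
#' @param calibration maximum output in dB SPL (default 100, a flat system).
#' @return a [StimulusGrid-class].
#' @export
fraGrid <- function(cf, octaves = seq(-3, 2, by = 0.1),
                    levels = seq(10, 90, by = 5), calibration = 100) {
  stimulusGrid(cf * 2^octaves, levels, calibration)
}

#' Default RLF level axis
#'
#' 10--90 dB attenuation in 10 dB steps (9 levels).
#' @return numeric vector of dB attenuation values.
#' @export
rlfLevels <- function() seq(10, 90, by = 10)

#' ResponseGrid: trial-wise spike counts on a stimulus grid
#'
#' Counts are stored as a frequency x level x trial array. Counts are
#' non-negative; integer-ness is enforced at the file I/O boundary (sampled
#' data are integer, noiseless expected-rate surfaces need not be).
#'
#' @slot grid a [StimulusGrid-class].
#' @slot counts numeric array, `length(frequencies) x length(levels) x nTrials`.
#' @aliases spikeCounts nTrials
#' @export
setClass("ResponseGrid",
         representation(grid = "StimulusGrid", counts = "array"))

setValidity("ResponseGrid", function(object) {
  msg <- character()
  d <- dim(object@counts)
  if (length(d) != 3L)
    msg <- c(msg, "counts must be a 3-d array (frequency x level x trial)")
  else {
    if (d[1L] != length(object@grid@frequencies) ||
        d[2L] != length(object@grid@levels))
      msg <- c(msg, "counts dimensions must match the stimulus grid")
    if (d[3L] < 1L) msg <- c(msg, "at least one trial per bin is required")
  }
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    msg <- c(msg, "counts must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a ResponseGrid
#'
#' @param grid a [StimulusGrid-class].
#' @param counts 3-d array (frequency x level x trial) or a frequency x level
#'   matrix (treated as one trial).
#' @return a [ResponseGrid-class].
#' @export
responseGrid <- function(grid, counts) {
  if (is.matrix(counts)) counts <- array(counts, c(dim(counts), 1L))
  new("ResponseGrid", grid = grid, counts = counts)
}

#' RateLevelFunction: per-level trial spike counts at CF
#'
#' Spike counts to repeated CF-tone presentations across sound levels; the
#' substrate of RLF classification, half-maximum and ROC analyses. Every
#' level carries the same number of trials (20 or 50 in the standard
#' paradigm).
#'
#' @slot frequency CF tone frequency, Hz.
#' @slot levels dB attenuation, strictly increasing.
#' @slot counts numeric matrix, levels x trials.
#' @slot calibration maximum output in dB SPL (scalar) or `NULL`.
#' @export
setClass("RateLevelFunction",
         representation(frequency = "numeric", levels = "numeric",
                        counts = "matrix", calibration = "numericOrNULL"))

setValidity("RateLevelFunction", function(object) {
  msg <- character()
  if (!isScalarNumber(object@frequency) || object@frequency <= 0)
    msg <- c(msg, "frequency must be a single positive number")
  if (length(object@levels) < 2L || any(diff(object@levels) <= 0))
    msg <- c(msg, "levels must be >= 2 strictly increasing attenuation values")
  if (nrow(object@counts) != length(object@levels))
    msg <- c(msg, "counts must have one row per level")
  if (ncol(object@counts) < 1L)
    msg <- c(msg, "at least one trial per level is required")
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    msg <- c(msg, "counts must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a RateLevelFunction
#'
#' @param frequency CF tone frequency, Hz.
#' @param levels dB attenuation values, strictly increasing.
#' @param counts levels x trials matrix of spike counts.
#' @param calibration optional maximum output in dB SPL.
#' @param standardTrials permitted trial counts; a trial count outside this
#'   set is rejected (set `NULL` to allow any).
#' @return a [RateLevelFunction-class].
#' @export
rateLevelFunction <- function(frequency, levels, counts, calibration = NULL,
                              standardTrials = NULL) {
  if (!is.null(standardTrials) && !(ncol(counts) %in% standardTrials))
    stop("trial count ", ncol(counts), " not in the permitted set {",
         paste(standardTrials, collapse = ", "), "}")
  new("RateLevelFunction", frequency = as.numeric(frequency),
      levels = as.numeric(levels), counts = counts, calibration = calibration)
}

## ---------------------------------------------------------------------------
## Unit metadata and paired-condition container
## ---------------------------------------------------------------------------

#' UnitRecord: metadata of one single unit
#'
#' @slot unitId identifier.
#' @slot estimatedCF estimated characteristic frequency, Hz (used to centre
#'   the FRA grid; the analysed CF comes from the FTC minimum).
#' @slot fraClass `"V"` or `"nonV"`.
#' @slot subtype nonV subtype (`"low-tilt"`, `"narrow"`, `"closed"`,
#'   `"broad"`, ...), empty for V units.
#' @slot deactivationMethod `"cooling"` or `"MDP"`.
#' @export
setClass("UnitRecord",
         representation(unitId = "character", estimatedCF = "numeric",
                        fraClass = "character", subtype = "character",
                        deactivationMethod = "character"))

setValidity("UnitRecord", function(object) {
  msg <- character()
  if (!object@fraClass %in% c("V", "nonV"))
    msg <- c(msg, "fraClass must be 'V' or 'nonV'")
  if (object@fraClass == "V" && length(object@subtype) &&
      nzchar(object@subtype))
    msg <- c(msg, "subtype is only meaningful for nonV units")
  if (!object@deactivationMethod %in% c("cooling", "MDP"))
    msg <- c(msg, "deactivationMethod must be 'cooling' or 'MDP'")
  if (length(msg)) msg else TRUE
})

#' Construct a UnitRecord
#' @param unitId identifier.
#' @param estimatedCF estimated CF, Hz.
#' @param fraClass `"V"` or `"nonV"`.
#' @param subtype nonV subtype label (ignored for V).
#' @param deactivationMethod `"cooling"` or `"MDP"`.
#' @return a [UnitRecord-class].
#' @export
unitRecord <- function(unitId, estimatedCF, fraClass = "V", subtype = "",
                       deactivationMethod = "cooling") {
  if (identical(fraClass, "V")) subtype <- ""
  new("UnitRecord", unitId = as.character(unitId),
      estimatedCF = as.numeric(estimatedCF), fraClass = fraClass,
      subtype = subtype, deactivationMethod = deactivationMethod)
}

#' ConditionTriplet: one unit measured across conditions
#'
#' Holds the control, deactivated and recovery measurements of one unit, the
#' unit serving as its own control. Control is mandatory; all measurements
#' share the same stimulus coordinates.
#'
#' @slot unit a [UnitRecord-class].
#' @slot fra named list of [ResponseGrid-class] per condition (possibly empty).
#' @slot rlf named list of [RateLevelFunction-class] per condition (possibly
#'   empty).
#' @export
setClass("ConditionTriplet",
         representation(unit = "UnitRecord", fra = "list", rlf = "list"))

conditionNames <- c("control", "deactivated", "recovery")

.sameGrid <- function(a, b) {
  isTRUE(all.equal(a@frequencies, b@frequencies)) &&
    isTRUE(all.equal(a@levels, b@levels))
}

setValidity("ConditionTriplet", function(object) {
  msg <- character()
  for (slotname in c("fra", "rlf")) {
    m <- slot(object, slotname)
    if (!length(m)) next
    if (!all(names(m) %in% conditionNames))
      msg <- c(msg, paste0(slotname, " conditions must be among {",
                           paste(conditionNames, collapse = ", "), "}"))
    if (!"control" %in% names(m))
      msg <- c(msg, paste0(slotname, ": control condition is mandatory"))
    if (slotname == "fra" && length(m) > 1L) {
      grids <- lapply(m, function(x) x@grid)
      if (!all(vapply(grids[-1L], .sameGrid, logical(1), b = grids[[1L]])))
        msg <- c(msg, "all FRA conditions must share one stimulus grid")
    }
    if (slotname == "rlf" && length(m) > 1L) {
      lv <- lapply(m, function(x) x@levels)
      if (!all(vapply(lv[-1L], function(v) isTRUE(all.equal(v, lv[[1L]])),
                      logical(1))))
        msg <- c(msg, "all RLF conditions must share one level axis")
    }
  }
  if (!length(object@fra) && !length(object@rlf))
    msg <- c(msg, "a triplet needs at least one measurement paradigm")
  if (length(msg)) msg else TRUE
})

#' Construct a ConditionTriplet
#' @param unit a [UnitRecord-class].
#' @param fra named list of per-condition [ResponseGrid-class] objects.
#' @param rlf named list of per-condition [RateLevelFunction-class] objects.
#' @return a [ConditionTriplet-class].
#' @export
conditionTriplet <- function(unit, fra = list(), rlf = list()) {
  new("ConditionTriplet", unit = unit, fra = fra, rlf = rlf)
}

## ---------------------------------------------------------------------------
## Generative archetypes and effects
## ---------------------------------------------------------------------------

fraClasses <- c("V", "low-tilt", "narrow", "closed", "broad")
rlfTypes <- c("monotonic", "saturating", "straight", "nonmonotonic", "flat")

#' FRAArchetype: parametric generative model of a frequency response area
#'
#' The excitatory region of a V archetype is everything louder than a
#' V-shaped threshold contour in octave x attenuation space: two linear
#' flanks meeting at `(cf, minThreshold)`, descending in attenuation at
#' `slopeLow`/`slopeHigh` dB per octave away from CF. nonV variants deform
#' this contour: `narrow` clips the excitatory bandwidth, `closed` adds an
#' upper (loud) level bound, `low-tilt` skews the threshold trough by a
#' linear tilt, `broad` is a V with shallow flank slopes. Expected response
#' is `drivenRate` spikes/presentation inside the region and `spontRate`
#' outside.
#'
#' @slot fraClass one of `"V"`, `"low-tilt"`, `"narrow"`, `"closed"`,
#'   `"broad"`.
#' @slot cf characteristic frequency, Hz.
#' @slot minThreshold dB attenuation of the contour trough (larger = more
#'   sensitive).
#' @slot slopeLow,slopeHigh flank slopes, dB per octave (> 0).
#' @slot closedUpperBound dB attenuation of the loud-side bound (closed
#'   only); must be louder (smaller attenuation) than `minThreshold`.
#' @slot tilt dB per octave linear skew of the contour (low-tilt only).
#' @slot bandwidthCap full excitatory bandwidth cap, octaves (narrow only).
#' @slot drivenRate expected spikes/presentation inside the region.
#' @slot spontRate expected spikes/presentation outside it.
#' @export
setClass("FRAArchetype",
         representation(fraClass = "character", cf = "numeric",
                        minThreshold = "numeric", slopeLow = "numeric",
                        slopeHigh = "numeric", closedUpperBound = "numeric",
                        tilt = "numeric", bandwidthCap = "numeric",
                        drivenRate = "numeric", spontRate = "numeric"))

setValidity("FRAArchetype", function(object) {
  msg <- character()
  if (!object@fraClass %in% fraClasses)
    msg <- c(msg, paste0("fraClass must be one of {",
                         paste(fraClasses, collapse = ", "), "}"))
  if (object@slopeLow <= 0 || object@slopeHigh <= 0)
    msg <- c(msg, "flank slopes must be positive")
  if (object@drivenRate <= object@spontRate || object@spontRate < 0)
    msg <- c(msg, "need drivenRate > spontRate >= 0")
  if (object@fraClass == "closed") {
    if (!is.finite(object@closedUpperBound) ||
        object@closedUpperBound >= object@minThreshold)
      msg <- c(msg, paste("closedUpperBound must be louder (smaller",
                          "attenuation) than minThreshold"))
  }
  if (object@fraClass == "narrow" &&
      (!is.finite(object@bandwidthCap) || object@bandwidthCap <= 0))
    msg <- c(msg, "narrow archetypes need a positive bandwidthCap")
  if (length(msg)) msg else TRUE
})

#' Construct an FRAArchetype
#'
#' @param fraClass archetype class; see [FRAArchetype-class].
#' @param cf CF, Hz.
#' @param minThreshold trough of the threshold contour, dB attenuation.
#' @param slopeLow,slopeHigh flank slopes, dB/octave.
#' @param closedUpperBound loud-side bound, dB attenuation (closed only).
#' @param tilt contour skew, dB/octave (low-tilt only).
#' @param bandwidthCap excitatory bandwidth cap, octaves (narrow only).
#' @param drivenRate,spontRate expected spikes per presentation inside /
#'   outside the excitatory region.
#' @return an [FRAArchetype-class].
#' @examples
#' a <- fraArchetype("V", cf = 4000, minThreshold = 80)
#' g <- fraGrid(4000)
#' surf <- expectedRateSurface(a, g)
#' sum(surf$mask)
#' @export
fraArchetype <- function(fraClass = "V", cf = 4000, minThreshold = 80,
                         slopeLow = 30, slopeHigh = 35,
                         closedUpperBound = NA_real_, tilt = 0,
                         bandwidthCap = NA_real_, drivenRate = 5,
                         spontRate = 0.5) {
  if (fraClass == "broad") { slopeLow <- min(slopeLow, 12); slopeHigh <- min(slopeHigh, 15) }
  if (fraClass != "low-tilt") tilt <- 0
  if (fraClass != "closed") closedUpperBound <- NA_real_
  if (fraClass != "narrow") bandwidthCap <- NA_real_
  if (fraClass == "low-tilt" && tilt == 0) tilt <- 10
  if (fraClass == "closed" && is.na(closedUpperBound))
    closedUpperBound <- minThreshold - 30
  if (fraClass == "narrow" && is.na(bandwidthCap)) bandwidthCap <- 0.5
  new("FRAArchetype", fraClass = fraClass, cf = cf,
      minThreshold = minThreshold, slopeLow = slopeLow, slopeHigh = slopeHigh,
      closedUpperBound = closedUpperBound, tilt = tilt,
      bandwidthCap = bandwidthCap, drivenRate = drivenRate,
      spontRate = spontRate)
}

#' RLFArchetype: parametric generative model of a rate-level function
#'
#' The expected rate at sound level `s` (dB SPL) is
#' `spontRate + maxRate * min(1, drive(s))`, where the drive is a
#' type-specific function of level rising from `threshold` and the `min(1, )`
#' clip is a fixed output saturation of the neuron. The five types:
#' `straight` (linear drive that stays below saturation across the tested
#' range), `saturating` (linear drive that reaches saturation within the
#' range), `monotonic` (decelerating power-law drive, no plateau in range),
#' `nonmonotonic` (rises to a best level, then falls by `reductionFraction`),
#' `flat` (no driven response).
#'
#' @slot type one of `"monotonic"`, `"saturating"`, `"straight"`,
#'   `"nonmonotonic"`, `"flat"`.
#' @slot threshold dB SPL at which the drive leaves zero.
#' @slot dynamicRange dB over which the drive reaches its nominal maximum.
#' @slot bestLevel dB SPL of peak drive (nonmonotonic only).
#' @slot reductionFraction fractional drop of expected rate above the best
#'   level (nonmonotonic only, >= 0).
#' @slot maxRate driven spikes/presentation at output saturation.
#' @slot spontRate spontaneous spikes/presentation.
#' @slot shapeExponent drive exponent; != 1 gives the curved
#'   `monotonic` shape.
#' @slot driveGain multiplicative gain on the drive before the output
#'   saturation (1 for a control archetype; deactivation rescales it).
#' @export
setClass("RLFArchetype",
         representation(type = "character", threshold = "numeric",
                        dynamicRange = "numeric", bestLevel = "numeric",
                        reductionFraction = "numeric", maxRate = "numeric",
                        spontRate = "numeric", shapeExponent = "numeric",
                        driveGain = "numeric"))

setValidity("RLFArchetype", function(object) {
  msg <- character()
  if (!object@type %in% rlfTypes)
    msg <- c(msg, paste0("type must be one of {",
                         paste(rlfTypes, collapse = ", "), "}"))
  if (object@maxRate < 0 || object@spontRate < 0)
    msg <- c(msg, "rates must be non-negative")
  if (object@dynamicRange <= 0)
    msg <- c(msg, "dynamicRange must be positive")
  if (object@type == "nonmonotonic" &&
      (!is.finite(object@reductionFraction) || object@reductionFraction < 0))
    msg <- c(msg, "nonmonotonic archetypes need reductionFraction >= 0")
  if (object@driveGain < 0)
    msg <- c(msg, "driveGain must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an RLFArchetype
#'
#' @param type RLF type label; see [RLFArchetype-class].
#' @param threshold dB SPL.
#' @param dynamicRange dB from threshold to nominal maximum drive.
#' @param bestLevel dB SPL of the peak (nonmonotonic only).
#' @param reductionFraction fractional high-level drop (nonmonotonic only).
#' @param maxRate driven spikes/presentation at saturation.
#' @param spontRate spontaneous spikes/presentation.
#' @param shapeExponent drive exponent (monotonic default 2, else 1).
#' @param driveGain gain on the drive before output saturation (default 1).
#' @return an [RLFArchetype-class].
#' @export
rlfArchetype <- function(type = "saturating", threshold = 25,
                         dynamicRange = 40, bestLevel = 60,
                         reductionFraction = 0.4, maxRate = 6,
                         spontRate = 0.3, shapeExponent = NA_real_,
                         driveGain = 1) {
  if (is.na(shapeExponent))
    shapeExponent <- if (type == "monotonic") 2 else 1
  if (type != "nonmonotonic") { reductionFraction <- 0; bestLevel <- NA_real_ }
  if (type == "straight")
    dynamicRange <- max(dynamicRange, 90 - threshold + 10)  # never saturates
  new("RLFArchetype", type = type, threshold = threshold,
      dynamicRange = dynamicRange, bestLevel = bestLevel,
      reductionFraction = reductionFraction, maxRate = maxRate,
      spontRate = spontRate, shapeExponent = shapeExponent,
      driveGain = driveGain)
}

#' DeactivationEffect: parameter-level model of contralateral deactivation
#'
#' Removing commissural input changes a unit's generative parameters:
#' a multiplicative `gain` on the driven input, `spontGain` on the
#' spontaneous rate, a `thresholdShift` in dB, and (nonV FRAs only) an
#' `areaScale` on excitatory-region extent. `nonmonoRelief` multiplies the
#' high-level reduction fraction of nonmonotonic RLF archetypes (values < 1
#' make the RLF more monotonic, emulating deactivation-induced type
#' transitions).
#'
#' @slot gain multiplicative factor on the driven input (>= 0).
#' @slot spontGain multiplicative factor on the spontaneous rate (>= 0).
#' @slot thresholdShift dB added to the archetype threshold (positive =
#'   less sensitive).
#' @slot areaScale factor on excitatory-region extent (>= 0; must be 1 for V
#'   FRAs).
#' @slot nonmonoRelief factor on the nonmonotonic reduction fraction (>= 0).
#' @export
setClass("DeactivationEffect",
         representation(gain = "numeric", spontGain = "numeric",
                        thresholdShift = "numeric", areaScale = "numeric",
                        nonmonoRelief = "numeric"))

setValidity("DeactivationEffect", function(object) {
  if (object@gain < 0 || object@spontGain < 0 || object@areaScale < 0 ||
      object@nonmonoRelief < 0)
    "gain, spontGain, areaScale and nonmonoRelief must be >= 0" else TRUE
})

#' Construct a DeactivationEffect
#' @param gain factor on the driven input.
#' @param spontGain factor on the spontaneous rate.
#' @param thresholdShift dB shift of the archetype threshold.
#' @param areaScale factor on excitatory-region extent (nonV FRAs only).
#' @param nonmonoRelief factor on the nonmonotonic reduction fraction.
#' @return a [DeactivationEffect-class].
#' @export
deactivationEffect <- function(gain = 1, spontGain = 1, thresholdShift = 0,
                               areaScale = 1, nonmonoRelief = 1) {
  new("DeactivationEffect", gain = gain, spontGain = spontGain,
      thresholdShift = thresholdShift, areaScale = areaScale,
      nonmonoRelief = nonmonoRelief)
}

## ---------------------------------------------------------------------------
## Result records
## ---------------------------------------------------------------------------

#' FTCResult: frequency-tuning-curve metrics of one FRA
#'
#' Per-frequency excitatory thresholds (2-SD criterion), the fitted
#' polynomial frequency tuning curve, the CF and threshold at its minimum,
#' the response area in bins and the total spike count.
#'
#' @slot thresholds per-frequency excitatory threshold, dB attenuation
#'   (`NA` where no bin met the criterion).
#' @slot fit list: polynomial coefficients, centring/scaling of the octave
#'   abscissa, degree used.
#' @slot cf characteristic frequency, Hz (FTC minimum).
#' @slot threshold dB at the FTC minimum, in `levelCoordinate`.
#' @slot levelCoordinate `"spl"` when a calibration exists, else
#'   `"attenuation"`.
#' @slot areaBins bins contained within the FTC classifier.
#' @slot maskBins bins of the raw 2-SD mask (diagnostic).
#' @slot totalSpikes total spikes in the FRA.
#' @slot method `"polynomial"` or `"fallback"`.
#' @export
setClass("FTCResult",
         representation(thresholds = "numeric", fit = "list", cf = "numeric",
                        threshold = "numeric", levelCoordinate = "character",
                        areaBins = "numeric", maskBins = "numeric",
                        totalSpikes = "numeric", method = "character"))

#' RLFMetrics: classification and discriminability metrics of one RLF
#'
#' @slot typeLabel one of the five RLF type labels.
#' @slot isNonmonotonic `TRUE` when some level above the best level drops
#'   the mean rate by >= 25%.
#' @slot maxRate maximum per-level mean rate, spikes/trial.
#' @slot bestLevel level of the maximum (quietest tied level), in
#'   `levelCoordinate`.
#' @slot halfMaxLevel level at which the max-normalised RLF first crosses
#'   0.5, in `levelCoordinate`.
#' @slot pairAUCs ROC areas of adjacent-level pairs, quiet to loud.
#' @slot di Discriminability Index, `sum(|AUC - 0.5|)`.
#' @slot sumAUC plain sum of the pair AUCs (diagnostic).
#' @slot levelCoordinate `"spl"` or `"attenuation"`.
#' @export
setClass("RLFMetrics",
         representation(typeLabel = "character", isNonmonotonic = "logical",
                        maxRate = "numeric", bestLevel = "numeric",
                        halfMaxLevel = "numeric", pairAUCs = "numeric",
                        di = "numeric", sumAUC = "numeric",
                        levelCoordinate = "character"))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "StimulusGrid", function(object) {
  cat(sprintf("StimulusGrid: %d frequencies (%.3g-%.3g Hz) x %d levels (%g-%g dB attn)%s\n",
              length(object@frequencies), min(object@frequencies),
              max(object@frequencies), length(object@levels),
              min(object@levels), max(object@levels),
              if (is.null(object@calibration)) "" else
                sprintf("; max output %g dB SPL", object@calibration)))
})

setMethod("show", "ResponseGrid", function(object) {
  d <- dim(object@counts)
  cat(sprintf("ResponseGrid: %d x %d bins, %d trial(s)/bin, %g spikes total\n",
              d[1L], d[2L], d[3L], sum(object@counts)))
})

setMethod("show", "RateLevelFunction", function(object) {
  cat(sprintf("RateLevelFunction at %.3g Hz: %d levels x %d trials, %g spikes\n",
              object@frequency, length(object@levels), ncol(object@counts),
              sum(object@counts)))
})

setMethod("show", "ConditionTriplet", function(object) {
  cat(sprintf("ConditionTriplet '%s' (%s%s, %s): FRA[%s] RLF[%s]\n",
              object@unit@unitId, object@unit@fraClass,
              if (nzchar(object@unit@subtype))
                paste0("/", object@unit@subtype) else "",
              object@unit@deactivationMethod,
              paste(names(object@fra), collapse = ","),
              paste(names(object@rlf), collapse = ",")))
})

setMethod("show", "FRAArchetype", function(object) {
  cat(sprintf("FRAArchetype '%s': CF %.3g Hz, trough %g dB attn, driven %g / spont %g spikes\n",
              object@fraClass, object@cf, object@minThreshold,
              object@drivenRate, object@spontRate))
})

setMethod("show", "RLFArchetype", function(object) {
  cat(sprintf("RLFArchetype '%s': threshold %g dB SPL, max %g spikes/trial\n",
              object@type, object@threshold, object@maxRate))
})

setMethod("show", "DeactivationEffect", function(object) {
  cat(sprintf("DeactivationEffect: gain %.3g, spontGain %.3g, shift %+g dB, areaScale %.3g, nonmonoRelief %.3g\n",
              object@gain, object@spontGain, object@thresholdShift,
              object@areaScale, object@nonmonoRelief))
})

setMethod("show", "FTCResult", function(object) {
  cat(sprintf("FTCResult (%s): CF %.4g Hz, threshold %.3g dB %s, area %g bins, %g spikes\n",
              object@method, object@cf, object@threshold,
              object@levelCoordinate, object@areaBins, object@totalSpikes))
})

setMethod("show", "RLFMetrics", function(object) {
  cat(sprintf("RLFMetrics: %s%s, half-max %.3g dB %s, DI %.3g (%d pairs)\n",
              object@typeLabel,
              if (object@isNonmonotonic) " (non-monotonic)" else "",
              object@halfMaxLevel, object@levelCoordinate, object@di,
              length(object@pairAUCs)))
})

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' @rdname StimulusGrid-class
setMethod("toneFrequencies", "StimulusGrid", function(x) x@frequencies)
#' @rdname StimulusGrid-class
setMethod("soundLevels", "StimulusGrid", function(x) x@levels)
#' @rdname StimulusGrid-class
setMethod("calibration", "StimulusGrid", function(x) x@calibration)
#' @rdname ResponseGrid-class
setMethod("toneFrequencies", "ResponseGrid", function(x) x@grid@frequencies)
#' @rdname ResponseGrid-class
setMethod("soundLevels", "ResponseGrid", function(x) x@grid@levels)
#' @rdname ResponseGrid-class
setMethod("calibration", "ResponseGrid", function(x) x@grid@calibration)
#' @rdname ResponseGrid-class
setMethod("spikeCounts", "ResponseGrid", function(x) x@counts)
#' @rdname ResponseGrid-class
setMethod("nTrials", "ResponseGrid", function(x) dim(x@counts)[3L])
#' @rdname RateLevelFunction-class
#' @param x a [RateLevelFunction-class].
setMethod("soundLevels", "RateLevelFunction", function(x) x@levels)
#' @rdname RateLevelFunction-class
setMethod("spikeCounts", "RateLevelFunction", function(x) x@counts)
#' @rdname RateLevelFunction-class
setMethod("nTrials", "RateLevelFunction", function(x) ncol(x@counts))
#' @rdname RateLevelFunction-class
setMethod("calibration", "RateLevelFunction", function(x) x@calibration)

#' @rdname totalSpikes
setMethod("totalSpikes", "ResponseGrid", function(x) sum(x@counts))
#' @rdname totalSpikes
setMethod("totalSpikes", "RateLevelFunction", function(x) sum(x@counts))
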