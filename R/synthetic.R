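## Synthetic populations with analytic ground truth. Effects act on
## archetype parameters (never on sampled counts), trial noise is Poisson,
## and every generator is a pure function of its seed.

#' @rdname expectedRateSurface
setMethod("expectedRateSurface", "FRAArchetype", function(archetype, grid) {
  f <- grid@frequencies
  if (archetype@cf < min(f) || archetype@cf > max(f))
    stop("stimulus grid does not cover the archetype CF")
  x <- octavesRe(f, archetype@cf)
  ## threshold contour in dB attenuation: quietest level that drives firing
  contour <- archetype@minThreshold -
    archetype@slopeLow * pmax(-x, 0) -
    archetype@slopeHigh * pmax(x, 0) +
    archetype@tilt * x
  mask <- outer(contour, grid@levels, function(thr, lev) lev <= thr)
  if (archetype@fraClass == "narrow")
    mask <- mask & (abs(x) <= archetype@bandwidthCap / 2)
  if (archetype@fraClass == "closed")
    mask <- mask & outer(rep(TRUE, length(x)), grid@levels >=
                           archetype@closedUpperBound, function(a, b) a & b)
  expected <- ifelse(mask, archetype@drivenRate, archetype@spontRate)
  dimnames(expected) <- dimnames(mask) <- NULL
  list(expected = expected, mask = mask)
})

#' @rdname applyDeactivation
setMethod("applyDeactivation", c("FRAArchetype", "DeactivationEffect"),
          function(archetype, effect) {
  if (archetype@fraClass == "V" && effect@areaScale != 1)
    stop("areaScale != 1 is not permitted for V archetypes: ",
         "V-shaped receptive-field areas are unchanged by deactivation")
  out <- archetype
  out@drivenRate <- archetype@drivenRate * effect@gain
  out@spontRate <- archetype@spontRate * effect@spontGain
  ## thresholdShift is a shift of threshold SPL (positive = less sensitive);
  ## in the attenuation coordinate that lowers the contour trough
  out@minThreshold <- archetype@minThreshold - effect@thresholdShift
  if (effect@areaScale != 1) {
    if (archetype@fraClass == "narrow") {
      out@bandwidthCap <- archetype@bandwidthCap * effect@areaScale
    } else {
      ## region area scales as 1/slope for contour-bounded classes
      out@slopeLow <- archetype@slopeLow / effect@areaScale
      out@slopeHigh <- archetype@slopeHigh / effect@areaScale
    }
  }
  validObject(out)
  out
})

#' @rdname applyDeactivation
setMethod("applyDeactivation", c("RLFArchetype", "DeactivationEffect"),
          function(archetype, effect) {
  out <- archetype
  out@driveGain <- archetype@driveGain * effect@gain
  out@spontRate <- archetype@spontRate * effect@spontGain
  out@threshold <- archetype@threshold + effect@thresholdShift
  out@reductionFraction <- archetype@reductionFraction * effect@nonmonoRelief
  validObject(out)
  out
})

#' Sample Poisson trials from an expected-count surface
#'
#' Independent Poisson draws per bin and trial; the same seed yields an
#' identical grid.
#'
#' @param expected frequency x level matrix of expected spikes per
#'   presentation (or the list returned by [expectedRateSurface()]).
#' @param grid the [StimulusGrid-class] the surface was evaluated on.
#' @param nTrials trials per bin (>= 1).
#' @param seed integer seed.
#' @return a [ResponseGrid-class].
#' @export
sampleTrials <- function(expected, grid, nTrials = 1L, seed = 1L) {
  if (is.list(expected)) expected <- expected$expected
  if (any(expected < 0)) stop("expected counts must be >= 0")
  if (nTrials < 1L) stop("nTrials must be >= 1")
  counts <- withSeed(seed, {
    array(stats::rpois(length(expected) * nTrials,
                       rep(as.vector(expected), times = nTrials)),
          c(dim(expected), nTrials))
  })
  responseGrid(grid, counts)
}

#' Noiseless expected rates of an RLF archetype
#'
#' Evaluates `spontRate + maxRate * min(1, driveGain * drive(SPL))` on a
#' level axis; see [RLFArchetype-class] for the per-type drive.
#'
#' @param archetype an [RLFArchetype-class].
#' @param levels dB attenuation axis (default [rlfLevels()]).
#' @param calibration maximum output in dB SPL (default 100).
#' @return numeric vector of expected spikes per trial, one per level.
#' @export
expectedRLFRates <- function(archetype, levels = rlfLevels(),
                             calibration = 100) {
  spl <- splFromAttenuation(levels, calibration)
  u <- .rlfDrive(archetype, spl)
  archetype@spontRate + archetype@maxRate *
    pmin(1, archetype@driveGain * u)
}

.rlfDrive <- function(a, spl) {
  rise <- pmax(0, spl - a@threshold) / a@dynamicRange
  switch(a@type,
    flat = rep(0, length(spl)),
    straight = rise,
    saturating = rise,
    monotonic = rise^a@shapeExponent,
    nonmonotonic = {
      peakRise <- pmax(0, a@bestLevel - a@threshold) / a@dynamicRange
      peak <- min(1, peakRise)
      up <- pmin(rise, peakRise) / peakRise * peak
      topSpan <- max(spl) - a@bestLevel
      fall <- ifelse(spl > a@bestLevel & topSpan > 0,
                     peak * a@reductionFraction *
                       (spl - a@bestLevel) / topSpan, 0)
      pmax(0, up - fall)
    },
    stop("unknown RLF type label: ", a@type))
}

#' Sample a rate-level function from an archetype
#'
#' Poisson trial counts around the archetype's expected rates.
#'
#' @param archetype an [RLFArchetype-class].
#' @param nTrials repetitions per level (paradigm standard: 20 or 50).
#' @param seed integer seed.
#' @param levels dB attenuation axis (default [rlfLevels()]).
#' @param calibration maximum output, dB SPL.
#' @param frequency CF tone frequency, Hz (metadata).
#' @return a [RateLevelFunction-class].
#' @export
makeRLF <- function(archetype, nTrials = 20L, seed = 1L,
                    levels = rlfLevels(), calibration = 100,
                    frequency = 4000) {
  if (nTrials < 1L) stop("nTrials must be >= 1")
  mu <- expectedRLFRates(archetype, levels, calibration)
  counts <- withSeed(seed, {
    matrix(stats::rpois(length(mu) * nTrials, rep(mu, times = nTrials)),
           nrow = length(mu))
  })
  rateLevelFunction(frequency, levels, counts, calibration)
}

## ---------------------------------------------------------------------------
## Population configuration and generation
## ---------------------------------------------------------------------------

#' PopulationConfig: study-scale synthetic population settings
#'
#' Defaults mirror the recorded dataset the analysis chain was built for:
#' 49 V and 50 nonV FRA units (FRAs from one presentation per bin on the
#' standard 51 x 17 grid), 38 RLF units (50 repetitions per level, five RLF
#' types with 12 non-monotonic), 16 units carrying both paradigms.
#'
#' @slot nV,nNonV numbers of V and nonV FRA units.
#' @slot nRLF number of RLF units.
#' @slot nBoth how many RLF units also carry an FRA (for threshold vs
#'   half-max comparisons).
#' @slot rlfComposition named integer vector over the five RLF types,
#'   summing to `nRLF`.
#' @slot fraTrials,rlfTrials trials per FRA bin / per RLF level.
#' @slot effect either a fixed [DeactivationEffect-class] applied to every
#'   unit, or `NULL` to sample per-unit effects from `effectSpread`.
#' @slot effectSpread list of spread parameters for sampled effects
#'   (log-sd of gain and spontaneous gain, dB sd of threshold shift, log-sd
#'   of nonV area scaling, range of the nonmonotonic relief factor).
#' @slot calibration maximum system output, dB SPL.
#' @slot seed integer seed; the whole population is a pure function of the
#'   configuration.
#' @export
setClass("PopulationConfig",
         representation(nV = "numeric", nNonV = "numeric", nRLF = "numeric",
                        nBoth = "numeric", rlfComposition = "numeric",
                        fraTrials = "numeric", rlfTrials = "numeric",
                        effect = "ANY", effectSpread = "list",
                        calibration = "numeric", seed = "numeric"))

setValidity("PopulationConfig", function(object) {
  msg <- character()
  if (any(c(object@nV, object@nNonV, object@nRLF, object@nBoth) < 0))
    msg <- c(msg, "unit counts must be >= 0")
  if (object@nBoth > object@nRLF)
    msg <- c(msg, "nBoth cannot exceed nRLF")
  if (!setequal(names(object@rlfComposition), rlfTypes))
    msg <- c(msg, "rlfComposition must name all five RLF types")
  else if (sum(object@rlfComposition) != object@nRLF)
    msg <- c(msg, "rlfComposition must sum to nRLF")
  if (!is.null(object@effect) && !is(object@effect, "DeactivationEffect"))
    msg <- c(msg, "effect must be NULL or a DeactivationEffect")
  if (length(msg)) msg else TRUE
})

#' Construct a PopulationConfig
#'
#' @param nV,nNonV,nRLF,nBoth unit counts (defaults 49, 50, 38, 16).
#' @param rlfComposition named counts over the five RLF types (default
#'   12 nonmonotonic, 14 saturating, 5 straight, 5 monotonic, 2 flat).
#' @param fraTrials,rlfTrials trials per FRA bin and per RLF level.
#' @param effect fixed [DeactivationEffect-class] for every unit, or `NULL`
#'   to sample per-unit effects.
#' @param effectSpread spread parameters for sampled effects; see
#'   [PopulationConfig-class].
#' @param calibration maximum output, dB SPL.
#' @param seed integer seed.
#' @return a [PopulationConfig-class].
#' @export
populationConfig <- function(nV = 49, nNonV = 50, nRLF = 38, nBoth = 16,
                             rlfComposition = c(nonmonotonic = 12,
                                                saturating = 16,
                                                straight = 4,
                                                monotonic = 4, flat = 2),
                             fraTrials = 1L, rlfTrials = 50L,
                             effect = NULL,
                             effectSpread = list(gainSdLog = 0.35,
                                                 spontGainSdLog = 0.25,
                                                 thresholdShiftSd = 3,
                                                 areaScaleSdLog = 0.7,
                                                 reliefRange = c(0.1, 1.1)),
                             calibration = 100, seed = 1L) {
  if (nRLF != 38 && sum(rlfComposition) != nRLF) {
    ## rescale the default composition to the requested size
    w <- rlfComposition / sum(rlfComposition)
    rlfComposition <- floor(w * nRLF)
    rem <- nRLF - sum(rlfComposition)
    if (rem > 0) {
      ord <- order(w * nRLF - floor(w * nRLF), decreasing = TRUE)
      rlfComposition[ord[seq_len(rem)]] <-
        rlfComposition[ord[seq_len(rem)]] + 1
    }
  }
  new("PopulationConfig", nV = nV, nNonV = nNonV, nRLF = nRLF,
      nBoth = min(nBoth, nRLF), rlfComposition = rlfComposition,
      fraTrials = fraTrials, rlfTrials = rlfTrials, effect = effect,
      effectSpread = effectSpread, calibration = calibration, seed = seed)
}

setMethod("show", "PopulationConfig", function(object) {
  cat(sprintf("PopulationConfig: %g V + %g nonV FRA units, %g RLF units (%g both), seed %g\n",
              object@nV, object@nNonV, object@nRLF, object@nBoth,
              object@seed))
})

.sampleFRAArchetype <- function(fraClass) {
  cf <- 2^stats::runif(1, log2(1000), log2(8000))
  minThr <- stats::runif(1, 70, 85)
  ## V flanks symmetric: the FTC-minimum method has an intrinsic bias
  ## toward the shallower flank of an asymmetric V (see vignette); nonV
  ## contours below are free to be asymmetric
  sLo <- stats::runif(1, 22, 32)
  sHi <- if (fraClass == "V") sLo else sLo * stats::runif(1, 1.0, 1.4)
  driven <- stats::runif(1, 4, 7)
  spont <- stats::runif(1, 0.2, 0.8)
  switch(fraClass,
    "V" = fraArchetype("V", cf, minThr, sLo, sHi, drivenRate = driven,
                       spontRate = spont),
    "low-tilt" = fraArchetype("low-tilt", cf, minThr, sLo, sHi,
                              tilt = stats::runif(1, 8, 15),
                              drivenRate = driven, spontRate = spont),
    "narrow" = fraArchetype("narrow", cf, minThr, sLo, sHi,
                            bandwidthCap = stats::runif(1, 0.3, 0.7),
                            drivenRate = driven, spontRate = spont),
    "closed" = fraArchetype("closed", cf, minThr, sLo, sHi,
                            closedUpperBound = minThr -
                              stats::runif(1, 20, 35),
                            drivenRate = driven, spontRate = spont),
    "broad" = fraArchetype("broad", cf, minThr,
                           stats::runif(1, 8, 12), stats::runif(1, 10, 15),
                           drivenRate = driven, spontRate = spont))
}

.sampleRLFArchetype <- function(type) {
  thr <- stats::runif(1, 15, 35)
  maxRate <- stats::runif(1, 4, 7)
  spont <- stats::runif(1, 0.05, 0.3)
  switch(type,
    flat = rlfArchetype("flat", threshold = thr, maxRate = maxRate,
                        spontRate = spont),
    straight = rlfArchetype("straight", threshold = thr,
                            dynamicRange = 90 - thr + 10,
                            maxRate = maxRate, spontRate = spont),
    saturating = rlfArchetype("saturating", threshold = thr,
                              dynamicRange = stats::runif(1, 25, 35),
                              maxRate = maxRate, spontRate = spont),
    monotonic = rlfArchetype("monotonic", threshold = thr,
                             dynamicRange = 90 - thr,
                             maxRate = maxRate, spontRate = spont,
                             shapeExponent = stats::runif(1, 1.8, 2.4)),
    nonmonotonic = rlfArchetype("nonmonotonic", threshold = thr,
                                dynamicRange = stats::runif(1, 25, 40),
                                bestLevel = stats::runif(1, 55, 70),
                                reductionFraction =
                                  stats::runif(1, 0.35, 0.8),
                                maxRate = maxRate, spontRate = spont))
}

.sampleEffect <- function(spread, fraClass = "V", rlfType = NA_character_) {
  areaScale <- if (identical(fraClass, "V")) 1 else
    exp(stats::rnorm(1, 0, spread$areaScaleSdLog))
  relief <- if (identical(rlfType, "nonmonotonic"))
    stats::runif(1, spread$reliefRange[1L], spread$reliefRange[2L]) else 1
  deactivationEffect(
    gain = exp(stats::rnorm(1, 0, spread$gainSdLog)),
    spontGain = exp(stats::rnorm(1, 0, spread$spontGainSdLog)),
    thresholdShift = stats::rnorm(1, 0, spread$thresholdShiftSd),
    areaScale = areaScale, nonmonoRelief = relief)
}

#' Generate a synthetic population with ground truth
#'
#' For every unit the control condition is sampled from its archetype, the
#' deactivated condition from the archetype transformed by the unit's
#' deactivation effect, and the recovery condition from the control
#' archetype again with fresh noise (exact parameter recovery, a clean null
#' for recovery-vs-control comparisons). The ledger records every true
#' parameter and effect, sufficient to compute the true value of every
#' downstream estimand.
#'
#' @param config a [PopulationConfig-class].
#' @return list with `triplets` (list of [ConditionTriplet-class]), `ledger`
#'   (data frame of true parameters/effects per unit), `archetypes` (list of
#'   per-unit control/deactivated archetype objects).
#' @export
makePopulation <- function(config) {
  stopifnot(is(config, "PopulationConfig"))
  validObject(config)
  withSeed(config@seed, .makePopulationImpl(config))
}

.makePopulationImpl <- function(config) {
  triplets <- list(); ledgerRows <- list(); archs <- list()
  grid0 <- NULL
  nonVSubtypes <- c("low-tilt", "narrow", "closed", "broad")

  fraClassOf <- c(rep("V", config@nV),
                  rep(nonVSubtypes, length.out = config@nNonV))
  rlfTypeOf <- rep(names(config@rlfComposition), config@rlfComposition)

  nFRA <- length(fraClassOf)
  nRLF <- length(rlfTypeOf)
  total <- nFRA + nRLF
  ids <- sprintf("u%03d", seq_len(total))

  for (i in seq_len(total)) {
    isFRA <- i <= nFRA
    fraClass <- if (isFRA) fraClassOf[i] else
      c("V", nonVSubtypes)[1L + (i %% 5L)]
    rlfType <- if (isFRA) NA_character_ else rlfTypeOf[i - nFRA]
    hasFRA <- isFRA || (i - nFRA) <= config@nBoth
    hasRLF <- !isFRA

    effect <- if (is.null(config@effect))
      .sampleEffect(config@effectSpread, fraClass, rlfType)
    else {
      e <- config@effect
      if (identical(fraClass, "V") && e@areaScale != 1) {
        e@areaScale <- 1  # V areas are never rescaled
      }
      e
    }

    unit <- unitRecord(ids[i], estimatedCF = 4000,
                       fraClass = if (fraClass == "V") "V" else "nonV",
                       subtype = if (fraClass == "V") "" else fraClass,
                       deactivationMethod =
                         if (stats::runif(1) < 0.75) "cooling" else "MDP")

    fraList <- list(); rlfList <- list()
    row <- list(unit_id = ids[i], kind = if (isFRA) "fra" else "rlf",
                fra_class = if (fraClass == "V") "V" else "nonV",
                fra_subtype = if (fraClass == "V") NA_character_ else fraClass,
                rlf_type = rlfType,
                gain = effect@gain, spont_gain = effect@spontGain,
                threshold_shift = effect@thresholdShift,
                area_scale = effect@areaScale,
                nonmono_relief = effect@nonmonoRelief,
                cf = NA_real_, min_threshold = NA_real_,
                true_area_control = NA_real_, true_area_deactivated = NA_real_,
                rlf_threshold = NA_real_,
                true_halfmax_control = NA_real_,
                true_halfmax_deactivated = NA_real_,
                true_nonmono_control = NA, true_nonmono_deactivated = NA)

    if (hasFRA) {
      ctl <- .sampleFRAArchetype(fraClass)
      ## estimated CF used for the grid: the true CF (a small octave jitter
      ## would only re-centre the grid)
      unit@estimatedCF <- ctl@cf
      grid <- fraGrid(ctl@cf, calibration = config@calibration)
      dea <- applyDeactivation(ctl, effect)
      sCtl <- expectedRateSurface(ctl, grid)
      sDea <- expectedRateSurface(dea, grid)
      seeds <- floor(stats::runif(3, 0, 2^31 - 1))
      fraList <- list(
        control = sampleTrials(sCtl, grid, config@fraTrials, seeds[1L]),
        deactivated = sampleTrials(sDea, grid, config@fraTrials, seeds[2L]),
        recovery = sampleTrials(sCtl, grid, config@fraTrials, seeds[3L]))
      row$cf <- ctl@cf
      row$min_threshold <- ctl@minThreshold
      row$true_area_control <- sum(sCtl$mask)
      row$true_area_deactivated <- sum(sDea$mask)
      archs[[ids[i]]] <- list(control = ctl, deactivated = dea)
    }

    if (hasRLF) {
      ctl <- .sampleRLFArchetype(rlfType)
      dea <- applyDeactivation(ctl, effect)
      muCtl <- expectedRLFRates(ctl, calibration = config@calibration)
      muDea <- expectedRLFRates(dea, calibration = config@calibration)
      seeds <- floor(stats::runif(3, 0, 2^31 - 1))
      freq <- if (hasFRA) unit@estimatedCF else 4000
      rlfList <- list(
        control = makeRLF(ctl, config@rlfTrials, seeds[1L],
                          calibration = config@calibration,
                          frequency = freq),
        deactivated = makeRLF(dea, config@rlfTrials, seeds[2L],
                              calibration = config@calibration,
                              frequency = freq),
        recovery = makeRLF(ctl, config@rlfTrials, seeds[3L],
                           calibration = config@calibration,
                           frequency = freq))
      ## quiet-to-loud ordering for the half-max / monotonicity truths
      splQ <- rev(splFromAttenuation(rlfLevels(), config@calibration))
      muCtlQ <- rev(muCtl); muDeaQ <- rev(muDea)
      row$rlf_threshold <- ctl@threshold
      row$true_halfmax_control <-
        if (max(muCtlQ) > 0) halfMaxLevel(muCtlQ, splQ) else NA_real_
      row$true_halfmax_deactivated <-
        if (max(muDeaQ) > 0) halfMaxLevel(muDeaQ, splQ) else NA_real_
      row$true_nonmono_control <- classifyMonotonicity(muCtlQ)
      row$true_nonmono_deactivated <- classifyMonotonicity(muDeaQ)
      archs[[ids[i]]] <- c(archs[[ids[i]]],
                           list(rlf_control = ctl, rlf_deactivated = dea))
    }

    triplets[[ids[i]]] <- conditionTriplet(unit, fra = fraList,
                                           rlf = rlfList)
    ledgerRows[[i]] <- row
  }

  ledger <- if (length(ledgerRows))
    do.call(rbind, lapply(ledgerRows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  else data.frame(unit_id = character(), kind = character())
  list(triplets = triplets, ledger = ledger, archetypes = archs)
}
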