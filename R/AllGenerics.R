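#' @import methods
NULL

#' @rdname StimulusGrid-class
#' @param x an object with a stimulus axis.
#' @export
setGeneric("toneFrequencies", function(x) standardGeneric("toneFrequencies"))

#' @rdname StimulusGrid-class
#' @export
setGeneric("soundLevels", function(x) standardGeneric("soundLevels"))

#' @rdname StimulusGrid-class
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))

#' @rdname ResponseGrid-class
#' @export
setGeneric("spikeCounts", function(x) standardGeneric("spikeCounts"))

#' @rdname ResponseGrid-class
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Total spike count of a measurement
#'
#' Sum of all spike counts over every stimulus bin and trial.
#'
#' @param x a [ResponseGrid-class] or [RateLevelFunction-class].
#' @return single non-negative number.
#' @examples
#' g <- stimulusGrid(c(1000, 2000), c(10, 15))
#' rg <- responseGrid(g, array(0:3, c(2, 2, 1)))
#' totalSpikes(rg)  # 6
#' @export
setGeneric("totalSpikes", function(x) standardGeneric("totalSpikes"))

#' Expected spikes-per-presentation surface of an FRA archetype
#'
#' Evaluates the noiseless generative response surface of an archetype on a
#' stimulus grid: `drivenRate` inside the excitatory region, `spontRate`
#' outside it.
#'
#' @param archetype an [FRAArchetype-class].
#' @param grid a [StimulusGrid-class] whose frequency span covers the CF.
#' @return list with `expected` (frequency x level matrix of expected counts
#'   per presentation) and `mask` (logical matrix, `TRUE` inside the
#'   excitatory region).
#' @export
setGeneric("expectedRateSurface",
           function(archetype, grid) standardGeneric("expectedRateSurface"))

#' Apply a deactivation effect to an archetype
#'
#' Transforms generative parameters: driven rate is multiplied by `gain`,
#' spontaneous rate by `spontGain`, the minimum threshold is shifted by
#' `thresholdShift`, and (nonV FRAs only) the excitatory-region extent is
#' scaled by `areaScale`. Ground truth therefore stays analytic: effects act
#' on parameters, never on sampled counts.
#'
#' @param archetype an [FRAArchetype-class] or [RLFArchetype-class].
#' @param effect a [DeactivationEffect-class].
#' @return transformed archetype of the same class.
#' @export
setGeneric("applyDeactivation",
           function(archetype, effect) standardGeneric("applyDeactivation"))
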