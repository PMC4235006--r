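## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded generators never perturb the global random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stream-specific child seed from a user seed; kept below 2^31.
childSeed <- function(seed, stream) {
  (as.numeric(seed) * 1103L + as.numeric(stream) * 12289L) %% 2147483629
}

#' Convert dB attenuation to dB SPL
#'
#' Sound levels are acquired as dB attenuation re the maximum system output
#' (larger attenuation = quieter). Given a calibration (maximum output in dB
#' SPL, a scalar for a flat system or a per-frequency value), the sound
#' pressure level is `calibration - attenuation`.
#'
#' @param attenuation numeric vector of dB attenuation values.
#' @param calibration maximum output in dB SPL (scalar), or `NULL`.
#' @return dB SPL vector; errors when calibration is absent.
#' @export
splFromAttenuation <- function(attenuation, calibration) {
  if (is.null(calibration))
    stop("no calibration available: cannot convert attenuation to dB SPL")
  if (!is.numeric(calibration) || length(calibration) != 1L)
    stop("'calibration' must be a single maximum-output value in dB SPL")
  calibration - attenuation
}

## Octave coordinate of frequencies re a reference frequency.
octavesRe <- function(frequencies, reference) log2(frequencies / reference)

isCount <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
    all(abs(x - round(x)) < 1e-8)
}

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
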