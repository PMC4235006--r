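---
title: "Receptive-field and sound-level analysis for paired-condition midbrain recordings"
author: "icresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{icresp methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icresp)
```

## The problem

Single units in the inferior colliculus (IC) are characterised by two
paradigms: the frequency response area (FRA), a map of spike counts over a
tone frequency x level grid (0.1-octave steps from -3 to +2 octaves re the
estimated characteristic frequency; 10-90 dB attenuation in 5 dB steps,
one presentation per bin), and the rate-level function (RLF), spike counts
to repeated CF tones across levels (10-90 dB attenuation in 10 dB steps,
20 or 50 repetitions). In deactivation experiments each neuron is measured
in three conditions - control, deactivated (the opposite IC silenced by
cooling or procaine microdialysis) and recovery - and serves as its own
control. `icresp` implements the full analysis chain for such data, plus a
seeded synthetic-population generator with analytic ground truth, so that
every stage is testable without recorded data.

Sound levels are stored as dB attenuation re the maximum system output
(larger = quieter); dB SPL is a derived view through a calibration value,
`SPL = calibration - attenuation`. The generator assumes a flat 100 dB SPL
maximum output, typical of a closed-field system below 10 kHz.

## FRA analysis

For one `ResponseGrid` the chain is:

1. **Spontaneous rate** (`estimateSpontaneous`): mean and SD of the
   per-presentation counts at the quietest level across all frequencies,
   pooling trials. No silence condition is used.
2. **Excitatory mask** (`excitatoryMask`): a bin is excitatory when its
   mean count strictly exceeds `mean + 2 SD` of the spontaneous estimate.
   Strict inequality means that with zero spontaneous variance any firing
   above the mean counts, which keeps noiseless grids from becoming
   all-excitatory.
3. **Denoising** (`cleanMask`, used by `analyzeFRA`, optional but default):
   the mask is restricted to its largest 8-connected component. With one
   presentation per bin the 2-SD criterion flags a few percent of purely
   spontaneous bins; left in place, those speckles seed spurious
   per-frequency thresholds on the FRA flanks and can relocate the fitted
   tuning-curve minimum entirely. The excitatory response area proper is a
   single connected region, so keeping the largest component is the
   mildest filter that removes the speckle; it is the identity on
   noiseless surfaces.
4. **Excitatory thresholds** (`excitatoryThresholds`): per frequency, the
   quietest excitatory level; frequencies with no excitatory bin are
   absent.
5. **Frequency tuning curve** (`fitFTC`): a least-squares polynomial of
   requested degree 10 through the thresholds, fitted in octave
   coordinates on a centred/scaled abscissa (degree-10 fits in Hz are
   hopelessly ill-conditioned). The degree is clamped to one less than the
   number of present thresholds. Absent frequencies are excluded.
6. **CF and threshold** (`extractCFThreshold`): the global minimum of the
   fitted curve over the span of present thresholds, by dense evaluation
   (200 points/octave) plus local refinement; ties break toward the lower
   frequency. Fitting works on a "threshold level" axis where smaller =
   more sensitive (dB SPL when calibrated, negated attenuation otherwise),
   so the minimum is always the sensitivity peak.
7. **Area** (`fraArea`): the number of bins at or above the fitted curve,
   restricted to frequencies with present thresholds. Each bin stands for
   a 5-dB band; a bin is counted when its band reaches the curve
   (half-step rule). The strict centre-point rule loses a bin wherever the
   smooth fit overshoots the staircase of quantised thresholds by an
   arbitrarily small amount, a systematic -6 to -8% bias; the band rule is
   symmetric in the sub-step fitting error and unbiased to < 1%.
8. **Fallback** (`fraAreaFallback`): for FRAs the polynomial does not
   reflect (fewer than two present thresholds, an explicit per-unit flag,
   or an optional RMS-residual limit), the area is the number of bins
   whose summed count strictly exceeds a spike criterion (default 1). The
   raw 2-SD mask bin count is always reported as a diagnostic alongside
   the FTC-based area, which is primary.

On noiseless V-shaped surfaces this chain recovers CF within 0.05 octave
and area within 5% of the generative region; under Poisson noise with
driven rate 10 x spontaneous it recovers CF within 0.2 octave in >= 95% of
seeded units. One caveat is intrinsic to the FTC-minimum method: the
minimum of a smooth polynomial through an *asymmetric* piecewise-linear V
is biased toward the shallower flank (about 0.07 octave at a 1.4 slope
ratio), and the 5-dB staircase quantisation of thresholds adds a
phase-dependent wobble of up to ~0.04 octave on its own. The generator
therefore samples V archetypes with symmetric flank slopes, which bounds
the noiseless bias at 0.039 octave across the whole parameter range; nonV
archetypes are free to be asymmetric.

## RLF analysis

Per-level trial means drive all decisions (medians and type-7 IQRs are
reported for plotting). All vectors are ordered from quietest to loudest.

* **Non-monotonicity** (`classifyMonotonicity`): an RLF is non-monotonic
  when the rate at some level above the best level falls 25% or more below
  the maximum; the boundary is inclusive. Under tied maxima the best level
  is the *quietest* tied level, so louder tied levels can still trigger
  the rule (the conservative reading).
* **Type labels** (`classifyRLF`): five rule-based labels with precedence
  flat (dynamic range < 1 spike/trial), non-monotonic, saturating (the
  two or more loudest levels within 10% of the maximum), straight (linear
  fit in dB with R^2 >= 0.95), else monotonic. The five type names come
  from the prior literature without quantitative definitions; these
  boundary constants are declared configuration, not recorded-data facts.
* **Half-maximum level** (`halfMaxLevel`): rates are normalised to their
  maximum and the first crossing of 0.5 from the quiet end is linearly
  interpolated. Non-monotonic RLFs can cross 0.5 more than once; the first
  crossing is used because the measure targets the rising limb. If the
  quietest level already reaches half maximum, that level is returned.
* **Discriminability Index** (`rocAUC`, `discriminabilityIndex`): for each
  adjacent level pair the ROC area between the two trial-count
  distributions (probability that a draw from the louder level exceeds one
  from the quieter, ties 1/2, computed through the rank/U identity), then
  `DI = sum |AUC - 0.5|`. For a 9-level RLF the DI is bounded by 4.0. The
  plain summed AUC is kept as a diagnostic variant. Counts are compared
  directly; since tone duration is constant within an RLF, rate
  normalisation would not change any AUC.

## Population statistics

`modulationIndex` implements `MI = (deactivated - control) /
(deactivated + control)`; `classifyChange` applies the 20% change
criterion with inclusive boundaries. The battery in `analyzePopulation`:
two-sample Kolmogorov-Smirnov on the V vs nonV MI distributions of FRA
area and FRA spikes; Friedman rank ANOVA over the three conditions for
half-maximum level and DI, with Wilcoxon signed-rank post hocs (control vs
deactivated, control vs recovery) at the Sidak-corrected alpha
`1 - (1 - 0.05)^(1/2) = 0.0253`; Spearman rank correlation between the
change in half-maximum and the change in threshold for units carrying both
paradigms; and an exact Fisher test on the r x 2 RLF type-transition table
(type x changed/unchanged), with the two-sided p defined by probability
ordering over all margin-consistent tables. Wilcoxon excludes zero
differences and is exact by enumeration for n <= 25 without ties, else a
continuity-corrected normal approximation; every result records whether
its p is exact. Median confidence intervals use a seeded percentile
bootstrap (default 2000 resamples in the pipeline; the CI method behind
published median CIs of this kind is rarely stated, and the bootstrap is a
declared surrogate).

## The synthetic generator

`FRAArchetype` defines a threshold contour in octave x attenuation space:
two linear flanks meeting at `(cf, minThreshold)`, deformed per class
(`narrow` clips bandwidth, `closed` adds a loud-side bound, `low-tilt`
skews the trough, `broad` has shallow slopes). Expected response is
`drivenRate` inside the region (default 5 spikes/presentation) and
`spontRate` outside (default 0.5); trials are independent Poisson draws.
Deactivation acts on parameters, never on sampled counts, so ground truth
stays analytic: `gain` scales the driven rate, `spontGain` the spontaneous
rate, `thresholdShift` moves the trough (defined on the SPL axis, positive
= less sensitive), and `areaScale` scales the region extent - bandwidth
for `narrow`, `1/slope` for the contour-bounded classes - and is
forbidden for V archetypes, encoding the finding that V areas do not
change. Recovery is modelled as an exact return to control parameters
with fresh noise, giving a clean null for recovery-vs-control tests.

`RLFArchetype` builds the expected rate as
`spont + maxRate * min(1, driveGain * drive(SPL))`: a type-specific drive
rising from threshold, clipped by a *fixed* output saturation. The gain of
a deactivation effect multiplies the drive *before* the clip. This is a
deliberate modelling choice: a gain applied after the output nonlinearity
leaves the max-normalised curve - and hence the half-maximum level -
unchanged, whereas a drive gain reproduces the experimentally observed
supra-threshold rescaling (a gain of 0.6 shifts half-max up by roughly a
third of the dynamic range in saturating units) while leaving thresholds
almost untouched. `nonmonoRelief` multiplies the non-monotonic reduction
fraction, letting deactivation convert non-monotonic RLFs toward monotonic
or straight shapes, as observed.

`populationConfig()` fixes the study conditions: 49 V + 50 nonV FRA units
(one presentation per bin), 38 RLF units at 50 repetitions per level
(the paradigm's larger standard count; the smaller 20 makes half-max
estimates noticeably noisier through first-crossing noise), 16 units
carrying both paradigms, and 12/38 non-monotonic RLFs. The remaining RLF
composition (16 saturating, 4 straight, 4 monotonic, 2 flat) is not
recorded in the source dataset; it was chosen once so that saturating
responses dominate the monotone group, which matches both IC physiology
and the observation that deactivation shifted half-maximum levels in the
majority of units. Sampled deactivation effects default to log-normal
gains (log-SD 0.35), threshold shifts of SD 3 dB, and - for nonV units
only - log-normal area scaling with log-SD 0.7, consistent with reported
per-unit area changes spanning roughly -86% to +234%.

What the generator does *not* emulate: spike timing (counts only),
overdispersion beyond Poisson (a config extension point), correlated
trial-to-trial variability, cooling/procaine pharmacokinetics and partial
or drifting deactivation, and the continuum of nonV shapes (the four
subtypes are parametric stand-ins). Passing tests therefore demonstrate
that the chain recovers known structure under Poisson variability at
desk scale - not that it would be unbiased on every recorded dataset.

## Numerical choices and degenerate inputs

* Polynomial fits use a centred/scaled abscissa and `lm.fit`; rank
  deficiencies yield zero coefficients rather than errors.
* CF ties break toward the lower frequency; dense evaluation uses 200
  points/octave before golden-section refinement.
* `excitatoryMask` with spontaneous SD 0 reduces to "any firing above the
  spontaneous mean".
* RLFs with zero maximum rate are classified flat; their half-max is
  undefined and excluded (with the unit) from condition matrices.
* Identical conditions give MI = 0, KS D = 0 and an all-zero-difference
  Wilcoxon; the population battery reports such degenerate tests as
  absent instead of failing.
* The Fisher wrapper relies on the exact network algorithm; tables too
  large for it raise an error suggesting row collapsing.
* Every stochastic step (trial sampling, population generation,
  bootstrap) takes an explicit seed and restores the caller's RNG state.

## Simulation sizes

The packaged checks run at the study-scale defaults where the quantity
under test depends on them (38 RLF units for direction-of-effect and
power checks, 100 seeded units or seeds for recovery and power rates) and
at reduced sizes where it does not: the type-I-error calibration of the
population battery uses 400 seeded zero-effect populations of 10 V + 11
nonV + 14 RLF units (7 with both paradigms), since calibration is a
property of the tests, not of the sample size, and the unequal group
sizes keep the exact KS p-value grid fine near the 0.05 level.

## Reproduction

`runRepro()` generates the default population, runs the full battery and
writes the per-unit change table, the ground-truth ledger, the RLF
transition table and a JSON summary (plus optional figures) under a run
directory, all determined by the configuration hash and seed recorded in
the provenance sidecar. `scripts/acceptance.R` recomputes the headline
quantities from scratch for a given seed.
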