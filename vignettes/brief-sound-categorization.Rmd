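---
title: "Methods: categorizing extremely brief auditory stimuli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: categorizing extremely brief auditory stimuli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soundgate)
```

## The question and the pipeline

How much auditory signal is needed to tell a spoken voice from instrumental
music or from an everyday environmental sound? In a gating design, listeners
hear randomly cut excerpts of 20, 30, 50, 100 and 200 ms and assign each to
one of the three categories. Two amplitude-normalization regimes matter:
*peak* normalization (sources rescaled to a common maximum amplitude before
cutting, so excerpt energy varies with where the cut lands) and *RMS*
normalization (each cut excerpt additionally rescaled to a common
root-mean-square energy). The question behind the design is whether rapid
voice categorization requires a voice-specific mechanism, or whether a
general process reading the *distribution of spectral envelopes* in the
stimulus set suffices — in which case the normalization regime, which
reshapes that distribution, should change the pattern of performance.

`soundgate` implements the full analysis chain as testable code:

1. **Synthesis** (`generate_corpus()`): seeded, category-structured source
   recordings stand in for undeposited real recordings.
2. **Stimulus preparation** (`peak_normalize()`, `extract_gates()`,
   `as_rms_condition()`): the 20 excerpts × 3 categories × 5 durations
   factorial per normalization condition (300 stimuli each), with
   quasi-silent cuts rejected.
3. **Cochlear model** (`excitation_pattern()`): 80 ERB-spaced 4th-order
   gammatone channels; per-channel RMS over the excerpt is the excitation
   pattern.
4. **Feature space** (`fit_pca()`, `correlation_circle()`,
   `summarize_categories()`, `distance_features()`): one global PCA over all
   600 patterns; category barycenters and dispersions; per-stimulus
   within-/between-category Euclidean distances on the first two components.
5. **Listener scoring** (`simulate_listener()`, `confusion_matrix()`,
   `accuracy_index()`, `above_chance_test()`): forced-choice logs scored
   with the hit/false-alarm index `Hit/N − FA/(2N)`.
6. **Linking regression** (`fit_standardized()`): standardized OLS of
   per-stimulus accuracy on within-distance, between-distance, duration and
   (peak condition only) mean RMS power.

`run_all()` executes everything from one seeded configuration;
`inst/exec/soundgate` exposes the stages as shell subcommands.

## The synthetic corpus: what it emulates and what it does not

No audio from the original experiment is deposited, so the package ships a
generator whose *only* calibrated claim is the structure the analysis
depends on: voices and music have low across-source spectral-envelope
variability, environmental sounds have high variability that partially
overlaps the other two categories.

Each source is a mixture of a harmonic complex (fundamental drawn from
`f0_range`) and spectrally matched noise, shaped by a Gaussian spectral
envelope on a log-frequency axis. The envelope centroid is drawn per source
from `Normal(envelope_centroid_mean, envelope_centroid_sd)`;
`envelope_centroid_sd` is the variability knob. Defaults
(`default_synth_specs()`):

| category | centroid mean (Hz) | centroid SD (Hz) | harmonicity | AM |
|---|---|---|---|---|
| VOICE  | 500  | 100 | 0.9  | 4 Hz, depth 0.9 |
| MUSIC  | 1100 | 150 | 1.0  | 2 Hz, depth 0.3 |
| ESOUND | 1300 | 900 | 0.15 | none |

The slow amplitude modulations are syllable- and note-rate envelopes added
for coarse ecological plausibility; they are deliberately kept weak enough
(music depth 0.3) that excerpt-level energy variation does not rival the
spectral dispersion the categories are defined by — the dispersion ordering
must come from `envelope_centroid_sd`, which is the design's contract. A
deeper music modulation would leak note-rate level variance into the first
principal component of the peak condition and confound the ordering.

The generator makes no attempt at intelligible speech, musical structure,
or perceptually validated timbre; it is mono, stationary in spectrum within
a source, and its categories are far more homogeneous than real corpora.
Passing tests therefore show that the *pipeline* is sensitive to the
dispersion structure it claims to measure — not that real voices behave
like these sources.

Randomness is counter-based: every source is generated from a sub-seed
derived from `(seed, label, source_index)`, so corpora are bit-reproducible
and order-independent.

## Stimulus preparation choices

- **Pipeline order**: sources are peak-normalized (target 0.99), then cut;
  the RMS condition applies RMS equalization to the already-cut excerpts.
  Both conditions share the same cuts.
- **Quasi-silence**: an excerpt is rejected iff its level is strictly below
  −40 dBFS (a conventional noise-gate level); rejection is bounded at 1000
  redraws per excerpt, after which the offending cell is reported.
- **RMS target**: 0.05 full scale by default, low enough that boosting
  quiet excerpts rarely clips; if a boost would clip, the excerpt is
  hard-limited at ±1 and the event is counted. The scenario configuration
  (below) instead uses `"auto"`, equalizing at the mean excerpt RMS.
- **Indexing**: 0-based onsets, half-open intervals; no onset/offset ramps
  on analysis paths.

## Cochlear model

The frequency analysis is an 80-channel gammatone filterbank with center
frequencies equally spaced on the ERB-rate scale
(`21.4·log10(4.37·f/1000 + 1)`) between 50 Hz and 15 kHz (10 kHz in the
desk profile, below its Nyquist), bandwidths `1.019·ERB(cf)`. Each channel
is realized as four cascaded complex one-pole sections (a 4th-order
all-pole digital gammatone) with analytic gain normalization; the contract,
enforced by tests, is unit gain at the center frequency within ±1 dB and
correct tonotopy for probe tones. The excitation pattern is the per-channel
RMS over the whole excerpt — one pattern per stimulus, no temporal
windowing, no middle-ear filtering or adaptation.

Patterns default to linear RMS, which makes the representation exactly
homogeneous (scaling the waveform scales the pattern). A dB scale (floored
at −100 dB) is available because PCA behaves differently on log energies;
the shipped analyses use the linear scale.

## Feature space

The PCA is *global*: one fit over all stimuli of all durations and both
normalization conditions, so every summary lives in a common space.
Correlation mode (center and scale each channel) is the default — the
correlation circle, the classic display of variable contributions, is its
companion — with covariance mode available. Component signs are fixed by
requiring the largest-magnitude loading entry to be positive.

Category ellipses use the population SD (divide by *n*) of scores per
component; PCA scaling uses the sample SD (*n* − 1). Distances are computed
on the first two components by default (the space in which the categories
are displayed and compared), configurable via `pca$n_components`. Per-
duration projections are score subsets of the global space, not refits.

## The simulated listener

Responses are generated by a softmax observer over category barycenters:
the probability of answering category *c* to a stimulus at *x* is
proportional to `exp(−sensitivity · gain(duration) · ‖x − b_c‖)`. Zero
sensitivity gives uniform guessing; large sensitivity approaches a
nearest-barycenter classifier. The duration gains (0.25, 0.45, 0.8, 1.4,
2.4 for 20–200 ms) encode that longer gates yield a cleaner percept, and
the default sensitivity of 0.6 per score unit was chosen so that simulated
accuracy spans the psychophysical range — near chance at 20 ms, high but
not saturated at 200 ms — in the shipped space, whose between-category
distances are of order 5–15 score units. The model exists to exercise the
pipeline end-to-end and to make scoring code testable; it is not a model
of human listeners. Its sensitivity is recoverable from simulated logs by
profile likelihood (`estimate_sensitivity()`), which is how the response
model is validated.

Scoring follows the balanced-design index `Hit/N − FA/(2N)`: with N items
per category and 2N items of the other categories, a responder guessing
uniformly among K = 3 labels expects `Hit/N = 1/3` and
`FA/(2N) = (K−1)/(2K) = 1/3`, so chance is exactly 0
(`chance_accuracy_index()`); the index ranges from −0.5 to 1. Above-chance
performance is assessed with a two-sided one-sample t test across
participants; a zero-variance set of indices is reported as degenerate
rather than tested. False-alarm rates use the non-label trial count (2N)
as denominator, consistent with the index.

## Linking regression

The regression unit is the stimulus: accuracy is the proportion of correct
responses pooled over participants (600 stimulus-level observations across
the two conditions force this reading of the design's degrees of freedom;
the hit/false-alarm index is category-level by construction and cannot be
attached to single stimuli). Response and predictors are z-scored with the
sample SD, so slopes are standardized betas; adjusted R² follows
`1 − (1 − R²)(n − 1)/(n − p − 1)` exactly, and a condition-number check
(threshold 1e8) refuses collinear predictor sets. Mean RMS power enters
only in the peak condition, where levels vary. No multiple-testing
correction is applied to the coefficient table.

## The voice-separation scenario

`scenario_synth_specs()` is a positive control for the pipeline's
sensitivity to the normalization manipulation. Voice sources carry a deep
(depth 1.0) 3 Hz amplitude modulation, so peak-normalized voice excerpts
have low and highly variable RMS energy: their linear-RMS excitation
patterns collapse toward the origin of the pattern space and lose their
distinctive low-centroid direction. RMS equalization restores every
excerpt to a common energy, so voice patterns regain full magnitude along
their own spectral direction while the steady-state music and
environmental-sound geometry barely moves. The expected signature — the
voice between-category distance increases from the peak to the RMS
condition, and more than music's does — is asserted by the test suite.
Because this comparison is *across* conditions, the scenario equalizes at
the mean excerpt RMS (`rms_target = "auto"`); a fixed low target would
shrink every RMS-condition distance by a common level factor and swamp the
geometric effect of interest.

This is a designed demonstration that the pipeline can detect a
normalization-induced reshaping of category geometry; it is not a claim
about any particular real stimulus set.

## Problem sizes and profiles

Two shipped profiles share the full factorial design (20 excerpts × 3
categories × 5 durations per condition, 18 and 19 simulated participants):

- `"paper"`: 44.1 kHz, 30 s sources, 10 sources per category, filterbank to
  15 kHz — the study-scale conditions.
- `"desk"`: 22.05 kHz, 10 s sources, 8 sources per category, filterbank to
  10 kHz — the package's chosen scale for test suites and worked examples;
  a full `run_all()` takes on the order of ten seconds.

The category structure, design counts and all analysis settings are
identical between profiles; only sampling rate, source length and corpus
size differ.

## Numerical conventions and degenerate inputs

- Quasi-silence uses a strict `<` at the threshold; an exactly-threshold
  excerpt is kept.
- Peak- or RMS-normalizing an all-zero signal, z-scoring a constant
  column, correlating with a zero-variance score column, and PCA on a
  constant channel in correlation mode are all classed errors, not NaNs.
- The accuracy index requires a balanced design and says so when refused.
- All randomness flows from one master seed through counter-based
  sub-seeds; rerunning any stage with the same configuration is
  bit-identical, which the suite verifies on report files.

## Known limitations

- The synthetic categories are stationary and unimodal in envelope; real
  voices, music and environmental sounds have temporal structure,
  multimodal spectra and far heavier tails.
- The listener model has no lapses, no bias, no reaction-time component,
  and its duration gains are imposed rather than estimated from humans.
- The cochlear front end is energy-only: no adaptation, masking or
  modulation filterbank, so any effect that depends on temporal fine
  structure within an excerpt is invisible to it.
- Printed variance fractions, betas and R² values from any particular real
  stimulus set depend on those recordings; on synthetic corpora the
  package reproduces directions and orderings, not those numbers.
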