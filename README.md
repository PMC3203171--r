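# soundgate

How much sound does it take to tell a voice from music, or from the rattle
of everyday life? In a gating design, listeners categorize randomly cut
excerpts of 20–200 ms under two amplitude-normalization regimes (peak vs
RMS). `soundgate` implements the complete analysis pipeline for that
question as an R package, for psychoacousticians and cognitive scientists
who want every stage — stimulus preparation, cochlear modeling, perceptual
geometry, behavioral scoring, and the regression linking the two — as
seeded, tested, re-runnable code. Because the original recordings and
response logs of such experiments are rarely deposited, the package also
ships a category-structured synthetic-audio generator and a simulated
listener, so the whole chain runs end-to-end at desk scale.

## What it computes

- **Stimulus preparation.** Sources are peak-normalized
  (`x · target/max|x|`), cut into gated excerpts at five durations with
  quasi-silent cuts (level < −40 dBFS) rejected, yielding the
  20 excerpts × 3 categories × 5 durations factorial (300 stimuli per
  condition); the RMS condition additionally equalizes each excerpt to a
  common root-mean-square energy.
- **Excitation patterns.** Each excerpt is passed through an 80-channel
  gammatone filterbank, ERB-spaced (ERB-rate `= 21.4·log10(4.37f/1000+1)`,
  bandwidth `1.019·ERB(cf)`), and summarized by per-channel RMS — the
  excitation pattern.
- **Perceptual geometry.** One global PCA over all patterns (correlation
  mode; correlation circle for channel contributions), category barycenters
  and dispersions on the first two components, and per-stimulus
  within-category and between-category mean Euclidean distances.
- **Behavioral scoring.** Confusion matrices and the balanced-design
  accuracy index `Hit/N − FA/(2N)` (chance = 0, range −0.5…1), with
  one-sample t tests against chance across participants. A softmax
  observer over category barycenters,
  `P(c) ∝ exp(−β·gain(d)·‖x − b_c‖)`, generates response logs.
- **Linking regression.** Standardized OLS of per-stimulus accuracy on
  within-distance, between-distance, duration, and (peak condition) mean
  RMS power: betas, adjusted R², F, SSE.

## Worked example

```r
library(soundgate)

res <- run_all(default_config(seed = 42, profile = "desk"))

round(100 * res$variance_fractions[1:3], 1)
#> [1] 43.3 29.5 12.2

res$confusions$PEAK
#> Response percentages by true category (rows):
#>          VOICE MUSIC ESOUND
#>   VOICE     86     8      6
#>   MUSIC      6    60     34
#>   ESOUND    19    27     54

res$regressions$PEAK
#> Standardized OLS: R2 = 0.680, adj R2 = 0.676, F(4, 295) = 156.94, SSE = 95.59, n = 300
#>          predictor   beta     se      t  p_value
#> 1  within_distance -0.532 0.0351 -15.15 9.25e-39
#> 2 between_distance  0.711 0.0348  20.45 1.65e-58
#> 3      duration_ms  0.294 0.0332   8.84 8.69e-17
#> 4         mean_rms -0.102 0.0339  -3.00 2.92e-03
```

The first two principal components carry most of the excitation-pattern
variance; the confusion matrix shows voices easiest and environmental
sounds hardest, with the music/environment confusion the dominant error;
and the regression recovers the signature the pipeline is built around —
accuracy falls with within-category distance (β < 0, tighter categories
are easier), rises with between-category distance and with gate duration.
`res$accuracy` tabulates the accuracy index per duration and condition,
and `plot_category_map(res$space, res$stimuli$label)` draws the
barycenter-and-ellipse view of the category geometry.

The same pipeline is scriptable from a shell via the bundled CLI
(`system.file("exec", "soundgate", package = "soundgate")`), whose
subcommands `synth`, `prepare`, `features`, `space`, `simulate`, `score`,
`regress` and `run-all` each restart from the previous stage's files.

## Package layout

- `R/` — synthesis, stimulus preparation, cochlear model (with
  `src/gammatone.cpp`), feature space, listener/scoring, regression,
  pipeline orchestration, plots.
- `tests/testthat/` — unit, property and end-to-end suites with
  brute-force oracles for the PCA, distances and regression.
- `vignettes/brief-sound-categorization.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical conventions, limitations.
- `inst/exec/soundgate` — the command-line wrapper.
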