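---
title: "Methods: time-shifted template decoding of speech tokens from population spike trains"
author: "neurogram package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-shifted template decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurogram)
```

## The decoding problem

A population of auditory units (simulated nerve fibres or multi-unit
recording sites) responds to a set of vowel-consonant-vowel (VCV) speech
tokens: by default 16 medial consonants in an /a/-C-/a/ frame, each spoken
by 3 talkers, each presented 10 times. The question the package answers is
operational: given the spike trains evoked by a single presentation, how
reliably can the stimulus be identified, at which temporal resolution, and
how is that ability distributed across units, classes and population
sizes?

## Representation

Spike trains are binned into PSTHs with 1-ms half-open bins over the first
650 ms of the 700-ms stimulus; the final 50 ms, which mostly carry the
tail of the final vowel, are excluded so the analysis window centres on
the medial consonant. Each PSTH row may be smoothed by convolution with a
unit-sum Hamming window; window lengths come from a 10-point grid, evenly
spaced on a logarithmic scale from 1 ms (no smoothing) to 400 ms (an
essentially rate-only code): 1, 2, 4, 7, 14, 28, 54, 106, 206, 400 ms.
Windows are normalised to unit sum so smoothed values stay on the
spike-count scale, and the convolution uses the zero-padded "same"
convention, which preserves row length. Rows are stacked across units,
ordered by characteristic frequency ascending (units lacking a CF follow
in id order), giving the *M x N* neurogram.

## The classifier

Cross-validation is leave-one-repetition-out: for each fold, one
repetition of *every* token is removed and class templates are averaged
over the remaining repetitions, so the held-out trial never contributes to
any template. Distances are Euclidean, minimised over relative lags within
±100 ms in 1-bin steps: the template is trimmed by 100 ms at both ends and
its core is slid across the test neurogram, a single shared lag applying
to all unit rows. The symmetric trim is what makes every lag's slice
exist; with the default 650-bin window the distance is computed over a
450-bin core. Classification is the argmin over class templates and lags.

Three modes:

* **token** — one class per (phoneme, talker) pair, 48 under the default
  design; chance 1/48 ≈ 2.08%.
* **phoneme** — per-talker token templates are merged into one template
  per phoneme before classification: the first talker in canonical order
  serves as the reference, each other talker's template is shifted by the
  lag minimising its distance to the reference (the same kernel the
  classifier uses), and the aligned templates are averaged element-wise,
  bins covered by fewer talkers averaging over those only. Sequential
  alignment to a fixed reference is deterministic and linear in the number
  of talkers; a joint optimisation over all pairwise lags would be
  combinatorial and is not attempted. Merging happens per fold, after the
  held-out repetition is removed.
* **hierarchical** — token-mode classification in which confusions between
  talker variants of the same phoneme are disregarded; by construction its
  accuracy can never fall below token-mode accuracy on the same trials.

Exact distance ties are resolved to the first class in canonical order,
with a warning: ties are measure-zero once smoothing makes values
continuous but certain on degenerate integer fixtures, and a deterministic
rule keeps every run reproducible. When the minimum is attained at several
lags the most negative lag is reported.

## Response statistics

*Sparseness.* `S = [1 - (Σr_i/n)² / (Σr_i²/n)] / [1 - 1/n]`, 0 for a flat
profile and 1 for a one-hot one. Lifetime sparseness feeds it the unit's
48 per-token mean rates; population sparseness the per-unit rates for a
single presentation (per-trial rather than trial-averaged, so summaries
can report dispersion across repetitions). "Rate" is always spike count in
the response window divided by its duration, in spikes/s. The statistic is
undefined on an all-zero vector and the functions say so rather than
returning a number.

*d' and discrimination specificity.* Per class, the hit rate is the
fraction of that class's trials predicted as it, the false-alarm rate the
fraction of other-class trials predicted as it; both are clipped to
`[1/(2n), 1 - 1/(2n)]` (n the relevant trial count) before the
inverse-normal transform so saturated rates stay finite — the familiar
1/(2N) convention from psychophysics. Discrimination specificity applies
the sparseness statistic to the per-class d' profile after clipping
negative values to zero (with a warning); 0 marks a generalist, 1 a
specialist.

*CF-neighbourhood correlations.* For unit pairs whose CFs lie within half
an octave, the Pearson correlation of unsmoothed trial-averaged 1-ms
PSTHs is computed per phoneme (averaging repetitions and talker variants —
the per-phoneme reading of "each of the 16 stimuli"; correlations of
constant PSTHs are undefined and are skipped), then averaged over phonemes
and pairs.

## Sweep experiments

Smoothing-window sweeps evaluate the full classifier at every grid length,
for single units or whole (sub)populations, and report the argmax window
with ties going to the shortest. Population-size sweeps either draw
random subpopulations without replacement — a fresh, independent draw per
size, 20 draws by default, fully seeded — or grow the population in rank
order of single-unit token accuracy at the population-optimal window
("best first" / "worst first"), ranking ties broken by higher mean firing
rate and then unit id. Sizes default to a roughly logarithmic ladder
(1, 2, 3, 5, 10, 20, 50, 100, ...) capped at the population size.

## Spike detection

Raw extracellular traces are bandpass-filtered at 0.3–6 kHz with a
fourth-order Butterworth filter applied forward and backward
(`signal::filtfilt`), realising zero phase at the cost of doubling the
effective order — "fourth order" here is the designed order. The
threshold is `T = -k median(|x| / 0.6745)` with k = 4: the median absolute
value over 0.6745 is a robust estimate of the noise SD, nearly insensitive
to the spikes themselves. The paper-style detector leaves the crossing
rule open; the package timestamps a spike at the first sample below
threshold after the trace was at or above it (the simplest reproducible
rule; timestamping at the local minimum would differ by a fraction of a
millisecond) and enforces a 1-ms dead time, matching the analysis bin
width.

## The synthetic population generator

The generator exists so the pipeline can be exercised and validated
end-to-end with data whose ground truth is known. It emulates the
statistical structure the analysis assumes, stage by stage:

* per phoneme, a latent rate envelope over the stimulus: brief Gaussian
  events (0.5–2 ms wide, lognormal amplitudes, ~20 events/s scaled by
  `eventRateGain`) on a low baseline, plus a fixed onset component at
  12 ms — tall, narrow events give the envelope genuine millisecond-scale
  structure, as phase-locked auditory responses have;
* per talker, a time shift of SD `talkerSd` and a gain jitter that both
  scale with `talkerSd`, so at `talkerSd = 0` the variants coincide
  exactly with the phoneme template;
* per unit, a lognormal gain, a smooth random temporal profile, and a
  phoneme-level selectivity mask: each unit is driven by a fraction
  `selectivity` of phonemes (and by all talker variants of those), others
  receiving a 5% spontaneous rate. Gating at the phoneme level keeps the
  invariant that talker variants derive from one phoneme-level template;
* spikes drawn per 1-ms bin from an inhomogeneous Poisson process, placed
  uniformly within their bin, then jittered trial-to-trial by Gaussian
  noise of SD `jitterSd`; jittered spikes leaving the stimulus window are
  dropped rather than piled on the boundary. A Poisson process (rather
  than a renewal process with refractoriness) is deliberate: every
  property the pipeline tests depends on rates and timing precision, not
  on interval statistics.

CFs are assigned log-spaced over 0.1–5 kHz, the convention for simulated
fibre banks. All randomness derives from one master seed through named
substreams (envelopes, masks, unit profiles, spikes, noise), so each stage
is independently reproducible.

The presets bundle the qualitative codes of the ascending pathway and were
fixed once, from physiological orders of magnitude: **dense**
(nerve-like: 120 spikes/s, selectivity 1, 0.5-ms jitter, 5-ms talker
shifts), **intermediate** (midbrain-like: 50 spikes/s, selectivity 0.5,
5-ms jitter, 10-ms shifts) and **sparse** (cortex-like: 30 spikes/s,
selectivity 0.15, 15-ms jitter, 20-ms shifts, onset-weighted responses
decaying with a 60-ms constant).

What the generator does *not* emulate: cochlear filtering and phase
locking to stimulus fine structure, refractoriness and adaptation,
correlated noise across units, and real across-talker acoustic structure
(talker variation is a smooth deformation, not a vocal-tract difference).
Passing tests therefore demonstrate that the pipeline measures what it
claims on data with known structure — not that real cortical responses
have any particular property.

## Numerical and design choices

* Window lengths are interpreted as milliseconds = number of 1-ms bins,
  rounded to integers; the printed 54-ms midpoint of the grid is exactly
  reproduced. (Two published descriptions of the distance normalisation
  conflict — "length minus the maximum lag" versus trimming both template
  ends; only the symmetric trim makes every offset's slice exist, so the
  package trims both ends.)
* The lag-search kernel is compiled (Rcpp): it is the innermost loop of
  every evaluation, and an R brute-force oracle in the test suite checks
  it exactly on small instances.
* Smoothing before or after trial averaging is immaterial (both are
  linear); the package smooths single trials first.
* Degenerate inputs error loudly: all-zero sparseness inputs, silent
  units, empty template sets, lags not smaller than half the window.

## Problem sizes used in the checks

The package's own validation runs at desk scale, chosen so the full suite
completes in minutes on one CPU: chance-level recovery uses the complete
default design (48 token classes, 10 repetitions) with 3-unit populations
over 20 seeds in the test suite and 8-unit populations in
`scripts/acceptance.R`; the dense-versus-sparse comparisons use 8 phonemes
x 2 talkers x 6 repetitions with 12-unit populations over 10 seeds; the
generator-property tests use 4-8 phonemes, 1-2 talkers and 1-6 units.
Directional conclusions (orderings of sparseness, specificity, accuracy
and optimal windows between presets) are stable at these sizes; absolute
accuracies of course are not comparable to full-scale recordings.
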