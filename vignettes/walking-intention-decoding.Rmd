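---
title: "Decoding walking intention from fNIRS subband slopes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding walking intention from fNIRS subband slopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsgait)
```

## The problem and the model

`nirsgait` decodes a walker's *intended* gait — step length (small / mid /
large) and synchronous walking speed (low / mid / high) — from multichannel
fNIRS hemoglobin signals recorded *before* movement begins. Six gait states
are walked (SP-LD, SP-MD, MP-LD, MP-MD, MP-HD, LP-MD); along either
dimension they collapse into three classes (e.g. for speed: LD = {SP-LD,
MP-LD}, MD = {SP-MD, MP-MD, LP-MD}, HD = {MP-HD}). Two signal kinds are
analysed per 22-channel recording: total hemoglobin, and the difference
between oxygenated and deoxygenated hemoglobin. The sampling period is
0.13 s.

The decoding pipeline is:

1. **Pre-movement window.** The 180 samples (about 23 s) immediately before
   movement onset, per channel.
2. **Zero-drift removal.** A mathematical morphology filter: the baseline is
   the average of the close–open and open–close compositions with a flat
   structuring element, and is subtracted from the signal.
3. **Normalization.** `xN = 2 (x - min) / (max - min) - 1`, mapping each
   drift-removed channel onto [-1, 1] to damp inter-subject amplitude
   differences.
4. **Subband slope features.** A depth-7 wavelet packet decomposition tiles
   0–Nyquist into 128 terminal subbands of width
   (1/(2·0.13))/128 ≈ 0.03 Hz. The six lowest subbands cover the
   hemodynamically active range 0–0.18 Hz. Each of the six is reconstructed
   on the original time grid, its per-sample first difference is taken as
   the local rate of change, and the 8 slope values just before onset
   (about one second) are averaged. Each trial thus yields a 6 × 22
   band-by-channel feature matrix per signal kind.
5. **Selection cascade.** For each target class, per training subject: the
   mean matrix M1 over the class's constituent states and the absolute
   coefficient of variation M2; masks M3 (bottom 50 % of CV — stable
   cells), M4/M5 (top/bottom 20 % of the mean — strongly
   activated/inhibited); key-channel masks M6 = M3∧M4, M7 = M3∧M5; and the
   region-quantized counts M8/M9 over 22 fixed three-channel regions.
   Across subjects, a (band, region, polarity) cell selected by at least
   60 % of the training cohort becomes a feature region, with the modal
   key-channel count. Contiguous-band regions merge within each of the two
   frequency parts (0–0.09 and 0.09–0.18 Hz), never across. One-way ANOVA
   on every pair of classes filters the candidates at p < 0.05.
6. **GA + SVM.** An adaptive genetic algorithm searches feature subsets;
   the fitness of a subset is the mean leave-one-subject-out accuracy of an
   RBF-kernel multiclass SVM on the training cohort. The best subset trains
   one final SVM, evaluated on held-out subjects (11 test subjects × 6
   states = 66 instances at the study's cohort sizes).

The crossover and mutation probabilities adapt to fitness: for an
above-average individual, `pc = pc1 - (pc1 - pc2)(f' - f_avg)/(f_max -
f_avg)` (else `pc1`), and analogously for `pm`, so that good chromosomes
are disturbed less while poor ones keep exploring.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| pre-movement window | 180 | samples | ~23 s of rest; also suits the dyadic decomposition |
| `se_length` | 31 | samples | ~4 s: several samples of the fastest in-band oscillation (0.18 Hz → 5.6 s period) |
| decomposition depth | 7 | — | 128 leaves of ≈0.03 Hz, matching the observed spectral peak spacing |
| `n_bands` | 6 | — | leaves covering 0–0.18 Hz, where the signal's power concentrates |
| `wavelet` | db4 | — | orthogonal, short support suits 180-sample windows; `db2`/`haar` available |
| `n_avg` | 8 | samples | ~1 s of slopes immediately before onset |
| CV mask fraction | 0.5 | — | bottom half of CV: 66 of 132 cells |
| mean mask fraction | 0.2 | — | top/bottom 26 of 132 cells |
| frequency threshold | 0.6 | — | ≥12 of 20 training subjects |
| ANOVA `alpha` | 0.05 | — | per-pair, no multiplicity correction |
| `pc1, pc2, pm1, pm2` | 0.9, 0.6, 0.1, 0.01 | — | classic adaptive-GA settings |
| population / budget | 50 / 20000 | chromosomes / evaluations | evaluation budget = generations × population |
| SVM | RBF, C = 1, γ = 1/d | — | library defaults (one-vs-one multiclass) |

## What the synthetic cohort emulates — and what it does not

No public recordings accompany the protocol in a machine-readable form, so
the package validates itself on synthetic cohorts
(`synth_config()` / `generate_cohort()`) built from:

* **Slow zero drift**: a random walk sampled at sub-0.005 Hz knot spacing
  (piecewise-linear within a trial) plus a random offset — the component
  the morphology filter must remove.
* **Oscillatory background**: 24 random-phase sinusoids with frequencies
  drawn in 0.005–0.18 Hz and 1/f-weighted amplitudes, normalized to a
  chosen standard deviation (default 0.5). This matches the observed
  concentration of power in 0–0.18 Hz without claiming a physiological
  model.
* **White measurement noise** (default sd 0.05).
* **Injected class effects** (`effect_spec()`): a sinusoid at the target
  subband's centre frequency with a linearly growing envelope, scaled so
  its per-sample derivative at onset equals the requested slope offset.
  Classes differ only in these offsets, at the named (subband, channel,
  signal kind) cells. Each subject scales all effects by
  `max(0, N(1, subject_sd))` (default `subject_sd = 0.2`).

The reference conditions (`demo_effect_map()`) place a walking-speed effect
at subband 2 of totalHb channel 15 and a step-length effect at subband 2 of
oxy−deoxy channel 4, with per-class offsets −d, 0, +d and d = 0.08 signal
units per sample. The magnitude was calibrated once against the generator's
own noise floor: after preprocessing, a trial-level subband-slope feature
has a standard deviation of roughly 0.03 under the default background, and
about 65 % of an injected slope survives the filter–transform path, so
d = 0.08 separates adjacent classes by roughly twice the trial-level noise
— clearly recoverable, far from ceiling, and in the accuracy regime
(60–75 %) typical of single-trial fNIRS decoding.

The generator does **not** emulate optical forward modelling, Beer–Lambert
conversion, motion artifacts, Mayer waves as a distinct process, spatial
correlation between neighbouring channels, or heteroscedastic noise.
Passing tests therefore demonstrate that the pipeline recovers the kind of
structure it assumes — class-dependent pre-onset subband slopes — not that
real cortical hemodynamics carry that structure.

## Numerical choices

* **Morphology filter.** Baseline = ½(close∘open + open∘close) with a flat
  element — the standard bias-balanced composition. Edges are replicated.
  Two consequences matter. First, the filter is effectively a high-pass:
  structures wider than the element are absorbed into the baseline. Second,
  within half an element of the window end, replication makes the baseline
  lag the signal, so slow pre-onset slopes pass partially into the residual
  exactly where the 8-point slope feature is read; measured on a pure
  band-2 ramp, about 95 % of the terminal slope survives. The filter is
  idempotent to machine precision on in-band inputs.
* **Boundary extension for the dyadic grid.** A 180-sample window is
  extended to 256 samples on the right before the periodized transform.
  Even (mirror) reflection was rejected after measurement: it makes the
  extended signal locally even about the window end, forcing every
  reconstructed subband's slope toward zero at the exact point where
  features are read (a band-2 ramp of slope 0.02/sample produced a feature
  of 0.0004). The package uses antisymmetric (point) reflection,
  `x[n + j] = 2 x[n] - x[n - j]`, which continues the local slope through
  the boundary; the same ramp then yields ≈65 % of its nominal slope.
* **Frequency ordering.** Terminal nodes are reordered from tree (Paley)
  order via the binary-reflected Gray code, verified against sinusoid
  probes at every leaf centre; the 0.03 Hz band indexing is meaningful only
  in frequency order.
* **Slopes after reconstruction.** Rates of change are computed on
  reconstructed subband signals (not on coefficients), so features live on
  the original time grid and the "8 points before movement" are literal
  samples.
* **Ties and degeneracies.** Rank thresholds use `floor` (66/26/26 of 132
  cells) with ties broken by ascending (band, channel) index. A cell with
  mean exactly 0 has CV +∞ and is never stability-selected. A class with a
  single constituent state has no between-state variability; its CV is 0
  everywhere. Zero-variance equal-mean ANOVA groups get p = 1. The modal
  key-channel count resolves ties toward the smaller count (a `"max"` rule
  is available).
* **Merged specs.** The scalar of a merged feature vector is the mean of
  its per-band extractions; concatenation was considered and rejected to
  keep one scalar per serial-notation entry.
* **Frequency threshold.** "At least 60 %" is implemented as ≥12/20 for
  the canonical cohort and `ceiling(0.6 n)` otherwise.
* **GA budget.** The iteration budget counts chromosome evaluations
  (generations × population size); a mask-keyed cache avoids recomputing
  repeated subsets but does not extend the search. Elitism of one makes the
  best-so-far trace non-decreasing. All GA randomness comes from a
  dedicated seed, and `generate_cohort()`/`ga_select()` restore the
  caller's random stream.
* **ANOVA scope.** The filter compares per-subject class-mean values
  (training subjects only), every pair of classes, retention on any
  significant pair, no multiple-testing correction.
* **Both polarities** (activation/inhibition) run through separate
  M8/M9 frequency statistics rather than one pooled count.

## Problem sizes used for validation

The shipped tests and the acceptance script run scaled-down but
structurally faithful experiments: 6 training subjects with 11 test
subjects (preserving the 66-instance test structure) for end-to-end
decoding at a GA budget of 2 000 evaluations (population 20); 20 reseeded
6-subject cohorts for effect-recovery frequency; and 12-subject null
cohorts for the chance-level check. The full-scale defaults (31 subjects,
20 training / 11 test, 20 000 evaluations, population 50) are the package
defaults and run in minutes rather than seconds.

## Known limitations

* At a 23-second window, a 0.03 Hz subband is at the time–bandwidth limit:
  a windowed in-band component spreads over neighbouring leaves (an
  injected subband-2 effect also raises subbands 1 and 3, and upper-part
  effects smear across pd4–pd6). The cascade's contiguous-band merging
  absorbs much of this, but band indices should be read as soft labels.
* Spectral leakage means sub-0.03 Hz drift and the lowest band are not
  separable in principle; the morphology filter attenuates both.
* The leave-one-subject-out fitness on a handful of subjects is an
  optimistic, high-variance estimate; the GA can overfit subsets to it,
  which is why held-out test accuracy, not training LOSO accuracy, is the
  quantity validated against permutation nulls.
* With the single-constituent classes (HD, LP) the CV stage carries no
  information and selection rests entirely on the mean masks.
* Class imbalance (3/2/1 constituent states per class) is left unweighted
  by default; a majority classifier reaches 50 %, which is the correct
  baseline for judging decoding above chance.
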