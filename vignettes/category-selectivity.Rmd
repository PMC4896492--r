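---
title: "Category selectivity of broadband gamma: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Category selectivity of broadband gamma: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammasel)
library(dplyr)
```

This vignette is the package's own account of the science it implements: the
signal model, the selectivity statistic and its null, the latency rule, the
mixed-effects topology models, what the synthetic generator does and does not
emulate, and the numerical choices made where the design was genuinely open.

## The measurement model

Subdural electrodes record cortical field potentials during visual naming of
five stimulus categories (faces, animate non-face objects, places, tools,
written words). The quantity analyzed throughout is broadband gamma activity
(BGA): power in the 60–120 Hz band expressed as percent change from a
pre-stimulus baseline. BGA tracks local population firing and the BOLD signal
better than either evoked potentials or narrowband oscillations, which is why
it is the standard currency for icEEG mapping studies.

The signal chain (`extract_bga()`) is, per trial:

1. **Line-noise removal** (`notch_line_noise()`): second-order IIR notches at
   60 and 120 Hz (2 Hz bandwidth), applied forward–backward. A 2 Hz notch has
   a ~160 ms transient time constant, so this stage uses a full second of
   padding (see *Edge handling*).
2. **Gamma band-pass** (`bandpass_gamma()`): minimum-order elliptical IIR
   filter with 0.5 dB passband ripple reaching 30 dB attenuation 5 Hz outside
   the 60–120 Hz band, applied forward–backward so the group delay is zero.
   The one-way design spec is conventional where only "30 dB sidelobe
   attenuation" is fixed by the field; order and ripple are otherwise free,
   and zero-phase application is essential so filtering cannot shift latency
   estimates (the tests assert an injected burst peak moves at most one
   sample).
3. **Analytic amplitude** (`analytic_amplitude()`): magnitude of the FFT-based
   Hilbert analytic signal, smoothed with a Savitzky–Golay FIR (order 5).
   The smoothing frame is specified as a *duration*, 155 ms, converted to an
   odd sample count at the recording's rate — 155 samples at 1 kHz, 311 at
   2 kHz. A fixed frame of exactly 155 samples is a convention some pipelines
   use at both rates; `sg_frame_samples` reproduces that strictly when
   needed. The duration-based default is rate-consistent and is the package's
   choice.
4. **Percent change** (`percent_change()`): the smoothed amplitude is squared
   to power and normalized per trial against the mean power in the −700 to
   −200 ms baseline: `100 * (P(t) − P̄_base) / P̄_base`. The name of the
   quantity is percent *power* change, while the object that is smoothed is
   the analytic *amplitude*; squaring after smoothing honors both the stated
   operation order and the quantity's name. An `measure = "amplitude"` option
   exists for sensitivity analyses.

**Edge handling.** Before any filtering, each epoch is padded by odd
(point-symmetric) reflection — continuous in value and first derivative at
the epoch edges — rounded up so the padded length is 5-smooth (fast FFTs),
and the padding is discarded afterwards. Plain (even) reflection leaves a
derivative kink at the epoch edge whose notch transient leaks ~300 ms into
the epoch; the odd reflection keeps all transients in the discarded padding.

**Contracts worth knowing.** Percent-change BGA is invariant to any positive
rescaling of the raw recording (amplifier gain cancels); the baseline window
must end at or before stimulus onset; a zero-power baseline is an error, not
a silent `Inf`.

## The d′ selectivity index and its null

Per electrode, the mean BGA in the 100–400 ms post-stimulus window gives one
scalar per retained trial (`window_mean_bga()`); the window restricts the
statistic to perceptual processing, before overt naming contaminates the
signal. For category *j* among *K* (here 5), with across-trial means `u` and
sample SDs `o` (denominator n−1; the unbiased default, since the convention
is not otherwise fixed):

$$ d'_j = \frac{u_j - \tfrac{1}{N}\sum_{i \ne j} u_i}
{\sqrt{\tfrac12\bigl(o_j^2 + \tfrac{1}{N}\sum_{i \ne j} o_i^2\bigr)}}, \qquad N = K - 1. $$

One index per category, so an electrode can be selective for several
categories at once. The denominator is the square root of the pooled
variance; the printed form of this expression sometimes loses the radical in
typesetting, but only the square-root reading makes d′ the standard
signal-detection sensitivity index (and dimensionless), and it is the reading
implemented here.

Significance is by permutation (`permutation_null()`): category labels are
shuffled across *all* trials jointly (preserving per-category counts) and all
K indices recomputed, 10,000 times by default. The one-sided p-value is the
fraction of shuffled d′ *strictly greater* than the observed one — ties count
as not greater, and p = 0 is possible. This estimator is implemented exactly
as stated; a `conservative` option applies the (count+1)/(n+1) correction for
users who prefer a never-zero p. Shuffling operates on the window-mean
scalars, not on re-filtered time series: it is the only reading consistent
with 10,000 recomputations per electrode at realistic cost, and label
exchangeability at the scalar level is exactly what the null hypothesis
asserts.

FDR control (`fdr_correct()`) is Benjamini–Hochberg step-up at q = 0.01
within each region × hemisphere family, pooling categories and electrodes —
four families for a bilateral two-region study. The word category exists only
where the word task was administered (left-hemisphere cohorts); electrodes
missing a category are excluded from that category's family with a warning,
never zero-filled.

## Onset latency

`pointwise_contrast()` tests the target category's trials against the pooled
other-category trials at every sample with a two-tailed two-sample t-test.
"Paired" tests are not possible here — trial counts differ across categories
— so the unpaired Welch test is the default ("two-way" read as two-tailed),
with a pooled-variance Student option. When both groups have zero variance at
a sample, p is defined as 1.

`onset_latency()` BH-corrects the p-trace across all samples in the search
window (default 0–700 ms; the correction family for the time dimension is not
fixed by convention, so it is a parameter) and reports the first sample whose
corrected significance is sustained for **more than 100 ms** — rate-aware:
more than 100 consecutive samples at 1 kHz, more than 200 at 2 kHz. A
significant run of exactly 80 ms yields no onset. Detected onsets can lead
the true modulation onset by at most the smoothing half-width (~77 ms at
1 kHz); the tests assert both that bound and recovery of a planted 200 ms
onset within ±40 ms.

`latency_summary()` reports per region × hemisphere × category medians and
SDs (SD is `NA` for singleton cells, not 0) and compares categories pairwise
with the Wilcoxon rank-sum test. The rank-sum (not signed-rank) form is
forced by the data: onsets come from different electrode sets per category,
so there is nothing to pair. The normal approximation without continuity
correction is used, since exact enumeration is degenerate at the tiny
per-cell counts (n = 1–9) this analysis produces; BH correction is applied
across pairs within each region × hemisphere.

## Topology: mixed-effects models of d′ on electrode coordinates

Electrode Talairach coordinates are mean-centered within each
region × hemisphere (`center_coordinates()`), which leaves slopes invariant
to any common shift of the coordinate frame. Because subdural grids lie on a
folded surface, coordinates are strongly collinear — in ventral temporal
cortex z tracks the lateral position (|Spearman ρ| ≈ 0.95 in the synthetic
geometry, by construction), in lateral occipital cortex x tracks y. The axis
dropped from each region's model is therefore fixed (`region_axes()`: VTC
uses x, y; LOC uses z, y) rather than chosen data-adaptively, with the
Spearman screen (`collinearity_screen()`) always reported alongside so the
reader can verify the rationale on their data.

Each category × region × hemisphere cell is fit with

```
d_prime ~ c1 + c2 + c1:c2 + (1 | subject)
```

by REML, with Satterthwaite degrees of freedom for the fixed-effect t-tests
(`lmerTest`). The subject random intercept absorbs between-subject
differences in overall responsiveness and the non-independence of electrodes
within a subject. Relevant behavior at the edges of the design space:

- **Boundary fits.** When the subject variance is estimated at zero the fit
  is flagged (`boundary = TRUE`) and the fixed effects coincide with OLS; the
  tests assert that equality to 1e-6.
- **One electrode per subject.** Subject and residual variances are then
  jointly unidentifiable; the fit is flagged `degenerate` and reduces to OLS
  with classical t-tests rather than reporting an arbitrary variance split.
- **Small cells.** `topology_report()` skips cells with fewer than 6
  electrodes or fewer than 2 subjects (four fixed effects need residual
  degrees of freedom), with a warning naming the skipped cells; absent
  category × hemisphere combinations are absent from the output, not
  zero-filled.
- Optimizer tolerances are tightened (`xtol_abs = ftol_abs = 1e-12`) so
  algebraically equivalent inputs (e.g. shifted coordinates) reproduce
  slopes to ~1e-8.

`tidy()`/`glance()` expose estimates and variance components broom-style;
`autoplot()` draws coefficient forest plots.

## The synthetic generator

`simulate_dataset(sim_config())` emulates the study conditions end to end:

- **Design**: 5 categories with realistic post-rejection trial counts
  (face 46, animate 31, place 49, tool 29, word 38), 1000 Hz sampling
  (2000 Hz supported), epochs −1 to +2 s, baseline −700 to −200 ms. Trials
  are generated as independent epochs; inter-stimulus jitter is irrelevant to
  an epoched analysis and is not simulated.
- **Background**: Fourier-synthesized 1/f² noise (icEEG spectra are close to
  1/f²) plus white noise, optional 60 Hz line component, and an optional pure
  in-band tone used by the closed-form oracle tests.
- **Effect injection**: a band-limited (60–120 Hz) gamma carrier whose
  post-stimulus amplitude is multiplied by `1 + gain`, ramping linearly over
  50 ms at the configured onset (200 ms default). The multiplicative ramp on
  a band-passed carrier produces a realistic BGA step without phase
  artifacts. Gains are injected only at t ≥ 0.
- **Topology**: per category, `gain = max(0, (base + slope × gradient)) ×
  subject modulation`, where the gradient coordinate is the mean-centered
  lateral position in VTC and ventral position in LOC, and the subject
  modulation is `1 + N(0, 0.3)` (floored at 0.1) — multiplicative, so a null
  configuration (`base = slope = 0`) stays exactly null for every subject.
  Default gains (e.g. face: base 0.9, slope +0.02 per mm laterally; place:
  base 0.9, slope −0.02) produce BGA responses of roughly +100–400 %,
  typical of responsive visual electrodes. With these defaults every
  electrode is truly selective for at least one category; partial- or
  null-selectivity cohorts are produced by zeroing bases and slopes, as the
  calibration tests do.
- **Geometry**: 65 % of electrodes in VTC, hemispheres assigned per subject
  in a 60:40 left:right split; z is generated collinear with the lateral
  coordinate in VTC and x with y in LOC, so the collinearity screen and the
  fixed axis-drop rule are exercised by construction.
- **Reproducibility**: one global seed; electrode *k* is generated under
  substream `seed + k`, so any electrode subset is bit-reproducible. A
  consequence worth knowing: datasets generated with *nearby* seeds share
  electrode substreams — use well-separated seeds for independent
  replicates.

What the generator does **not** emulate: artifact and epileptiform
contamination (trial rejection is represented only as an input mask), eye
movements and EMG, common-average referencing (signals are generated as
already referenced), volume conduction between electrodes, and any
relationship between the cortical folding pattern and the gamma response
beyond the configured coordinate gradients. Passing tests therefore
demonstrate calibration and recovery of the statistical machinery under the
stated signal model, not robustness to every artifact of real recordings.

Default cohort sizes in examples and the acceptance script (6 subjects × 8
electrodes, and scans at 2 subjects × 20 electrodes for calibration) are the
package's choice of a size where Monte-Carlo error is small relative to the
effects under test; raw-trace simulation at a full 26-subject, 242-electrode
scale multiplies runtime and memory roughly five-fold without changing any
conclusion of the property suite.

## Deposited electrode-level matrices

`read_mat()` is a self-contained MATLAB v5 reader (numeric, char and nested
cell arrays; zlib-compressed elements; both endiannesses). v7.3 files are
HDF5 containers and are refused with an explicit message rather than
half-parsed. `read_supplementary()` locates the per-cohort variables by name
pattern (coordinates, per-category d′/BGA matrices, the per-subject cell of
stored shuffled d′), validates that electrode counts agree across variables,
and recovers subject attribution from the cell lengths.
`reproduce_supplementary()` then recomputes permutation p-values from the
stored 10,000 shuffles, applies BH at q = 0.01 per region × hemisphere, and
refits the topology models on the stored d′ — the exact computation whose
published outputs are electrode counts and coefficient tables. Since the
estimation details of the original mixed-model software are not fully
determined (ML vs REML, degrees-of-freedom method, optimizer), coefficient
reproduction is expected to be close but not bit-exact.

## Known limitations

- Raw voltage traces are not deposited with the published study, so the BGA
  and latency stages can only be validated against synthetic ground truth;
  the published onset medians (~130–300 ms) are not reproducible from the
  deposited matrices.
- The permutation p-value with 10,000 draws has a granularity of 1e-4;
  FDR decisions at q = 0.01 near the cutoff can flip between reruns with
  different permutation seeds. Stored-shuffle reproduction is deterministic.
- The latency rule's time-dimension FDR family (0–700 ms, BH) is a
  convention; other windows change onsets near threshold.
- `epoch_set` voltage matrices are dense doubles; a 26-subject full-scale
  simulated cohort occupies ~1 GB. The text serialization is
  correspondingly large; it favors transparency and exact round-trips over
  compactness.
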