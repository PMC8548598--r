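---
title: "Methods: circadian trace, phase and rhythmicity analysis in circaflux"
author: "circaflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian trace, phase and rhythmicity analysis in circaflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaflux)
library(dplyr)
```

circaflux analyzes circadian oscillations in two kinds of data: per-region
luminescence traces extracted from bioluminescence time-lapse image stacks
(e.g. Per2::Luc reporter fibroblasts under cyclic feeding-fasting media), and
gene-expression time courses sampled across one circadian cycle. This
vignette explains the models and estimators, the tunable parameters and their
defaults, what the synthetic-data generators emulate, and the numerical
choices made where the design was genuinely open. Every claim here about
estimator behaviour is one the package's test suite or acceptance script
computes; nothing is quoted from external data.

## Synthetic data as ground truth

All quantitative guarantees are established on synthetic data whose
generating parameters are known exactly.

**Traces.** `sim_traces()` draws from

$$y(t) = b + m t + A\, e^{-t/\tau} \sin\!\left(\tfrac{2\pi t}{T} +
\tfrac{2\pi \varphi_0}{T}\right) + \varepsilon_t,\qquad
\varepsilon_t \sim N(0, \sigma^2),$$

a damped sinusoid over a linear baseline — the same functional family the
period estimator fits, so noise-free recovery can be checked to numerical
precision. Defaults mirror a typical luminescence experiment: 30-minute
sampling over 6 days, period near 24 h, amplitude in arbitrary camera units,
damping time constant of a few days (cultures desynchronize gradually), and
a slow negative baseline drift. The generator is seeded and bit-reproducible.

**Image stacks.** `sim_image_stack()` tiles a frame with square ROIs
(regions of interest), gives each ROI one trace (all pixels of an ROI share
the clean value), and adds per-pixel Gaussian shot noise plus Poisson-placed
single-pixel "cosmic ray" spikes of fixed amplitude, returning the spike
coordinates as ground truth. This emulates what matters to the pipeline —
ROI-mean extraction and outlier removal — and deliberately omits optics
(PSF blur, vignetting, registration drift), so passing tests say nothing
about segmentation or flat-field problems in real images.

**Protocols and metabolites.** `protocol()` describes feeding-fasting
schedules: a cycle length (e.g. 20, 24, 26 h), a duty split between
high-nutrient (H: high glucose + insulin) and low-nutrient (L) media such as
12:12 or 4:20, an order (HL, LH, or the constant controls HH/LL), a cycle
count, and free-running afterwards. `protocol_concentration()` implements a
deliberately simple single-compartment nutrient model: the concentration
resets to the fresh medium's level at every change and decays by first-order
uptake, $C(t) = C_{\mathrm{reset}} e^{-k (t - t_{\mathrm{reset}})}$. The
model form is the package's own choice (a named but unspecified "simplified
model" in the motivating experimental design); $k$ is a free parameter with
no default claimed to be physiological. Media concentrations are stored as
free parameters (default H: 25 mM glucose / 10 nM insulin, L: 2 mM / 0 nM).

**Expression matrices.** `expr_truth()` + `sim_expr_counts()` generate the
standard circadian transcriptome design — 6 timepoints every 4 h over 24 h,
4 i.i.d. replicates — with a fraction of genes following
$\mathrm{cpm}(t) = \beta\,(1 + a \cos(2\pi (t - \ell)/T))$ and the rest
flat. Counts are negative binomial (variance $\mu + \phi\mu^2$), the
standard bulk RNA-seq noise model; $\phi = 0$ falls back to Poisson.
Relative amplitudes above 1 are rejected (they would imply negative means).
No batch effects, library-size variation, or gene-gene correlation are
simulated, so the measured type-I error and sensitivity describe idealized
NB noise, not technical artifacts.

## Imaging: from stack to traces

`remove_cosmic_rays()` is a selective median filter: a pixel is replaced by
the median of its $(2r+1)^2$ neighbourhood only when it exceeds the median
by more than a threshold (bright-only by default). Defaults are radius 2 px
and threshold 50, the conventional "remove outliers" settings of interactive
image tools. The selectivity matters: an unconditional median filter would
bias every ROI mean, while the selective rule provably alters no more pixels
than exceed the criterion (a tested invariant).

`rescale_contrast()` exists for display only. It maps the stack to the full
bit range using one global min/max so that relative temporal dynamics are
preserved; per-frame histogram equalization would destroy the amplitude
information downstream fitting needs, which is why the quantitative path
skips contrast adjustment entirely and the function is not part of
`run_pipeline()`'s imaging stage.

`define_roi_grid()` tiles the frame (or a rectangular mask) with
non-overlapping squares of 8, 16 or 32 px; trailing partial ROIs are dropped
rather than shrunk so all ROIs have equal area and their mean intensities
remain comparable. Coordinates are 0-based with half-open bounds.
`extract_traces()` is then simply the per-frame arithmetic mean of each
ROI's pixels; it is exactly linear, and on a noise-free synthetic stack the
extracted traces equal the generating truths to machine precision (the
"pipeline identity" test).

## Detrending

Raw luminescence has a large slowly-decaying baseline. `detrend_running()`
subtracts a running average; the window is centered by default with a
24-hour width (`detrend_window24()`), the approximate expected period. Two
exact closed-form requirements shaped the implementation: a window equal to
the period must annihilate the oscillation's contribution to the baseline
(mean of a sinusoid over one period is zero), and a symmetric window must
annihilate linear drift. A plain arithmetic mean over samples in
$[t - w/2,\, t + w/2]$ satisfies neither exactly on a discrete grid (the two
window endpoints both sample the same phase and are double-counted), so the
running mean is computed as the **integral average** of the linear
interpolant over the window — trapezoid weights, i.e. half weight on the two
endpoint samples. With that choice both identities hold to machine precision
in the interior; edge windows shrink to the observed support, so the first
and last half-window of a detrended trace is approximate.

## Period by damped-sine fitting

`fit_damped_sine()` estimates the dominant period of a detrended trace by
nonlinear least squares on

$$y(t) = A\, e^{-t/\tau} \sin(2\pi t / T + \varphi) + C.$$

Numerical choices:

* **Initialization.** $T$ starts from the discrete periodogram (zero-padded
  FFT) restricted to the allowed period band, default 16–32 h. The top three
  periodogram peaks are used as multi-starts to avoid locking onto a
  harmonic; for each, $A$, $\varphi$, $C$ come from a linear least-squares
  fit at fixed period, and $\tau$ is multi-started at one-third of the
  record, twice the record, and effectively undamped.
* **Optimizer.** Levenberg–Marquardt with box bounds
  (`minpack.lm::nlsLM`), $\tau \in [1, 10^6]$ h, $T$ inside the band,
  tolerances $10^{-10}$. The best of all starts by residual sum of squares
  is kept. An undamped truth is representable as $\tau$ at its upper bound:
  over 6 days the envelope then deviates from 1 by $<2\times10^{-4}$.
* **Failure is data, not an exception.** If the band holds no periodogram
  peak or no start converges, the trace gets a row flagged
  `converged = FALSE`.

Measured behaviour (test suite and `scripts/acceptance.R`): noise-free
random truths with $T \in [20, 28]$ h are recovered with relative error
below $10^{-4}$ (observed $\sim10^{-11}$); 200 traces at signal-to-noise 10
(amplitude 100, noise SD 10, 6 days of 30-min sampling, truth 23.7 h)
give a mean period estimate within 0.005 h of truth. The fit is exactly
homogeneous: scaling a trace scales $\hat A$ and nothing else.

Results are tibbles with one row per trace plus a `fit` list-column of
objects supporting `tidy()`, `glance()` and `autoplot()`.

## Peaks, phase shifts and circular summaries

`detect_peaks()` finds local maxima (optionally after a short running-mean
smoothing), enforces a minimum separation (default 12 h, half a cycle,
keeping the higher peak on conflict) and refines each peak time by a
quadratic fit through the three samples around the maximum — so a refined
peak moves at most half a sample from the discrete argmax.

`peak_phase_shift()` implements the peak-to-peak definition of a phase
shift between two conditions. Pairs are formed by **mutual nearest
neighbour** within half a period: a pair is kept only when each peak is the
other's closest match. One-directional nearest-neighbour matching is not
symmetric in its arguments; mutual matching is, which makes the reported
mean difference exactly antisymmetric under swapping conditions — a
property the tests assert with `expect_identical`. The sign convention is
`mean(t_A - t_B)`: positive when A peaks later.

`acrophase_polar()` summarizes acrophases on the 24-h circle: angle
$\theta = 2\pi h/24$, circular mean from the argument of the mean resultant,
and circular SD $\sqrt{-2\ln \bar R}\cdot 24/(2\pi)$ — the standard
directional-statistics definition, chosen because no formula is canonical in
luminometry software. Amplitude is averaged arithmetically. The summary is
rotation-equivariant (SD invariant, mean rotates), and on von Mises samples
the SD matches the $I_1/I_0$ closed form within Monte-Carlo error.

Peak times are reported at interpolated (sub-sample) resolution by default;
passing `smooth_window_h = 0` and reading the discrete argmax reproduces
half-hour-quantized acrophases where those are wanted for comparability.

## Hilbert phase and Kuramoto synchrony

`analytic_phase()` computes the analytic signal by FFT (positive
frequencies doubled, negative zeroed) and returns its argument as the
wrapped instantaneous phase. Finite recordings with a non-integer number of
cycles leak spectral energy across frequencies and distort the phase; the
implementation multiplies the trace by a full Hann taper first. Because a
positive, slowly varying amplitude envelope does not change the phase of
the analytic signal (Bedrosian's theorem), the taper suppresses leakage
while leaving the quantity of interest intact: interior phase error on pure
sinusoids drops from $\sim0.1$ rad (rectangular window) to below $0.01$ rad.
Samples within 12 h of either end are flagged `edge = TRUE` and should not
be trusted; inputs that do not look detrended (|mean| > 0.1 SD) are flagged
and warned about. Irregular time grids are linearly resampled first.

`unwrap_phase()` removes the $2\pi$ jumps deterministically (a multiple of
$2\pi$ is added wherever a consecutive difference exceeds $\pi$), giving the
continuous phase whose local slope is the instantaneous frequency.
`instantaneous_period()` estimates that slope by local linear regression
over a sliding window (default 24 h) and reports $2\pi/\mathrm{slope}$;
non-advancing windows yield `NA`.

`kuramoto_k()` quantifies ensemble synchrony:
$r(t) = \lvert \tfrac1n \sum_j e^{i\varphi_j(t)} \rvert$, and $K$ is the
**time average of $r(t)$** over the stated interval (default from 0.5 d,
skipping the unreliable edge, to the end). The alternative — pooling phases
across time and taking one resultant — was rejected because common
frequency drift would then masquerade as desynchrony; with the time-averaged
definition $K$ is exactly invariant under any common time-dependent phase
rotation (tested). Identical trajectories give $K = 1$ exactly, evenly
spaced phase offsets give $K = 0$ (roots of unity), independent von Mises
scatter of concentration $\kappa$ gives $K \to I_1(\kappa)/I_0(\kappa)$,
and $K$ is non-increasing in independent phase noise. `kuramoto_curve()`
evaluates $K$ over expanding intervals for synchrony-vs-time plots.

## JTK rhythmicity test

`jtk_scan()` is a from-scratch implementation of the JTK_CYCLE idea: score
each gene's expression ordering against the orderings of cosine reference
waveforms over a grid of peak times (lags), using a tie-aware
Kendall/Jonckheere–Terpstra statistic with an exact permutation null.

* **References** (`jtk_references()`): for each lag on a grid of default
  resolution half the sampling interval (2 h for 4-h sampling: 12 lags per
  24-h period), the ranks of $\cos(2\pi(t-\ell)/T)$ at each sample's
  collection time. Replicates share their timepoint's reference value and
  enter as repeated measurements — never averaged — because the exact null
  is defined by the reference's tie structure.
* **Statistic** (`jt_statistic()`): $S = \sum_{i<j}
  \operatorname{sign}(y_j - y_i)\operatorname{sign}(r_j - r_i)$, and
  $\tau = S / \#\{\text{pairs untied in both}\}$.
* **Exact null** (`jtk_null()`): under permutation of continuous data
  against a reference with tie groups $n_1,\dots,n_g$, $S$ is a
  Jonckheere–Terpstra sum whose distribution factorizes into independent
  Mann–Whitney components (the $q$-binomial factorization behind Harding's
  algorithm). Each component's count distribution is computed exactly by the
  classic recurrence; components are convolved as normalized probabilities
  because raw permutation counts (e.g. $24!/(4!)^6 \approx 3\times10^{16}$)
  exceed exact integer doubles. The suite verifies the null against full
  permutation enumeration for every tie structure up to $n = 8$, to
  $10^{-12}$. Past 50 samples a normal approximation with continuity
  correction takes over (not exercised at the default design size of 24).
* **Scan**: per gene the best (period, lag) maximizes $|\tau|$ (ties resolved
  toward positive concordance, then the earlier lag); the two-sided exact
  p-value of the observed $S$ is Bonferroni-multiplied by the number of
  (period, lag) hypotheses. The period grid defaults to the single value
  24 h: one sampled cycle at 6 timepoints cannot meaningfully distinguish
  periods within 20–28 h, so a period scan is off unless requested.
* **Amplitude**: half the Hodges–Lehmann estimate of peak-to-trough — the
  median of all pairwise differences between samples in the reference's
  peak half ($\cos > 0$) and trough half ($\cos < 0$) — on the cpm scale,
  robust to single outlying replicates. The selection rule
  (`select_rhythmic()`) is adjusted $p < 0.01$ and amplitude $> 10$ cpm,
  and is monotone in both thresholds.

Measured operating characteristics (acceptance script, seeds varied): on
2,000 flat negative-binomial genes the rejection rate at nominal 0.01 is
$\le 0.003$ — conservative, as expected from Bonferroni over a discrete
exact null; on genes with relative amplitude 0.5 at baseline 100 cpm and
low dispersion, sensitivity is $\ge 0.9$ (observed 1.0); a noiseless cosine
recovers its generating lag exactly for every lag on the 2-h grid.

Downstream summaries follow the conventional presentation: `cpm_filter()`
(keep genes with $\ge 1$ cpm in $\ge 3$ samples), `phase_day_night()`
(day = lag in $[0, 12)$, the boundary value 12 counted as night, plus 2-h
bins for polar diagrams), `set_overlaps()` (exclusive Venn region counts),
`heatmap_matrix()` (per-gene replicate-mean profiles min–max scaled to
$[-1, 1]$, constant profiles to 0, rows ordered by lag), and `deg_anova()`
(one-way ANOVA across conditions on replicate-mean temporal profiles at
$P < 0.01$, followed by Tukey HSD at $P < 0.05$ to assign contrasts).

## Orchestration and reproducibility

`run_pipeline()` drives an end-to-end synthetic experiment from a YAML (or
list) configuration: stage list, per-stage parameters, and one master seed.
Per-stage seeds are derived by a stable string hash (`derive_seed()`), so
stages are decoupled yet the whole run is reproducible; a `manifest.json`
records parameters, stage seeds and MD5 checksums of every output, and a
rerun with the same config is byte-identical (tested). Validation reports
every missing key by name; a failing stage keeps partial outputs and an
error log.

All file formats are plain text: wide CSV for traces (one `time_h` column
plus one column per trace), TSV for fits and truth tables, JSON for grids,
schedules and summaries, multi-page 16-bit grayscale TIFF for image stacks
(intensities quantized to gray levels on write, so a written stack
round-trips exactly).

## Problem sizes and limitations

The test suite and acceptance script use 6-day, 30-min-sampled traces
(289 samples), image stacks of 48×64 px with twelve 16-px ROIs, 200-trace
fitting cohorts, and expression matrices of 500–2,000 genes at the 6×4
design — sizes chosen so the full verification runs in about a minute while
every estimator is exercised at its intended operating point.

Known limitations: the Hilbert phase is untrustworthy within ~12 h of the
record ends (flagged, not fixed); the damped-sine model assumes a single
dominant period and will average over period drift (use
`instantaneous_period()` to see drift); JTK at one sampled cycle has no
period resolution and its amplitude threshold is scale-dependent (cpm units
are assumed); the synthetic generators do not model batch effects,
spatially correlated noise, or coupling between oscillators, so synchrony
results describe the statistic, not the biology of coupling.
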