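# circaflux

Circadian analysis of bioluminescence recordings and rhythmic
transcriptomes under cyclic metabolic perturbation.

Peripheral circadian clocks — for example Per2::Luc reporter fibroblasts
kept under programmed feeding-fasting media cycles — are read out in two
ways: continuous luminescence time-lapse imaging, and gene-expression time
courses sampled across one circadian cycle. `circaflux` implements the
complete computational path for both, for experimentalists who need
period, phase, synchrony and rhythmicity numbers with verifiable
statistical behaviour:

* **Imaging → traces**: selective-median cosmic-ray removal, optional
  global contrast rescaling, non-overlapping ROI grids (8/16/32 px), and
  per-ROI mean-intensity traces from multi-page TIFF stacks.
* **Traces → rhythm parameters**: running-average baseline subtraction
  (24-h centered window by default); period estimation by nonlinear least
  squares on the damped sine `A·exp(-t/τ)·sin(2πt/T + φ) + C`; peak
  detection with quadratic refinement; peak-to-peak phase shifts between
  conditions; circular acrophase summaries (circular mean, circular SD
  `sqrt(-2 ln R̄)·24/2π`, mean amplitude); qPCR `2^-ΔΔCt` fold changes.
* **Phase and synchrony**: instantaneous phase from the Hilbert analytic
  signal (Hann-tapered FFT), deterministic phase unwrapping, time-resolved
  period from the continuous-phase slope, and the Kuramoto order parameter
  `K = time-average of |mean_j exp(i φ_j(t))|` over ROI ensembles
  (`K = 1` complete synchrony, `K = 0` incoherent).
* **Rhythmic transcriptomics**: a from-scratch JTK_CYCLE test — cosine
  reference rank patterns over a lag grid, tie-aware Kendall/
  Jonckheere–Terpstra statistic, **exact** permutation null by convolution
  (verified against full enumeration), Bonferroni over the lag×period
  hypotheses, Hodges–Lehmann amplitude — plus cpm filtering, the
  `p < 0.01 & amplitude > 10` selection rule, day/night phase binning,
  phase-ordered `[-1, 1]` heatmap scaling, Venn overlaps between condition
  gene sets, and an ANOVA + Tukey rule for differential mean expression.
* **Synthetic ground truth**: seeded generators for traces, image stacks
  with known spike coordinates, feeding-fasting protocol schedules, a
  first-order metabolite-depletion model, and negative-binomial rhythmic
  count matrices — so every stage is testable end to end without external
  data.

Everything is data-frame-first and pipe-friendly: traces are long tibbles
(`trace`, `time_h`, `value`), results are tibbles, fitted objects support
`tidy()`, `glance()` and `autoplot()`, and `plot_*()` helpers cover the
standard figures (trace panels, synchrony curves, polar acrophase and
phase diagrams, phase-ordered heatmaps).

## Worked example

Three replicate dishes with a known 23.7-h rhythm, detrended, fitted and
summarized:

```r
library(circaflux)
library(dplyr)

truth <- bind_rows(
  trace_truth(period_h = 23.7, phase0_h = 2, amplitude = 120, damping_tau_h = 72,
              baseline_offset = 400, trend_slope = -0.8, noise_sd = 8, seed = 101),
  trace_truth(period_h = 23.7, phase0_h = 2, amplitude = 100, damping_tau_h = 72,
              baseline_offset = 380, trend_slope = -0.7, noise_sd = 8, seed = 102),
  trace_truth(period_h = 23.7, phase0_h = 2, amplitude = 110, damping_tau_h = 72,
              baseline_offset = 390, trend_slope = -0.75, noise_sd = 8, seed = 103))

traces <- sim_traces(truth, t_grid = seq(0, 144, by = 0.5))  # 6 d, 30 min
det    <- detrend_window24(traces)
fits   <- fit_damped_sine(det)
select(fits, trace:rmse)
#> # A tibble: 3 × 7
#>   trace   amplitude damping_tau_h period_h phase_rad offset  rmse
#>   <chr>       <dbl>         <dbl>    <dbl>     <dbl>  <dbl> <dbl>
#> 1 trace01     107.           82.5     23.5     0.482 -1.14   9.31
#> 2 trace02      88.1          85.6     23.6     0.511 -0.831  9.10
#> 3 trace03      97.0          84.2     23.5     0.454 -1.07   9.56
```

The fitted periods sit within 0.2 h of the generating 23.7 h despite noise
and drift. Ensemble synchrony and the acrophase summary:

```r
ph <- unwrap_phase(analytic_phase(det))
kuramoto_k(ph, t_start_h = 12)
#> # A tibble: 1 × 4
#>       K t_start_h t_end_h n_traces
#>   <dbl>     <dbl>   <dbl>    <int>
#> 1 0.935        12     144        3

acrophase_polar(
  acrophase_h = (fits$period_h / 4 - fits$phase_rad * fits$period_h / (2*pi)) %% 24,
  amplitude   = fits$amplitude)
#> # A tibble: 1 × 4
#>   mean_acrophase_h   sd_h mean_amplitude     n
#>              <dbl>  <dbl>          <dbl> <int>
#> 1             4.08 0.0808           97.3     3
```

`K = 0.935` reflects three well-synchronized replicates; the circular mean
acrophase of ~4 h matches the generating phase offset (peak at
`T/4 - phase0 ≈ 3.9 h`), with a circular SD of 0.08 h.

For the transcriptome side, `expr_truth() |> sim_expr_counts()` simulates a
6×4 count matrix, and `cpm() |> cpm_filter() |> jtk_scan() |>
select_rhythmic()` runs the rhythmicity analysis; see the methods vignette
(`vignettes/circaflux-methods.Rmd`) for the statistical details and
`run_pipeline()` for configuration-driven end-to-end runs with a
reproducibility manifest.

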