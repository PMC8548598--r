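#' Ground-truth parameters for a synthetic bioluminescence trace
#'
#' Describes one damped circadian oscillation the way the downstream fitting
#' model sees it: a sinusoid of period `period_h` and acrophase `phase0_h`,
#' damped by `exp(-t / damping_tau_h)`, on top of a linear baseline, with
#' i.i.d. Gaussian measurement noise.
#'
#' @param period_h Oscillation period in hours (> 0). Default 24.
#' @param phase0_h Acrophase offset in hours, in `[0, 24)`; the sine argument
#'   is `2*pi*t/period_h + 2*pi*phase0_h/period_h`.
#' @param amplitude Initial oscillation amplitude, arbitrary units (>= 0).
#' @param damping_tau_h Exponential damping time constant in hours (> 0);
#'   `Inf` means an undamped oscillation.
#' @param baseline_offset Constant baseline level (a.u.).
#' @param trend_slope Linear baseline drift (a.u. per hour).
#' @param noise_sd Standard deviation of additive Gaussian noise (a.u., >= 0).
#' @param seed Integer seed for the noise stream, or `NULL`.
#' @return A one-row tibble of class `trace_truth`.
#' @examples
#' trace_truth(period_h = 23.7, amplitude = 100, noise_sd = 5, seed = 1)
#' @export
trace_truth <- function(period_h = 24, phase0_h = 0, amplitude = 100,
                        damping_tau_h = Inf, baseline_offset = 0,
                        trend_slope = 0, noise_sd = 0, seed = NULL) {
  check_number(period_h, "period_h", min = 1e-6)
  check_number(phase0_h, "phase0_h", min = 0, max = 24 - 1e-12)
  check_number(amplitude, "amplitude", min = 0)
  check_number(damping_tau_h, "damping_tau_h", min = 1e-6, allow_inf = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  out <- tibble(
    period_h = period_h, phase0_h = phase0_h, amplitude = amplitude,
    damping_tau_h = damping_tau_h, baseline_offset = baseline_offset,
    trend_slope = trend_slope, noise_sd = noise_sd,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  class(out) <- c("trace_truth", class(out))
  out
}

trace_model <- function(t, truth) {
  env <- if (is.infinite(truth$damping_tau_h)) 1 else exp(-t / truth$damping_tau_h)
  truth$baseline_offset + truth$trend_slope * t +
    truth$amplitude * env *
      sin(2 * pi * t / truth$period_h + 2 * pi * truth$phase0_h / truth$period_h)
}

#' Simulate bioluminescence traces with known ground truth
#'
#' Evaluates the damped-sine trace model on a time grid and adds seeded
#' Gaussian noise, one trace per row of `truth`. The default 30-min sampling
#' matches typical luminescence time-lapse acquisition.
#'
#' @param truth A `trace_truth` tibble (one row per trace, see
#'   [trace_truth()]); a `trace` column may supply trace names.
#' @param t_grid Strictly increasing sampling times in hours. Default: 6 days
#'   at 30-min intervals.
#' @return A long tibble with columns `trace`, `time_h`, `value`.
#' @examples
#' sim_traces(trace_truth(noise_sd = 2, seed = 7), t_grid = seq(0, 48, 0.5))
#' @export
sim_traces <- function(truth, t_grid = seq(0, 144, by = 0.5)) {
  check_increasing(t_grid)
  if (!all(c("period_h", "amplitude") %in% names(truth))) {
    stop_invalid("`truth` must be a trace_truth tibble")
  }
  ids <- if ("trace" %in% names(truth)) as.character(truth$trace) else
    sprintf("trace%02d", seq_len(nrow(truth)))
  purrr::map(seq_len(nrow(truth)), function(i) {
    row <- truth[i, ]
    clean <- trace_model(t_grid, row)
    noise <- if (row$noise_sd > 0) {
      with_seed_if(if (is.na(row$seed)) NULL else row$seed,
                   rnorm(length(t_grid), 0, row$noise_sd))
    } else {
      rep(0, length(t_grid))
    }
    tibble(trace = ids[i], time_h = t_grid, value = clean + noise)
  }) |>
    list_rbind()
}

#' Feeding-fasting protocol description
#'
#' A daily schedule alternating high-nutrient (H: high glucose + insulin) and
#' low-nutrient (L) media, imposed for `n_cycles` cycles and followed by a
#' free-running interval with no further medium switches.
#'
#' @param cycle_period_h Length of one feeding-fasting cycle in hours
#'   (e.g. 20, 24, 26).
#' @param duty Two hours `(H, L)`: time spent in the H and L media per cycle;
#'   must sum to `cycle_period_h`. E.g. `c(12, 12)` or `c(4, 20)`.
#' @param order One of `"HL"`, `"LH"`, `"HH"`, `"LL"`: which medium the cycle
#'   starts with (HH/LL are constant-media controls using the same switch
#'   times).
#' @param n_cycles Number of cycles (>= 1) before free-running.
#' @param start_zt_h Zeitgeber time of the schedule start, hours.
#' @param media Named list with `H` and `L` numeric vectors
#'   `(glucose_mM, insulin_nM)`.
#' @return A list of class `protocol`.
#' @export
protocol <- function(cycle_period_h = 24, duty = c(12, 12), order = "HL",
                     n_cycles = 3, start_zt_h = 0,
                     media = list(H = c(glucose_mM = 25, insulin_nM = 10),
                                  L = c(glucose_mM = 2, insulin_nM = 0))) {
  check_number(cycle_period_h, "cycle_period_h", min = 1e-6)
  if (length(duty) != 2L || abs(sum(duty) - cycle_period_h) > 1e-9) {
    stop_invalid("`duty` must be two phase durations summing to cycle_period_h")
  }
  order <- match.arg(order, c("HL", "LH", "HH", "LL"))
  check_number(n_cycles, "n_cycles", min = 1)
  structure(
    list(cycle_period_h = cycle_period_h, duty = duty, order = order,
         n_cycles = as.integer(n_cycles), start_zt_h = start_zt_h,
         media = media),
    class = "protocol"
  )
}

#' Expand a protocol into its piecewise-constant media schedule
#'
#' @param p A [protocol()].
#' @param until_h End of the reported schedule in hours after `start_zt_h`;
#'   defaults to one cycle length of free-running after the last switch.
#' @return A tibble with `t_start_h`, `t_end_h`, `state` (`"H"`, `"L"`, or
#'   `"FR"` for free-running) and `switch` (logical: a medium change happens
#'   at `t_start_h`). Switch times are `start_zt_h + duty[first]`, then every
#'   phase boundary up to `n_cycles` full cycles.
#' @export
protocol_schedule <- function(p, until_h = NULL) {
  stopifnot(inherits(p, "protocol"))
  states <- switch(p$order,
    HL = c("H", "L"), LH = c("L", "H"), HH = c("H", "H"), LL = c("L", "L"))
  durs <- switch(p$order,
    HL = p$duty, LH = rev(p$duty), HH = p$duty, LL = p$duty)
  t0 <- p$start_zt_h
  seg <- purrr::map(seq_len(p$n_cycles), function(cy) {
    base <- t0 + (cy - 1) * p$cycle_period_h
    tibble(
      t_start_h = c(base, base + durs[1]),
      t_end_h   = c(base + durs[1], base + p$cycle_period_h),
      state     = states
    )
  }) |> list_rbind()
  fr_start <- t0 + p$n_cycles * p$cycle_period_h
  until_h <- until_h %||% (fr_start + p$cycle_period_h)
  out <- bind_rows(
    seg,
    tibble(t_start_h = fr_start, t_end_h = until_h, state = "FR")
  )
  mutate(out, switch = c(FALSE, out$state[-1] != out$state[-nrow(out)] |
                           out$state[-nrow(out)] != "FR"))
}

#' Simulate a metabolite concentration under a feeding-fasting protocol
#'
#' A simplified single-compartment model of a representative nutrient: at
#' every medium change the concentration resets to the fresh medium's level
#' (`C_H` or `C_L`), and between changes it is depleted by first-order
#' cellular uptake, `dC/dt = -k * C`, so
#' `C(t) = C_reset * exp(-k * (t - t_reset))`. During free-running the decay
#' continues from the last reset. `k = 0` gives a piecewise-constant trace.
#'
#' @param p A [protocol()].
#' @param k_uptake First-order uptake rate, 1/h (>= 0).
#' @param C_H,C_L Fresh-medium concentrations (e.g. glucose, mM) for the H and
#'   L media.
#' @param t_grid Sampling times in hours (strictly increasing).
#' @return A tibble `time_h`, `concentration`, `state`.
#' @export
protocol_concentration <- function(p, k_uptake, C_H = 25, C_L = 2,
                                   t_grid = seq(0, 96, by = 0.1)) {
  stopifnot(inherits(p, "protocol"))
  check_number(k_uptake, "k_uptake", min = 0)
  check_increasing(t_grid)
  sched <- protocol_schedule(p, until_h = max(t_grid) + 1e-9)
  # resets happen at the start of every H/L segment; FR keeps the last medium
  resets <- filter(sched, .data$state %in% c("H", "L"))
  reset_t <- resets$t_start_h
  reset_c <- ifelse(resets$state == "H", C_H, C_L)
  idx <- findInterval(t_grid, reset_t)
  if (any(idx == 0)) stop_invalid("t_grid starts before the protocol start")
  conc <- reset_c[idx] * exp(-k_uptake * (t_grid - reset_t[idx]))
  st <- sched$state[findInterval(t_grid, sched$t_start_h)]
  tibble(time_h = t_grid, concentration = conc, state = st)
}

#' Simulate a bioluminescence image stack with per-ROI ground truth
#'
#' Builds a time-lapse stack in which each cell of a non-overlapping ROI grid
#' carries one damped-sine trace (every pixel of the ROI shares the ROI's
#' clean trace value), then adds optional per-pixel Gaussian shot noise and
#' Poisson-placed single-pixel cosmic-ray spikes of fixed amplitude. The
#' injected spike coordinates are returned as ground truth for evaluating
#' spike-removal recall.
#'
#' @param truth A `trace_truth` tibble with one row per ROI, row-major over
#'   the grid (row index varies slowest).
#' @param frame_shape Integer `(rows, cols)` of each frame in pixels; both
#'   must be divisible by `roi_size_px` times the grid extent.
#' @param roi_size_px ROI edge length in pixels (the grid tiles the frame).
#' @param t_grid Frame timestamps in hours.
#' @param noise_sd Per-pixel Gaussian noise SD (a.u.).
#' @param spike_rate Expected number of cosmic-ray spikes per frame (Poisson).
#' @param spike_amp Spike amplitude added to a single pixel (a.u.).
#' @param seed Integer seed; the stack is bit-reproducible given the seed.
#' @return A list with `stack` (an `image_stack`), `truth` (the input truth
#'   with `trace` ids `r<row>c<col>`), and `spikes` (tibble `frame`, `row`,
#'   `col`, 1-based, one row per injected spike).
#' @export
sim_image_stack <- function(truth, frame_shape, roi_size_px = 16,
                            t_grid = seq(0, 144, by = 0.5),
                            noise_sd = 0, spike_rate = 0, spike_amp = 1000,
                            seed = NULL) {
  check_increasing(t_grid)
  n_rows <- frame_shape[1] %/% roi_size_px
  n_cols <- frame_shape[2] %/% roi_size_px
  if (n_rows * roi_size_px != frame_shape[1] ||
      n_cols * roi_size_px != frame_shape[2]) {
    stop_invalid("frame_shape must be divisible by roi_size_px")
  }
  if (nrow(truth) != n_rows * n_cols) {
    stop_invalid("truth must have one row per ROI (%d x %d = %d rows)",
                 n_rows, n_cols, n_rows * n_cols)
  }
  truth$trace <- sprintf("r%dc%d",
                         rep(seq_len(n_rows), each = n_cols),
                         rep(seq_len(n_cols), times = n_rows))
  nt <- length(t_grid)
  # clean per-ROI values, traces x time
  clean <- vapply(seq_len(nrow(truth)),
                  function(i) trace_model(t_grid, truth[i, ]),
                  numeric(nt))
  frames <- array(0, dim = c(nt, frame_shape[1], frame_shape[2]))
  for (i in seq_len(nrow(truth))) {
    rr <- (i - 1) %/% n_cols + 1
    cc <- (i - 1) %% n_cols + 1
    rows <- ((rr - 1) * roi_size_px + 1):(rr * roi_size_px)
    cols <- ((cc - 1) * roi_size_px + 1):(cc * roi_size_px)
    frames[, rows, cols] <- rep(clean[, i], times = length(rows) * length(cols))
  }
  spikes <- tibble(frame = integer(), row = integer(), col = integer())
  with_seed_if(seed, {
    if (noise_sd > 0) {
      frames <- frames + array(rnorm(length(frames), 0, noise_sd), dim(frames))
    }
    if (spike_rate > 0) {
      n_sp <- rpois(nt, spike_rate)
      spikes <- purrr::map(which(n_sp > 0), function(f) {
        tibble(frame = f,
               row = sample.int(frame_shape[1], n_sp[f], replace = TRUE),
               col = sample.int(frame_shape[2], n_sp[f], replace = TRUE))
      }) |> list_rbind()
      if (nrow(spikes)) {
        frames[cbind(spikes$frame, spikes$row, spikes$col)] <-
          frames[cbind(spikes$frame, spikes$row, spikes$col)] + spike_amp
      }
    }
  })
  list(stack = image_stack(frames, t_grid), truth = truth, spikes = spikes)
}

#' Ground-truth design for a synthetic rhythmic expression matrix
#'
#' Emulates a circadian bulk RNA-seq time course: samples every 4 h over one
#' 24-h cycle with replicates, a fraction of genes oscillating as
#' `cpm(t) = baseline * (1 + rel_amplitude * cos(2*pi*(t - lag)/period))`
#' and the rest flat, with negative-binomial count noise.
#'
#' @param n_genes Number of genes (>= 1).
#' @param frac_rhythmic Fraction of rhythmic genes in `[0, 1]`.
#' @param period_h Common oscillation period (hours).
#' @param lag_h Peak times: either a vector to sample from (default: the 2-h
#'   lag grid) or a single value recycled to all rhythmic genes.
#' @param rel_amplitude Relative amplitude(s) in `[0, 1]`; values above 1
#'   would imply negative mean cpm and are rejected.
#' @param baseline_cpm Baseline expression level(s), cpm.
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param timepoints_h Equally spaced collection times (default 0..20 by 4).
#' @param n_replicates Replicates per timepoint (default 4).
#' @param seed Integer seed.
#' @return A tibble of class `expr_truth`, one row per gene, with the design
#'   stored in attributes `timepoints_h`, `n_replicates`, `seed`.
#' @export
expr_truth <- function(n_genes = 1000, frac_rhythmic = 0.2, period_h = 24,
                       lag_h = seq(0, 22, by = 2), rel_amplitude = 0.5,
                       baseline_cpm = 100, dispersion = 0.05,
                       timepoints_h = seq(0, 20, by = 4), n_replicates = 4,
                       seed = NULL) {
  check_number(n_genes, "n_genes", min = 1)
  check_number(frac_rhythmic, "frac_rhythmic", min = 0, max = 1)
  if (any(rel_amplitude > 1 | rel_amplitude < 0)) {
    stop_invalid("rel_amplitude must lie in [0, 1] (values > 1 imply negative means)")
  }
  if (length(timepoints_h) > 1 && !is_uniform_grid(timepoints_h)) {
    stop_invalid("timepoints_h must be equally spaced")
  }
  if (any(lag_h < 0 | lag_h >= period_h)) {
    stop_invalid("lag_h must lie in [0, period_h)")
  }
  n_r <- round(n_genes * frac_rhythmic)
  tt <- with_seed_if(seed, {
    rhythmic <- c(rep(TRUE, n_r), rep(FALSE, n_genes - n_r))
    tibble(
      gene = sprintf("g%05d", seq_len(n_genes)),
      rhythmic = rhythmic,
      period_h = period_h,
      lag_h = ifelse(rhythmic,
                     sample(rep_len(lag_h, max(n_r, length(lag_h))), n_genes,
                            replace = TRUE),
                     NA_real_),
      rel_amplitude = ifelse(rhythmic, rep_len(rel_amplitude, n_genes), 0),
      baseline_cpm = rep_len(baseline_cpm, n_genes),
      dispersion = rep_len(dispersion, n_genes)
    )
  })
  attr(tt, "timepoints_h") <- timepoints_h
  attr(tt, "n_replicates") <- as.integer(n_replicates)
  attr(tt, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  class(tt) <- c("expr_truth", class(tt))
  tt
}

#' Simulate a rhythmic count matrix from an expression ground truth
#'
#' Draws negative-binomial counts around the cosine (or flat) mean profile of
#' each gene. Mean counts are the model cpm scaled by `lib_size / 1e6`;
#' replicates are i.i.d. at each timepoint.
#'
#' @param truth An [expr_truth()] tibble.
#' @param lib_size Nominal library size used to convert cpm to mean counts.
#' @param seed Integer seed; defaults to the truth's own seed.
#' @return A list with `counts` (genes x samples integer matrix), `samples`
#'   (tibble `sample`, `timepoint_h`, `replicate`), and `truth`.
#' @export
sim_expr_counts <- function(truth, lib_size = 5e6, seed = NULL) {
  stopifnot(inherits(truth, "expr_truth"))
  tp <- attr(truth, "timepoints_h")
  n_rep <- attr(truth, "n_replicates")
  seed <- seed %||% (if (!is.na(attr(truth, "seed")))
    derive_seed(attr(truth, "seed"), "counts") else NULL)
  samples <- tidyr::expand_grid(timepoint_h = tp, replicate = seq_len(n_rep)) |>
    mutate(sample = sprintf("t%02d_r%d", .data$timepoint_h, .data$replicate)) |>
    select("sample", "timepoint_h", "replicate")
  # model cpm, genes x samples
  mu_cpm <- vapply(seq_len(nrow(samples)), function(j) {
    t <- samples$timepoint_h[j]
    ifelse(truth$rhythmic,
           truth$baseline_cpm *
             (1 + truth$rel_amplitude *
                cos(2 * pi * (t - truth$lag_h) / truth$period_h)),
           truth$baseline_cpm)
  }, numeric(nrow(truth)))
  mu <- mu_cpm * lib_size / 1e6
  counts <- with_seed_if(seed, {
    k <- matrix(0L, nrow(mu), ncol(mu))
    for (j in seq_len(ncol(mu))) {
      disp <- truth$dispersion
      pois <- disp <= 0
      kj <- integer(nrow(mu))
      if (any(pois)) kj[pois] <- rpois(sum(pois), mu[pois, j])
      if (any(!pois)) {
        kj[!pois] <- rnbinom(sum(!pois), size = 1 / disp[!pois],
                             mu = mu[!pois, j])
      }
      k[, j] <- kj
    }
    k
  })
  dimnames(counts) <- list(truth$gene, samples$sample)
  list(counts = counts, samples = samples, truth = truth)
}

#' Counts per million
#'
#' @param counts Genes x samples matrix of non-negative counts.
#' @param lib_sizes Library sizes per sample; defaults to the column sums.
#'   When `counts` covers only a subsample of the transcriptome (as in
#'   simulations), pass the true/nominal library sizes so the cpm scale is
#'   not inflated by the missing genes.
#' @return Matrix of the same shape: `counts / lib_sizes * 1e6`.
#' @export
cpm <- function(counts, lib_sizes = NULL) {
  ls <- lib_sizes %||% colSums(counts)
  if (any(ls <= 0)) stop_invalid("all library sizes must be positive")
  sweep(counts, 2, ls, "/") * 1e6
}
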