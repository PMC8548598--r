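# analytic signal via FFT: zero the negative frequencies, double the
# positive ones (DC and Nyquist kept once)
analytic_signal <- function(y) {
  n <- length(y)
  Y <- fft(y)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(Y * h, inverse = TRUE) / n
}

#' Instantaneous phase of detrended traces via the Hilbert transform
#'
#' Computes the analytic signal `y + i * H(y)` of each detrended trace and
#' returns its argument as the wrapped instantaneous phase in `(-pi, pi]`.
#' Before the transform the trace is multiplied by a Hann taper: a positive,
#' slowly varying amplitude envelope leaves the analytic phase unchanged
#' (Bedrosian's theorem) while suppressing the spectral leakage that a
#' finite recording with a non-integer number of cycles otherwise injects
#' into the phase. Samples within `edge_margin_h` of either end, where the
#' taper is steep and the transform is intrinsically unreliable, are flagged
#' `edge = TRUE`. Traces on an irregular time grid are linearly resampled to
#' a uniform grid first.
#'
#' For a pure cosine `cos(2*pi*t/T)` the wrapped phase is `2*pi*t/T` wrapped,
#' i.e. 0 at the peak and advancing by `2*pi` per cycle.
#'
#' @param data Long tibble of detrended traces (`trace`, `time_h`, `value`);
#'   the mean of each trace should be near zero.
#' @param edge_margin_h Width of the unreliable edge region, hours.
#' @return Tibble `trace`, `time_h`, `phase_wrapped` (radians), `edge`
#'   (logical), `detrend_warning` (TRUE when `|mean| > 0.1 * SD`, indicating
#'   the input did not look baseline-subtracted).
#' @export
analytic_phase <- function(data, edge_margin_h = 12) {
  check_trace_tbl(data)
  data |>
    group_by(.data$trace) |>
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$time_h)
      t <- df$time_h; y <- df$value
      if (length(y) < 64) stop_invalid("need at least 64 samples per trace")
      if (!is_uniform_grid(t)) {
        tu <- seq(min(t), max(t), length.out = length(t))
        y <- approx(t, y, xout = tu)$y
        t <- tu
      }
      warn_flag <- abs(mean(y)) > 0.1 * sd(y)
      if (warn_flag) {
        warn(sprintf("trace `%s` does not look detrended (|mean| > 0.1 SD)",
                     key$trace))
      }
      n <- length(y)
      taper <- pmax(0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1))),
                    1e-6)
      ph <- Arg(analytic_signal(y * taper))
      edge <- t - min(t) < edge_margin_h | max(t) - t < edge_margin_h
      tibble(time_h = t, phase_wrapped = ph, edge = edge,
             detrend_warning = warn_flag)
    }) |>
    ungroup()
}

#' Unwrap instantaneous phase into a continuous phase
#'
#' Removes the 2*pi jumps of the wrapped phase: whenever the difference
#' between consecutive samples exceeds pi in absolute value, a multiple of
#' 2*pi is added so that all consecutive differences are below pi. The
#' continuous phase equals the wrapped phase mod 2*pi and its slope gives
#' the instantaneous frequency.
#'
#' @param data Output of [analytic_phase()] (uniform grid per trace), or any
#'   tibble with `trace`, `time_h` and a wrapped-phase column.
#' @param phase_col Name of the wrapped-phase column.
#' @return The input with a `phase_continuous` column added.
#' @export
unwrap_phase <- function(data, phase_col = "phase_wrapped") {
  check_trace_tbl(data, cols = c("time_h", "trace", phase_col))
  data |>
    group_by(.data$trace) |>
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$time_h)
      p <- df[[phase_col]]
      d <- diff(p)
      corr <- cumsum(-2 * pi * round(d / (2 * pi)))
      mutate(df, phase_continuous = p + c(0, corr))
    }) |>
    ungroup()
}

#' Instantaneous period from the continuous phase
#'
#' Estimates a time-resolved period as `2*pi / slope`, where the slope is a
#' local linear regression of the continuous phase against time over a
#' sliding window. Windows with non-positive slope yield `NA` (the phase is
#' not advancing there).
#'
#' @param data Output of [unwrap_phase()].
#' @param window_h Regression window width in hours (>= 4).
#' @return Tibble `trace`, `time_h` (window centers = sample times whose
#'   window fits), `period_h`.
#' @export
instantaneous_period <- function(data, window_h = 24) {
  check_trace_tbl(data, cols = c("time_h", "trace", "phase_continuous"))
  check_number(window_h, "window_h", min = 4)
  data |>
    group_by(.data$trace) |>
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$time_h)
      t <- df$time_h; p <- df$phase_continuous
      half <- window_h / 2
      res <- purrr::map(seq_along(t), function(i) {
        j <- which(t >= t[i] - half - 1e-9 & t <= t[i] + half + 1e-9)
        if (length(j) < 3 || t[i] - min(t) < half - 1e-9 ||
            max(t) - t[i] < half - 1e-9) {
          return(NULL)
        }
        tc <- t[j] - mean(t[j])
        slope <- sum(tc * (p[j] - mean(p[j]))) / sum(tc^2)
        tibble(time_h = t[i],
               period_h = if (slope > 0) 2 * pi / slope else NA_real_)
      })
      list_rbind(purrr::compact(res))
    }) |>
    ungroup()
}

#' Kuramoto order parameter of a trace ensemble
#'
#' Population synchrony of an ensemble of oscillators: at each time point the
#' mean resultant length `r(t) = |mean_j exp(i * phi_j(t))|` of the ensemble
#' phases is computed, and `K` is the time average of `r(t)` over the stated
#' interval. `K = 1` means complete synchrony (all regions of interest share
#' one phase trajectory); evenly spread phases give `K = 0`. Averaging
#' `r(t)` over time (rather than pooling phases across time) keeps common
#' frequency drift from being mistaken for desynchrony.
#'
#' @param data Phase tibble (`trace`, `time_h`, and the phase column) with at
#'   least two traces on a shared grid.
#' @param t_start_h,t_end_h Averaging interval (hours); defaults 12 h (i.e.
#'   0.5 d, skipping the unreliable early edge) to the end of the recording.
#' @param phase_col Phase column to use; wrapped and continuous phases give
#'   identical `K`.
#' @return One-row tibble `K`, `t_start_h`, `t_end_h`, `n_traces`.
#' @export
kuramoto_k <- function(data, t_start_h = 12, t_end_h = NULL,
                       phase_col = "phase_wrapped") {
  check_trace_tbl(data, cols = c("time_h", "trace", phase_col))
  wide <- tidyr::pivot_wider(data[c("time_h", "trace", phase_col)],
                             names_from = "trace",
                             values_from = dplyr::all_of(phase_col)) |>
    arrange(.data$time_h)
  n_traces <- ncol(wide) - 1L
  if (n_traces < 2) stop_invalid("need at least 2 traces for synchrony")
  t_end_h <- t_end_h %||% max(wide$time_h)
  keep <- wide$time_h >= t_start_h - 1e-9 & wide$time_h <= t_end_h + 1e-9
  if (!any(keep)) stop_invalid("interval [%g, %g] h contains no samples",
                               t_start_h, t_end_h)
  ph <- as.matrix(wide[keep, -1])
  r_t <- Mod(rowMeans(exp(1i * ph)))
  tibble(K = mean(r_t), t_start_h = t_start_h, t_end_h = t_end_h,
         n_traces = n_traces)
}

#' Kuramoto synchrony over expanding intervals
#'
#' Reproduces synchrony-vs-time curves: `K` is evaluated on the expanding
#' intervals `[t_start_h, t_end]` for each requested end point, as in plots
#' of K against the interval end.
#'
#' @inheritParams kuramoto_k
#' @param t_ends_h Vector of interval end points (hours); default every 12 h
#'   from `t_start_h + 12` to the end of the recording.
#' @return Tibble with one row per interval: `K`, `t_start_h`, `t_end_h`,
#'   `n_traces`.
#' @export
kuramoto_curve <- function(data, t_start_h = 12, t_ends_h = NULL,
                           phase_col = "phase_wrapped") {
  t_max <- max(data$time_h)
  t_ends_h <- t_ends_h %||% seq(t_start_h + 12, t_max, by = 12)
  purrr::map(t_ends_h, function(te) {
    kuramoto_k(data, t_start_h = t_start_h, t_end_h = te,
               phase_col = phase_col)
  }) |> list_rbind()
}
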