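# trapezoid-weighted running mean: integral average of the linear
# interpolant over [t - w/2, t + w/2] (or [t - w, t] for causal), restricted
# to the observed support (shrinking windows at the edges). Endpoint samples
# get half weight, so a window spanning exactly one period of a sinusoid
# averages to zero and a symmetric window reproduces a linear ramp exactly.
running_baseline <- function(t, y, window_h, centered = TRUE) {
  n <- length(t)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (centered) {
      lo <- t[i] - window_h / 2; hi <- t[i] + window_h / 2
    } else {
      lo <- t[i] - window_h; hi <- t[i]
    }
    j <- which(t >= lo - 1e-9 & t <= hi + 1e-9)
    if (length(j) == 1L) { out[i] <- y[j]; next }
    tj <- t[j]; yj <- y[j]
    dt <- diff(tj)
    w <- c(dt / 2, 0) + c(0, dt / 2)
    out[i] <- sum(w * yj) / sum(w)
  }
  out
}

#' Subtract a running-average baseline from traces
#'
#' Baseline subtraction for luminescence traces: the baseline is a running
#' mean of the data over a `window_h`-hour window (centered by default) and
#' is subtracted from the raw trace. The running mean is the integral average
#' of the trace over the window (trapezoid weights), so a window equal to the
#' oscillation period removes the baseline without touching the oscillation,
#' and linear drift is removed exactly in the interior. Edge windows shrink
#' to the observed support.
#'
#' @param data Long trace tibble (`trace`, `time_h`, `value`).
#' @param window_h Window width in hours (> 0, shorter than the trace).
#' @param centered If `TRUE` (default) the window is `[t - w/2, t + w/2]`;
#'   otherwise causal, `[t - w, t]`.
#' @return The input tibble with `value` replaced by the detrended signal and
#'   a `baseline` column added.
#' @export
detrend_running <- function(data, window_h = 24, centered = TRUE) {
  check_trace_tbl(data)
  check_number(window_h, "window_h", min = 1e-9)
  data |>
    group_by(.data$trace) |>
    group_modify_detrend(window_h, centered) |>
    ungroup()
}

group_modify_detrend <- function(grouped, window_h, centered) {
  dplyr::group_modify(grouped, function(df, key) {
    df <- arrange(df, .data$time_h)
    if (diff(range(df$time_h)) <= window_h / if (centered) 2 else 1) {
      stop_invalid("window_h (%g h) is too long for trace duration (%g h)",
                   window_h, diff(range(df$time_h)))
    }
    bl <- running_baseline(df$time_h, df$value, window_h, centered)
    mutate(df, baseline = bl, value = .data$value - bl)
  })
}

#' Subtract a 24-h centered moving-window baseline
#'
#' Convenience wrapper equal to `detrend_running(data, window_h = 24)`: the
#' window matches the approximate expected circadian period, so any waveform
#' whose period divides 24 h is preserved in the interior.
#'
#' @inheritParams detrend_running
#' @return As [detrend_running()].
#' @export
detrend_window24 <- function(data) detrend_running(data, window_h = 24)

# FFT periodogram restricted to a period band; returns periods of the top
# local maxima (zero-padded for frequency resolution)
periodogram_peaks <- function(t, y, period_bounds_h, n_peaks = 3) {
  dt <- diff(t)[1]
  n <- length(y)
  nfft <- 2^ceiling(log2(n * 8))
  sp <- Mod(fft(c(y - mean(y), rep(0, nfft - n))))[seq_len(nfft %/% 2)]^2
  freq <- (seq_len(nfft %/% 2) - 1) / (nfft * dt)
  per <- ifelse(freq > 0, 1 / freq, Inf)
  in_band <- which(per >= period_bounds_h[1] & per <= period_bounds_h[2])
  if (!length(in_band)) return(numeric(0))
  s <- sp[in_band]
  is_max <- s >= c(-Inf, s[-length(s)]) & s >= c(s[-1], -Inf)
  cand <- in_band[is_max]
  cand <- cand[order(sp[cand], decreasing = TRUE)]
  per[utils::head(cand, n_peaks)]
}

fit_one_damped_sine <- function(t, y, period_bounds_h, tau_max = 1e6) {
  starts <- periodogram_peaks(t, y, period_bounds_h)
  failed <- tibble(amplitude = NA_real_, damping_tau_h = NA_real_,
                   period_h = NA_real_, phase_rad = NA_real_,
                   offset = NA_real_, rmse = NA_real_, converged = FALSE)
  if (!length(starts)) return(failed)
  best <- NULL
  span <- diff(range(t))
  for (T0 in starts) {
    # linear LS at fixed period for amplitude/phase/offset starting values
    X <- cbind(sin(2 * pi * t / T0), cos(2 * pi * t / T0), 1)
    b <- tryCatch(qr.solve(X, y), error = function(e) c(sd(y), 0, mean(y)))
    A0 <- max(sqrt(b[1]^2 + b[2]^2), 1e-9)
    phi0 <- atan2(b[2], b[1])
    for (tau0 in c(span / 3, 2 * span, tau_max / 10)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ A * exp(-t / tau) * sin(2 * pi * t / per + phi) + cc,
          start = list(A = A0, tau = tau0, per = T0, phi = phi0, cc = b[3]),
          lower = c(A = 0, tau = 1, per = period_bounds_h[1], phi = -2 * pi,
                    cc = -Inf),
          upper = c(A = Inf, tau = tau_max, per = period_bounds_h[2],
                    phi = 2 * pi, cc = Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10,
                                               ptol = 1e-10)
        ),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(failed)
  p <- coef(best$fit)
  phi <- wrap_pi(p[["phi"]])
  tibble(amplitude = p[["A"]], damping_tau_h = p[["tau"]],
         period_h = p[["per"]], phase_rad = phi, offset = p[["cc"]],
         rmse = sqrt(best$rss / length(y)), converged = TRUE)
}

#' Fit a damped sine wave to detrended traces
#'
#' Estimates the dominant period of each detrended trace by nonlinear least
#' squares on the model
#' `y(t) = A * exp(-t / tau) * sin(2*pi*t/T + phi) + C`
#' (a sine multiplied by a decaying exponential envelope). The period is
#' initialized from the discrete periodogram restricted to `period_bounds_h`;
#' the top three periodogram peaks are used as multi-starts to avoid harmonic
#' lock-in, and the fit with the smallest residual sum of squares is kept.
#' Non-convergence (or no periodogram peak inside the bounds) yields a row
#' flagged `converged = FALSE` rather than an error.
#'
#' @param data Long trace tibble of detrended values.
#' @param period_bounds_h Allowed period range in hours (default `c(16, 32)`).
#' @return A tibble of class `damped_sine_fits` with one row per trace:
#'   `trace`, `amplitude`, `damping_tau_h`, `period_h`, `phase_rad`,
#'   `offset`, `rmse`, `converged`, plus a `fit` list-column of
#'   `damped_sine_fit` objects usable with [tidy()], [glance()] and
#'   [autoplot()].
#' @export
fit_damped_sine <- function(data, period_bounds_h = c(16, 32)) {
  check_trace_tbl(data)
  if (period_bounds_h[1] <= 0 || diff(period_bounds_h) <= 0) {
    stop_invalid("period_bounds_h must be an increasing positive pair")
  }
  res <- data |>
    group_by(.data$trace) |>
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$time_h)
      if (diff(range(df$time_h)) < 2 * period_bounds_h[1]) {
        stop_invalid("need at least two putative cycles of data")
      }
      est <- fit_one_damped_sine(df$time_h, df$value, period_bounds_h)
      obj <- structure(list(estimates = est, data = df),
                       class = "damped_sine_fit")
      mutate(est, fit = list(obj))
    }) |>
    ungroup()
  class(res) <- c("damped_sine_fits", class(res))
  res
}

#' @export
print.damped_sine_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf(
    "<damped_sine_fit> T = %.3f h, A = %.3g, tau = %.3g h, phi = %.3f rad, rmse = %.3g%s\n",
    e$period_h, e$amplitude, e$damping_tau_h, e$phase_rad, e$rmse,
    if (e$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Tidiers for damped-sine fits
#'
#' `tidy()` returns one row per model parameter; `glance()` returns one row
#' of fit diagnostics.
#'
#' @param x A `damped_sine_fit` object (from the `fit` list-column of
#'   [fit_damped_sine()]).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.damped_sine_fit <- function(x, ...) {
  e <- x$estimates
  tibble(term = c("amplitude", "damping_tau_h", "period_h", "phase_rad",
                  "offset"),
         estimate = c(e$amplitude, e$damping_tau_h, e$period_h, e$phase_rad,
                      e$offset))
}

#' @rdname tidy.damped_sine_fit
#' @export
glance.damped_sine_fit <- function(x, ...) {
  e <- x$estimates
  tibble(rmse = e$rmse, converged = e$converged, n = nrow(x$data),
         duration_h = diff(range(x$data$time_h)))
}

#' @rdname tidy.damped_sine_fit
#' @param object A `damped_sine_fit`.
#' @export
autoplot.damped_sine_fit <- function(object, ...) {
  e <- object$estimates
  df <- object$data
  pred <- if (isTRUE(e$converged)) {
    tibble(time_h = df$time_h,
           value = e$amplitude * exp(-df$time_h / e$damping_tau_h) *
             sin(2 * pi * df$time_h / e$period_h + e$phase_rad) + e$offset)
  } else NULL
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$value)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "time (h)", y = "detrended luminescence (a.u.)")
  if (!is.null(pred)) {
    p <- p + ggplot2::geom_line(data = pred, colour = "#d95f02")
  }
  p
}

#' Detect oscillation peaks in detrended traces
#'
#' Finds local maxima separated by at least `min_separation_h`, optionally
#' after smoothing with a short running mean, and refines each peak time by
#' quadratic interpolation through the three samples around the maximum.
#' When several maxima fall within the separation, the highest is kept.
#'
#' @param data Long trace tibble of detrended values.
#' @param min_separation_h Minimum spacing between reported peaks (default
#'   12 h, half a circadian cycle).
#' @param smooth_window_h Optional running-mean smoothing width in hours
#'   before peak picking (0 = none).
#' @return Tibble `trace`, `peak_time_h`, `peak_value`, ordered in time; a
#'   trace without local maxima contributes no rows.
#' @export
detect_peaks <- function(data, min_separation_h = 12, smooth_window_h = 0) {
  check_trace_tbl(data)
  check_number(min_separation_h, "min_separation_h", min = 1e-9)
  data |>
    group_by(.data$trace) |>
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$time_h)
      t <- df$time_h; y <- df$value
      if (smooth_window_h > 0) y <- running_baseline(t, y, smooth_window_h)
      n <- length(y)
      if (n < 3) return(tibble(peak_time_h = numeric(), peak_value = numeric()))
      cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
      if (!length(cand)) {
        return(tibble(peak_time_h = numeric(), peak_value = numeric()))
      }
      # greedy: keep highest candidates, enforce separation
      cand <- cand[order(y[cand], decreasing = TRUE)]
      kept <- integer(0)
      for (i in cand) {
        if (all(abs(t[i] - t[kept]) >= min_separation_h)) kept <- c(kept, i)
      }
      kept <- sort(kept)
      refine <- vapply(kept, function(i) {
        y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
        den <- y0 - 2 * y1 + y2
        delta <- if (abs(den) < 1e-300) 0 else 0.5 * (y0 - y2) / den
        delta <- max(min(delta, 0.5), -0.5)
        c(t[i] + delta * (t[i + 1] - t[i]),
          y1 - 0.25 * (y0 - y2) * delta)
      }, numeric(2))
      tibble(peak_time_h = refine[1, ], peak_value = refine[2, ])
    }) |>
    ungroup()
}

#' Peak-to-peak phase shift between two conditions
#'
#' The phase shift is the time difference between corresponding peaks of two
#' conditions. Peaks are paired by mutual nearest neighbour within half a
#' period (each retained pair consists of a peak in A and a peak in B that
#' are each other's closest match), which makes the statistic exactly
#' antisymmetric under swapping the two conditions. The reported shift is
#' the mean of `t_A - t_B` over matched pairs: positive when A peaks later
#' than B.
#'
#' @param peaks_a,peaks_b Numeric vectors of peak times (hours), or
#'   [detect_peaks()] tibbles (their `peak_time_h` column is used).
#' @param period_h Oscillation period used for the matching window (default
#'   24 h; the window is `period_h / 2`).
#' @return A one-row tibble `shift_h`, `sd_h`, `n_pairs`, `matched`;
#'   `matched = FALSE` flags failure to pair any peaks (with `shift_h = NA`).
#' @export
peak_phase_shift <- function(peaks_a, peaks_b, period_h = 24) {
  get_times <- function(x) {
    if (is.data.frame(x)) x <- x$peak_time_h
    sort(as.numeric(x))
  }
  a <- get_times(peaks_a); b <- get_times(peaks_b)
  if (!length(a) || !length(b)) stop_invalid("both peak lists must be non-empty")
  near_b <- vapply(a, function(t) which.min(abs(b - t)), integer(1))
  near_a <- vapply(b, function(t) which.min(abs(a - t)), integer(1))
  mutual <- which(near_a[near_b] == seq_along(a))
  d <- a[mutual] - b[near_b[mutual]]
  d <- d[abs(d) <= period_h / 2 + 1e-9]
  if (!length(d)) {
    return(tibble(shift_h = NA_real_, sd_h = NA_real_, n_pairs = 0L,
                  matched = FALSE))
  }
  tibble(shift_h = mean(d), sd_h = if (length(d) > 1) sd(d) else 0,
         n_pairs = length(d), matched = TRUE)
}

#' Circular summary of acrophases for polar plots
#'
#' Summarizes a set of acrophases (peak times on the 24-h clock) with the
#' circular mean, the circular standard deviation
#' `sqrt(-2 * log(Rbar)) * 24 / (2*pi)` (Rbar = mean resultant length), and
#' the arithmetic mean amplitude — the quantities displayed in a polar
#' acrophase diagram (angle = acrophase, arrow length = amplitude).
#'
#' @param acrophase_h Acrophases in hours (taken mod 24).
#' @param amplitude Optional amplitudes (a.u.), same length.
#' @return One-row tibble `mean_acrophase_h` in `[0, 24)`, `sd_h`,
#'   `mean_amplitude`, `n`.
#' @examples
#' acrophase_polar(c(23, 1))  # circular mean 0 h, not 12 h
#' @export
acrophase_polar <- function(acrophase_h, amplitude = NULL) {
  if (!length(acrophase_h)) stop_invalid("need at least one acrophase")
  theta <- 2 * pi * acrophase_h / 24
  z <- mean(exp(1i * theta))
  rbar <- Mod(z)
  mean_h <- wrap_24(Arg(z) * 24 / (2 * pi))
  if (24 - mean_h < 1e-9) mean_h <- 0
  sd_h <- if (rbar >= 1 - 1e-15) 0 else sqrt(-2 * log(rbar)) * 24 / (2 * pi)
  tibble(mean_acrophase_h = mean_h, sd_h = sd_h,
         mean_amplitude = if (is.null(amplitude)) NA_real_ else
           mean(amplitude),
         n = length(acrophase_h))
}

#' qPCR relative quantification by the 2^-ddCt method
#'
#' Fold change of a target gene relative to a reference gene and a calibrator
#' sample: `2^-((ct_gene - ct_ref) - (ct_gene_cal - ct_ref_cal))`.
#'
#' @param ct_gene,ct_ref Target and reference-gene Ct values in the sample.
#' @param ct_gene_cal,ct_ref_cal The same in the calibrator sample.
#' @return Fold change(s), vectorized.
#' @examples
#' fold_change_ddct(24, 20, 25, 20)  # ddCt = -1 -> 2
#' @export
fold_change_ddct <- function(ct_gene, ct_ref, ct_gene_cal, ct_ref_cal) {
  ddct <- (ct_gene - ct_ref) - (ct_gene_cal - ct_ref_cal)
  2^(-ddct)
}
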