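t6d <- seq(0, 144, by = 0.5)

test_that("running-average detrending annihilates constants, drift and the
           matched-period oscillation", {
  const <- one_trace(t6d, rep(5, length(t6d)))
  expect_true(all(detrend_running(const, 24)$value == 0))
  # linear ramp: interior exactly zero (symmetric integral average)
  ramp <- one_trace(t6d, 3 + 2 * t6d)
  dr <- detrend_running(ramp, 24)
  interior <- dr$time_h >= 12 & dr$time_h <= 132
  expect_lt(max(abs(dr$value[interior])), 1e-9)
  # 24 h sinusoid passes through a 24 h window untouched in the interior
  sine <- one_trace(t6d, 100 * sin(2 * pi * t6d / 24))
  ds <- detrend_running(sine, 24)
  expect_lt(max(abs(ds$value[interior] - sine$value[interior])), 1e-6 * 100)
  # 12 h sinusoid also preserved (period divides the window)
  s12 <- one_trace(t6d, 50 * sin(2 * pi * t6d / 12))
  d12 <- detrend_window24(s12)
  expect_lt(max(abs(d12$value[interior] - s12$value[interior])), 1e-6 * 50)
  expect_error(detrend_running(one_trace(0:5, rnorm(6)), 24),
               class = "circaflux_invalid_input")
})

test_that("both detrenders are linear and window24 is definitional", {
  withr::local_seed(11)
  y1 <- rnorm(length(t6d)); y2 <- rnorm(length(t6d))
  d1 <- detrend_running(one_trace(t6d, y1), 24)$value
  d2 <- detrend_running(one_trace(t6d, y2), 24)$value
  d12 <- detrend_running(one_trace(t6d, 2 * y1 - 3 * y2), 24)$value
  expect_equal(d12, 2 * d1 - 3 * d2, tolerance = 1e-12)
  expect_equal(detrend_window24(one_trace(t6d, y1))$value, d1)
})

test_that("damped-sine fit recovers noise-free truths to 1e-4 relative error", {
  withr::local_seed(20)
  for (i in 1:8) {
    T_true <- runif(1, 20, 28)
    tau_true <- runif(1, 24, 200)
    A_true <- runif(1, 50, 150)
    phi_true <- runif(1, -pi, pi)
    y <- A_true * exp(-t6d / tau_true) * sin(2 * pi * t6d / T_true + phi_true)
    fit <- fit_damped_sine(one_trace(t6d, y))
    expect_true(fit$converged)
    expect_equal(fit$period_h, T_true, tolerance = 1e-4)
    expect_equal(fit$amplitude, A_true, tolerance = 1e-4)
    expect_equal(fit$damping_tau_h, tau_true, tolerance = 1e-4)
    expect_lt(abs(circaflux:::wrap_pi(fit$phase_rad - phi_true)), 1e-4)
  }
  # undamped truth: period still exact, envelope effectively flat
  y0 <- 100 * sin(2 * pi * t6d / 24)
  f0 <- fit_damped_sine(one_trace(t6d, y0))
  expect_equal(f0$period_h, 24, tolerance = 1e-4)
})

test_that("fit is homogeneous in amplitude and flags failures", {
  y <- 80 * exp(-t6d / 96) * sin(2 * pi * t6d / 23 + 1)
  f1 <- fit_damped_sine(one_trace(t6d, y))
  f10 <- fit_damped_sine(one_trace(t6d, 10 * y))
  expect_equal(f10$amplitude, 10 * f1$amplitude, tolerance = 1e-6)
  expect_equal(f10$period_h, f1$period_h, tolerance = 1e-8)
  expect_equal(f10$damping_tau_h, f1$damping_tau_h, tolerance = 1e-6)
  expect_equal(f10$phase_rad, f1$phase_rad, tolerance = 1e-6)
  # no periodogram peak inside a sliver band: flagged, not an error
  fbad <- fit_damped_sine(one_trace(t6d, y),
                          period_bounds_h = c(16.0001, 16.0002))
  expect_false(fbad$converged)
  expect_true(is.na(fbad$period_h))
})

test_that("tidy/glance/autoplot expose the fit object", {
  y <- 50 * sin(2 * pi * t6d / 24)
  f <- fit_damped_sine(one_trace(t6d, y))
  obj <- f$fit[[1]]
  td <- generics::tidy(obj)
  expect_setequal(td$term, c("amplitude", "damping_tau_h", "period_h",
                             "phase_rad", "offset"))
  gl <- generics::glance(obj)
  expect_true(gl$converged)
  expect_equal(gl$n, length(t6d))
  expect_s3_class(ggplot2::autoplot(obj), "ggplot")
})

test_that("peak detection finds sinusoid maxima and matches a brute-force
           per-cycle argmax on noisy traces", {
  tr <- one_trace(t6d, sin(2 * pi * t6d / 24))
  pk <- detect_peaks(tr)
  expect_equal(pk$peak_time_h, seq(6, 138, by = 24), tolerance = 0.25)
  expect_equal(nrow(detect_peaks(one_trace(t6d, rep(1, length(t6d))))), 0)
  # noisy trace vs argmax-per-cycle brute-force oracle (same 4-h smoothing;
  # quadratic refinement moves a peak at most half a sample, 0.25 h)
  withr::local_seed(4)
  y <- 100 * sin(2 * pi * t6d / 24) + rnorm(length(t6d), 0, 5)
  pk2 <- detect_peaks(one_trace(t6d, y), smooth_window_h = 4)
  ysm <- circaflux:::running_baseline(t6d, y, 4)
  oracle <- vapply(0:5, function(cy) {
    j <- which(t6d >= cy * 24 & t6d < (cy + 1) * 24)
    t6d[j][which.max(ysm[j])]
  }, numeric(1))
  matched <- vapply(oracle, function(o) min(abs(pk2$peak_time_h - o)),
                    numeric(1))
  expect_lte(max(matched), 0.25 + 1e-9)
  # and the peaks sit near the true acrophases
  truth_pk <- seq(6, 138, by = 24)
  expect_lt(max(abs(sort(pk2$peak_time_h)[1:6] - truth_pk)), 1)
})

test_that("peak-to-peak phase shift recovers offsets and is antisymmetric", {
  a <- seq(6, 138, by = 24)
  expect_equal(peak_phase_shift(a, a)$shift_h, 0)
  b <- a + 6
  expect_equal(peak_phase_shift(a, b)$shift_h, -6)
  expect_identical(peak_phase_shift(a, b)$shift_h,
                   -peak_phase_shift(b, a)$shift_h)
  # two synthetic conditions generated 8 h apart
  trA <- sim_traces(trace_truth(phase0_h = 0, amplitude = 100,
                                noise_sd = 3, seed = 1), t6d)
  trB <- sim_traces(trace_truth(phase0_h = 8, amplitude = 100,
                                noise_sd = 3, seed = 2), t6d)
  pa <- detect_peaks(detrend_window24(trA), smooth_window_h = 4)
  pb <- detect_peaks(detrend_window24(trB), smooth_window_h = 4)
  sh <- peak_phase_shift(pa, pb)
  expect_equal(sh$shift_h, 8, tolerance = 0.5)
  expect_error(peak_phase_shift(numeric(0), a),
               class = "circaflux_invalid_input")
})

test_that("circular acrophase summaries respect the 24-h wrap-around", {
  s <- acrophase_polar(rep(6, 5), rep(2, 5))
  expect_equal(s$mean_acrophase_h, 6)
  expect_equal(s$sd_h, 0)
  expect_equal(s$mean_amplitude, 2)
  expect_equal(acrophase_polar(c(23, 1))$mean_acrophase_h, 0)
  expect_error(acrophase_polar(numeric(0)),
               class = "circaflux_invalid_input")
})

test_that("circular statistics are rotation-invariant and match the von
           Mises closed form", {
  withr::local_seed(8)
  h <- runif(30, 0, 24)
  base <- acrophase_polar(h)
  for (rot in c(3, 11.5, 20)) {
    r <- acrophase_polar((h + rot) %% 24)
    expect_equal(r$sd_h, base$sd_h, tolerance = 1e-10)
    expect_equal(r$mean_acrophase_h,
                 (base$mean_acrophase_h + rot) %% 24, tolerance = 1e-8)
  }
  # population circular SD of von Mises(kappa): sqrt(-2 log(I1/I0)) * 24/2pi
  kappa <- 4
  th <- rvonmises(20000, mu = pi / 3, kappa = kappa)
  samp <- acrophase_polar((th * 24 / (2 * pi)) %% 24)
  pop_sd <- sqrt(-2 * log(besselI(kappa, 1) / besselI(kappa, 0))) * 24 / (2 * pi)
  expect_equal(samp$sd_h, pop_sd, tolerance = 0.05)
})

test_that("2^-ddCt fold change follows its closed form", {
  expect_equal(fold_change_ddct(20, 18, 22, 20), 1)
  expect_equal(fold_change_ddct(20, 18, 23, 20), 2)
  expect_equal(fold_change_ddct(24, 20, 22, 20), 0.25)
})
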