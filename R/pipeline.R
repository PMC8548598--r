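# required keys per stage; validation reports every missing key by name
stage_schema <- list(
  simulate = c("n_traces", "days", "conditions"),
  imaging  = c("roi_size_px", "frame_shape"),
  rhythms  = c("detrend_window_h", "period_bounds_h"),
  sync     = c("t_start_h"),
  jtk      = c("n_genes", "frac_rhythmic", "p_max", "amp_min")
)

validate_config <- function(cfg) {
  problems <- character(0)
  if (is.null(cfg$seed)) problems <- c(problems, "seed")
  if (is.null(cfg$stages)) problems <- c(problems, "stages")
  for (st in cfg$stages %||% character(0)) {
    if (!st %in% names(stage_schema)) {
      problems <- c(problems, sprintf("stages: unknown stage `%s`", st))
      next
    }
    missing <- setdiff(stage_schema[[st]], names(cfg[[st]] %||% list()))
    problems <- c(problems, sprintf("%s.%s", st, missing))
  }
  if (length(problems)) {
    stop_invalid("invalid run config; missing or bad keys: %s",
                 paste(problems, collapse = ", "))
  }
  invisible(cfg)
}

#' Run a configuration-driven synthetic circadian experiment end to end
#'
#' Orchestrates the package's stages from one YAML (or list) configuration:
#' `simulate` generates ground-truth traces per condition (and the protocol
#' schedule), `imaging` builds an image stack and re-extracts ROI traces,
#' `rhythms` detrends, fits damped sines and summarizes acrophases, `sync`
#' computes Hilbert phases and the Kuramoto synchrony curve, and `jtk`
#' simulates a rhythmic count matrix and runs the rhythmicity scan with
#' selection, day/night phase summary and condition overlaps. Each stage
#' draws its seed from the master `seed` via [derive_seed()], every output
#' is a plain-text table, and a `manifest.json` records parameters, stage
#' seeds and MD5 checksums of all outputs, so a rerun with the same config
#' is byte-identical.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Required top-level keys: `seed`, `stages`; per-stage keys are validated
#'   and missing ones are reported by name.
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$out_dir` or a temporary directory.
#' @return The manifest, invisibly, with `out_dir` attached.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_config(cfg)
  out_dir <- out_dir %||% cfg$out_dir %||% tempfile("circaflux_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- lapply(setNames(nm = cfg$stages), function(st)
    derive_seed(cfg$seed, st))
  manifest <- list(package = "circaflux",
                   version = as.character(utils::packageVersion("circaflux")),
                   config = cfg, stage_seeds = seeds)
  state <- new.env(parent = emptyenv())

  for (st in cfg$stages) {
    res <- tryCatch(
      switch(st,
        simulate = stage_simulate(cfg$simulate, seeds$simulate, out_dir, state),
        imaging  = stage_imaging(cfg$imaging, seeds$imaging, out_dir, state),
        rhythms  = stage_rhythms(cfg$rhythms, out_dir, state),
        sync     = stage_sync(cfg$sync, out_dir, state),
        jtk      = stage_jtk(cfg$jtk, seeds$jtk, out_dir, state)
      ),
      error = function(e) e)
    if (inherits(res, "error")) {
      writeLines(sprintf("stage %s failed: %s", st, conditionMessage(res)),
                 file.path(out_dir, "error.log"))
      stop(sprintf("stage `%s` failed (partial outputs kept in %s): %s",
                   st, out_dir, conditionMessage(res)), call. = FALSE)
    }
  }
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest$checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(manifest, list(out_dir = out_dir)))
}

default_t_grid <- function(days) seq(0, days * 24, by = 0.5)

stage_simulate <- function(p, seed, out_dir, state) {
  t_grid <- default_t_grid(p$days)
  conds <- names(p$conditions)
  traces <- purrr::imap(p$conditions, function(cc, nm) {
    truth <- purrr::map(seq_len(p$n_traces), function(i) {
      trace_truth(
        period_h = cc$period_h %||% 24,
        phase0_h = wrap_24(cc$phase0_h %||% 0),
        amplitude = cc$amplitude %||% 100,
        damping_tau_h = cc$damping_tau_h %||% 72,
        baseline_offset = cc$baseline_offset %||% 200,
        trend_slope = cc$trend_slope %||% -0.5,
        noise_sd = cc$noise_sd %||% 5,
        seed = derive_seed(seed, paste0(nm, i))
      )
    }) |> list_rbind()
    truth$trace <- sprintf("%s_%02d", nm, seq_len(p$n_traces))
    mutate(sim_traces(truth, t_grid), condition = nm)
  }) |> list_rbind()
  write_traces(traces[c("time_h", "trace", "value")],
               file.path(out_dir, "traces.csv"))
  utils::write.csv(traces, file.path(out_dir, "traces_long.csv"),
                   row.names = FALSE)
  sched <- protocol_schedule(protocol(n_cycles = max(1, p$days - 3)))
  jsonlite::write_json(sched, file.path(out_dir, "schedule.json"),
                       digits = NA)
  state$traces <- traces
  invisible(TRUE)
}

stage_imaging <- function(p, seed, out_dir, state) {
  n_rows <- p$frame_shape[1] %/% p$roi_size_px
  n_cols <- p$frame_shape[2] %/% p$roi_size_px
  truth <- purrr::map(seq_len(n_rows * n_cols), function(i) {
    trace_truth(period_h = 24, phase0_h = wrap_24(2 * (i %% 4)),
                amplitude = 100, damping_tau_h = 72,
                baseline_offset = 500, noise_sd = 0)
  }) |> list_rbind()
  sim <- sim_image_stack(truth, p$frame_shape, p$roi_size_px,
                         t_grid = default_t_grid(p$days %||% 4),
                         noise_sd = p$noise_sd %||% 2,
                         spike_rate = p$spike_rate %||% 2,
                         spike_amp = p$spike_amp %||% 2000, seed = seed)
  clean <- remove_cosmic_rays(sim$stack,
                              radius_px = p$radius_px %||% 2,
                              threshold = p$threshold %||% 50)
  grid <- define_roi_grid(p$frame_shape, p$roi_size_px)
  roi_traces <- extract_traces(clean, grid)
  write_traces(roi_traces, file.path(out_dir, "roi_traces.csv"))
  jsonlite::write_json(grid$rois, file.path(out_dir, "roi_grid.json"),
                       digits = NA)
  state$roi_traces <- roi_traces
  invisible(TRUE)
}

stage_rhythms <- function(p, out_dir, state) {
  traces <- state$traces %||% stop_invalid("rhythms stage needs simulate first")
  det <- detrend_running(traces[c("trace", "time_h", "value")],
                         window_h = p$detrend_window_h)
  fits <- fit_damped_sine(det, period_bounds_h = unlist(p$period_bounds_h))
  utils::write.table(select(fits, -"fit"),
                     file.path(out_dir, "damped_sine_fits.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  peaks <- detect_peaks(det)
  utils::write.table(peaks, file.path(out_dir, "peaks.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  acro <- fits |>
    filter(.data$converged) |>
    with(acrophase_polar(wrap_24(-phase_rad * period_h / (2 * pi)),
                         amplitude))
  utils::write.table(acro, file.path(out_dir, "acrophase_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  state$detrended <- det
  invisible(TRUE)
}

stage_sync <- function(p, out_dir, state) {
  det <- state$detrended %||% stop_invalid("sync stage needs rhythms first")
  ph <- analytic_phase(det) |> unwrap_phase()
  utils::write.csv(ph, file.path(out_dir, "phases.csv"), row.names = FALSE)
  curve <- kuramoto_curve(ph, t_start_h = p$t_start_h)
  jsonlite::write_json(curve, file.path(out_dir, "kuramoto.json"),
                       digits = NA)
  invisible(TRUE)
}

stage_jtk <- function(p, seed, out_dir, state) {
  truth <- expr_truth(n_genes = p$n_genes, frac_rhythmic = p$frac_rhythmic,
                      seed = seed)
  sim <- sim_expr_counts(truth)
  mat <- cpm_filter(cpm(sim$counts, lib_sizes = rep(5e6, ncol(sim$counts))))
  res <- jtk_scan(mat, sim$samples)
  utils::write.table(res, file.path(out_dir, "jtk_results.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  sel <- select_rhythmic(res, p_max = p$p_max, amp_min = p$amp_min)
  writeLines(sel, file.path(out_dir, "rhythmic_genes.txt"))
  pdn <- phase_day_night(res[res$gene %in% sel, ])
  jsonlite::write_json(select(pdn, -"bins"),
                       file.path(out_dir, "day_night.json"), digits = NA)
  truth_sets <- list(rhythmic_true = truth$gene[truth$rhythmic],
                     rhythmic_called = sel)
  venn <- set_overlaps(truth_sets)
  jsonlite::write_json(venn, file.path(out_dir, "overlap.json"), digits = NA)
  utils::write.table(truth, file.path(out_dir, "expr_truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(TRUE)
}
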