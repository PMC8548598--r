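#' Bioluminescence image stack
#'
#' A light container for a grayscale time-lapse: a 3-D array
#' (time x rows x cols) of intensities in arbitrary units, frame timestamps
#' in hours, and the nominal bit depth used when writing TIFF.
#'
#' @param frames Numeric array, `time x rows x cols`.
#' @param timestamps_h Strictly increasing frame times, hours.
#' @param bit_depth Nominal bit depth for TIFF export (8 or 16).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, timestamps_h, bit_depth = 16L) {
  if (length(dim(frames)) != 3L) {
    stop_invalid("`frames` must be a 3-D array (time x rows x cols)")
  }
  if (length(timestamps_h) != dim(frames)[1]) {
    stop_invalid("one timestamp per frame required")
  }
  check_increasing(timestamps_h, "timestamps_h")
  structure(list(frames = frames, timestamps_h = timestamps_h,
                 bit_depth = as.integer(bit_depth)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frames of %d x %d px, %g-%g h, %d-bit\n",
              d[1], d[2], d[3], min(x$timestamps_h), max(x$timestamps_h),
              x$bit_depth))
  invisible(x)
}

# neighbourhood median via shifted copies; border pixels use the in-frame
# part of their neighbourhood (edge-replicated shifts)
frame_median_filter <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  shifts <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  stack <- vapply(seq_len(nrow(shifts)), function(k) {
    dr <- shifts$dr[k]; dc <- shifts$dc[k]
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    m[ri, ci]
  }, numeric(nr * nc))
  matrix(apply(stack, 1, median), nr, nc)
}

#' Remove cosmic-ray spikes with a selective median filter
#'
#' Replicates the ImageJ-style "Remove Outliers" step: each pixel is compared
#' with the median of its `(2*radius+1)^2` neighbourhood and replaced by that
#' median only when it deviates beyond `threshold`; all other pixels are left
#' untouched, so genuine signal is preserved. Defaults match ImageJ's
#' bright-outlier defaults (radius 2, threshold 50).
#'
#' @param stack An [image_stack()].
#' @param radius_px Neighbourhood radius in pixels (>= 1).
#' @param threshold Minimum deviation from the local median (a.u., > 0).
#' @param bright_only If `TRUE` (default) only positive outliers (spikes) are
#'   replaced; otherwise both signs.
#' @return A filtered `image_stack`.
#' @export
remove_cosmic_rays <- function(stack, radius_px = 2, threshold = 50,
                               bright_only = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  check_number(radius_px, "radius_px", min = 1)
  check_number(threshold, "threshold", min = 1e-12)
  out <- stack
  for (f in seq_len(dim(stack$frames)[1])) {
    m <- stack$frames[f, , ]
    med <- frame_median_filter(m, as.integer(radius_px))
    dev <- m - med
    bad <- if (bright_only) dev > threshold else abs(dev) > threshold
    m[bad] <- med[bad]
    out$frames[f, , ] <- m
  }
  out
}

#' Rescale stack contrast to the full bit range
#'
#' Linear min-max rescaling using one global minimum and maximum across the
#' whole stack, so relative temporal dynamics are preserved (per-frame
#' equalization would destroy the amplitude information downstream fitting
#' needs). A constant stack is returned unchanged. This step is cosmetic and
#' is off by default in the quantitative pipeline.
#'
#' @param stack An [image_stack()].
#' @return A rescaled `image_stack` spanning `[0, 2^bit_depth - 1]`.
#' @export
rescale_contrast <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  lo <- min(stack$frames); hi <- max(stack$frames)
  if (hi <= lo) return(stack)
  stack$frames <- (stack$frames - lo) / (hi - lo) * (2^stack$bit_depth - 1)
  stack
}

#' Define a non-overlapping ROI grid over a frame
#'
#' Tiles the frame (or a rectangular masked region) with square
#' `roi_size_px x roi_size_px` ROIs; trailing partial ROIs are dropped so all
#' ROIs have equal area and their mean intensities stay comparable. Pixel
#' bounds are half-open, 0-based.
#'
#' @param frame_shape Integer `(rows, cols)` in pixels.
#' @param roi_size_px ROI edge length in pixels (commonly 8, 16 or 32).
#' @param origin 0-based `(row, col)` pixel offset of the grid.
#' @param mask Optional logical matrix of `frame_shape`; an ROI is included
#'   only if entirely inside the mask.
#' @return A list of class `roi_grid` with the ROI bounds tibble (`trace`,
#'   `row`, `col`, `r0`, `r1`, `c0`, `c1`), `roi_size_px`, `n_rows`, `n_cols`.
#' @examples
#' define_roi_grid(c(128, 96), 16)  # 8 x 6 = 48 ROIs
#' @export
define_roi_grid <- function(frame_shape, roi_size_px, origin = c(0, 0),
                            mask = NULL) {
  check_number(roi_size_px, "roi_size_px", min = 1)
  n_rows <- (frame_shape[1] - origin[1]) %/% roi_size_px
  n_cols <- (frame_shape[2] - origin[2]) %/% roi_size_px
  if (n_rows < 1 || n_cols < 1) {
    stop_invalid("frame (or mask) smaller than one ROI of %d px", roi_size_px)
  }
  rois <- tidyr::expand_grid(row = seq_len(n_rows), col = seq_len(n_cols)) |>
    mutate(
      r0 = origin[1] + (.data$row - 1L) * roi_size_px,
      r1 = .data$r0 + roi_size_px,
      c0 = origin[2] + (.data$col - 1L) * roi_size_px,
      c1 = .data$c0 + roi_size_px,
      trace = sprintf("r%dc%d", .data$row, .data$col)
    ) |>
    select("trace", "row", "col", "r0", "r1", "c0", "c1")
  if (!is.null(mask)) {
    keep <- vapply(seq_len(nrow(rois)), function(i) {
      all(mask[(rois$r0[i] + 1):rois$r1[i], (rois$c0[i] + 1):rois$c1[i]])
    }, logical(1))
    rois <- rois[keep, ]
    if (nrow(rois) == 0) stop_invalid("mask smaller than one ROI")
  }
  structure(list(rois = rois, roi_size_px = as.integer(roi_size_px),
                 n_rows = n_rows, n_cols = n_cols),
            class = "roi_grid")
}

#' Extract mean-intensity ROI traces from an image stack
#'
#' For every ROI of the grid, the arithmetic mean of its pixels is computed
#' per frame, yielding one luminescence trace per ROI. Trace ids encode the
#' grid position (`r<row>c<col>`).
#'
#' @param stack An [image_stack()].
#' @param grid An [define_roi_grid()] result fitting inside the frames.
#' @return A long tibble `trace`, `time_h`, `value`.
#' @export
extract_traces <- function(stack, grid) {
  stopifnot(inherits(stack, "image_stack"), inherits(grid, "roi_grid"))
  d <- dim(stack$frames)
  if (max(grid$rois$r1) > d[2] || max(grid$rois$c1) > d[3]) {
    stop_invalid("ROI grid does not fit inside the stack frames")
  }
  purrr::map(seq_len(nrow(grid$rois)), function(i) {
    ri <- grid$rois[i, ]
    block <- stack$frames[, (ri$r0 + 1):ri$r1, (ri$c0 + 1):ri$c1, drop = FALSE]
    tibble(trace = ri$trace, time_h = stack$timestamps_h,
           value = apply(block, 1, mean))
  }) |> list_rbind()
}

# TIFF / CSV I/O -------------------------------------------------------------

#' Write and read image stacks as multi-page grayscale TIFF
#'
#' Intensities are clipped to `[0, 2^bit_depth - 1]` and quantized to integer
#' gray levels on write; [read_image_stack()] restores them on that integer
#' scale, so writing an already-quantized stack round-trips exactly.
#' Timestamps are not stored in the TIFF; supply them on read.
#'
#' @param stack An [image_stack()].
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  maxv <- 2^stack$bit_depth - 1
  pages <- purrr::map(seq_len(dim(stack$frames)[1]), function(f) {
    m <- round(pmin(pmax(stack$frames[f, , ], 0), maxv))
    m / maxv
  })
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  invisible(path)
}

#' @rdname write_image_stack
#' @param timestamps_h Frame times in hours for the stack being read; default
#'   30-min spacing from 0.
#' @param bit_depth Bit depth the file was written with.
#' @export
read_image_stack <- function(path, timestamps_h = NULL, bit_depth = 16L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  maxv <- 2^bit_depth - 1
  frames <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (f in seq_along(pages)) frames[f, , ] <- pages[[f]] * maxv
  timestamps_h <- timestamps_h %||% seq(0, by = 0.5,
                                        length.out = length(pages))
  image_stack(frames, timestamps_h, bit_depth)
}

#' Read and write trace sets as wide CSV
#'
#' The on-disk format is one `time_h` column followed by one column per
#' trace; in memory traces are long tibbles (`trace`, `time_h`, `value`).
#'
#' @param data Long trace tibble.
#' @param path CSV path.
#' @return `write_traces()` returns `path` invisibly; `read_traces()` a long
#'   tibble.
#' @export
write_traces <- function(data, path) {
  check_trace_tbl(data)
  wide <- tidyr::pivot_wider(data[c("time_h", "trace", "value")],
                             names_from = "trace", values_from = "value") |>
    arrange(.data$time_h)
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  wide <- utils::read.csv(path, check.names = FALSE)
  if (names(wide)[1] != "time_h") {
    stop_invalid("trace CSV must start with a `time_h` column")
  }
  tidyr::pivot_longer(as_tibble(wide), -"time_h", names_to = "trace",
                      values_to = "value") |>
    select("trace", "time_h", "value") |>
    arrange(.data$trace, .data$time_h)
}
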