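#' @importFrom rlang .data abort warn `%||%`
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across bind_rows bind_cols left_join n rename pull distinct slice
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map2 imap pmap list_rbind
#' @importFrom stats median rnorm rpois rnbinom runif fft coef aov TukeyHSD
#'   lm approx sd setNames quantile residuals pnorm
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# centralised input checks ---------------------------------------------------

stop_invalid <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "circaflux_invalid_input")
}

check_number <- function(x, name, min = -Inf, max = Inf, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= min && x <= max
  if (!ok) {
    stop_invalid("`%s` must be a single number in [%s, %s]", name,
                 format(min), format(max))
  }
  invisible(x)
}

check_increasing <- function(t, name = "t_grid") {
  if (length(t) < 2L || any(diff(t) <= 0)) {
    stop_invalid("`%s` must be strictly increasing with length >= 2", name)
  }
  invisible(t)
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Stage seeds in [run_pipeline()] and in simulation helpers are derived from
#' one master seed with a stable string hash, so that independent stages draw
#' from decoupled streams while the whole run stays reproducible from one
#' integer.
#'
#' @param master Integer master seed.
#' @param label Character label of the stream (e.g. a stage name).
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, label) {
  check_number(master, "master")
  h <- 0
  for (k in utf8ToInt(as.character(label))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer((abs(master) %% 2147483647 * 7919 + h) %% 2147483647)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

wrap_pi <- function(x) {
  # wrap to (-pi, pi]
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

wrap_24 <- function(h) h %% 24

is_uniform_grid <- function(t, tol = 1e-8) {
  d <- diff(t)
  length(d) > 0 && max(abs(d - d[1])) <= tol * max(abs(d[1]), 1)
}

# long trace tibbles: columns time_h, trace, value (+ extras)
check_trace_tbl <- function(data, cols = c("time_h", "trace", "value")) {
  if (!is.data.frame(data) || !all(cols %in% names(data))) {
    stop_invalid("trace data must contain columns %s",
                 paste(cols, collapse = ", "))
  }
  invisible(data)
}
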