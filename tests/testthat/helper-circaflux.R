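# shared fixtures and independent oracles, built in code

# all permutations of a vector (used for exact-null enumeration, n <= 8)
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  unlist(lapply(seq_along(v), function(i) {
    lapply(perms(v[-i]), function(p) c(v[i], p))
  }), recursive = FALSE)
}

# brute-force S statistic: explicit double loop over pairs
brute_S <- function(values, ref) {
  S <- 0
  n <- length(values)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S <- S + sign(values[j] - values[i]) * sign(ref[j] - ref[i])
    }
  }
  S
}

# exact S null by full enumeration of permutations of distinct data
enum_null <- function(ref_ranks) {
  n <- length(ref_ranks)
  sr <- sign(outer(ref_ranks, ref_ranks, "-"))
  ss <- vapply(perms(seq_len(n)), function(p) {
    sum(sign(outer(p, p, "-")) * sr) / 2
  }, numeric(1))
  tab <- table(ss)
  list(S = as.numeric(names(tab)), prob = as.numeric(tab) / length(ss))
}

# seeded von Mises sampler by inverse CDF on a fine grid (test-only; checked
# against the besselI closed form for the mean resultant length)
rvonmises <- function(n, mu, kappa, grid_n = 4096) {
  th <- seq(-pi, pi, length.out = grid_n + 1)[-1]
  dens <- exp(kappa * cos(th))
  mu + sample(th, n, replace = TRUE, prob = dens)
}

# long tibble for a single named trace
one_trace <- function(t, y, id = "a") {
  tibble::tibble(trace = id, time_h = t, value = y)
}

# standard 6 timepoints x 4 replicates sample sheet
design_6x4 <- function() {
  tp <- rep(seq(0, 20, by = 4), each = 4)
  tibble::tibble(sample = sprintf("s%02d", seq_along(tp)), timepoint_h = tp,
                 replicate = rep(1:4, times = 6))
}
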