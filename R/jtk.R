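#' Filter an expression matrix on minimum cpm
#'
#' Keeps genes expressed at or above `min_cpm` in at least `min_samples`
#' samples (defaults: >= 1 cpm in >= 3 samples), the standard low-expression
#' filter before rhythmicity testing.
#'
#' @param mat Genes x samples matrix of cpm values (use [cpm()] on counts).
#' @param min_cpm Minimum expression level (cpm).
#' @param min_samples Minimum number of samples reaching `min_cpm`.
#' @return The filtered matrix, with attributes `n_kept` and `n_dropped`.
#' @export
cpm_filter <- function(mat, min_cpm = 1, min_samples = 3) {
  keep <- rowSums(mat >= min_cpm) >= min_samples
  out <- mat[keep, , drop = FALSE]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Cosine reference rank patterns for the JTK rhythmicity test
#'
#' For each candidate peak time (lag) on a grid covering one period, the
#' reference waveform `cos(2*pi*(t - lag)/period)` is evaluated at every
#' sample's collection time (replicates share their timepoint's value) and
#' converted to ranks. The test then measures the concordance of a gene's
#' expression ordering with each reference ordering.
#'
#' @param timepoints_h Collection time of every sample, hours (length =
#'   number of samples, replicates repeated).
#' @param period_h Reference period, hours.
#' @param lag_resolution_h Spacing of the lag grid; default half the sampling
#'   interval (e.g. 2 h for 4-h sampling, giving 12 lags per 24-h period).
#' @return A list of class `jtk_refs`: `ranks` (lags x samples matrix of
#'   reference ranks), `lags_h`, `period_h`, `timepoints_h`.
#' @export
jtk_references <- function(timepoints_h, period_h = 24,
                           lag_resolution_h = NULL) {
  if (length(timepoints_h) < 2) stop_invalid("need >= 2 samples")
  check_number(period_h, "period_h", min = 1e-6)
  span <- diff(range(timepoints_h))
  if (period_h > 2 * (span + min(diff(sort(unique(timepoints_h)))))) {
    stop_invalid("period %g h is incompatible with a %g h sampling span",
                 period_h, span)
  }
  lag_resolution_h <- lag_resolution_h %||%
    (min(diff(sort(unique(timepoints_h)))) / 2)
  if (lag_resolution_h <= 0 || lag_resolution_h > period_h) {
    stop_invalid("empty lag grid: lag_resolution_h must lie in (0, period_h]")
  }
  lags <- seq(0, period_h - lag_resolution_h / 2, by = lag_resolution_h)
  ranks <- t(vapply(lags, function(lag) {
    ref <- cos(2 * pi * (timepoints_h - lag) / period_h)
    rank(round(ref, 9), ties.method = "average")
  }, numeric(length(timepoints_h))))
  structure(list(ranks = ranks, lags_h = lags, period_h = period_h,
                 timepoints_h = timepoints_h),
            class = "jtk_refs")
}

#' Jonckheere-Terpstra-style concordance statistic
#'
#' The tie-aware Kendall-type statistic at the heart of the JTK test:
#' `S = sum over pairs i < j of sign(y_j - y_i) * sign(r_j - r_i)`, and
#' `tau = S / (number of pairs untied in both the data and the reference)`.
#'
#' @param values Numeric gene values (one per sample).
#' @param ref_ranks Reference ranks of equal length.
#' @return One-row tibble `S`, `tau`, `n_pairs` (untied comparable pairs);
#'   `tau` is `NA` when all values are tied (flagged by `degenerate`).
#' @export
jt_statistic <- function(values, ref_ranks) {
  if (length(values) != length(ref_ranks)) {
    stop_invalid("values and reference must have equal length")
  }
  sd_ <- sign(outer(values, values, "-"))
  sr_ <- sign(outer(ref_ranks, ref_ranks, "-"))
  S <- sum(sd_ * sr_) / 2
  n_pairs <- sum(sd_ != 0 & sr_ != 0) / 2
  degenerate <- all(values == values[1])
  tibble(S = S, tau = if (n_pairs > 0) S / n_pairs else NA_real_,
         n_pairs = n_pairs, degenerate = degenerate)
}

# exact Mann-Whitney U count distribution for group sizes m, n, via the
# classic recurrence N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1) with
# N(u; 0, n) = N(u; m, 0) = [u == 0]; returns counts over u = 0..m*n
mw_counts <- function(m, n) {
  len <- m * n + 1
  f <- lapply(0:n, function(nn) c(1, rep(0, len - 1)))  # m' = 0 row
  for (mm in seq_len(m)) {
    g <- vector("list", n + 1)
    g[[1]] <- c(1, rep(0, len - 1))                      # n' = 0
    for (nn in seq_len(n)) {
      shifted <- c(rep(0, nn), f[[nn + 1]])[seq_len(len)]
      g[[nn + 1]] <- shifted + g[[nn]]
    }
    f <- g
  }
  f[[n + 1]]
}

#' Exact permutation null distribution of the JTK statistic
#'
#' Distribution of `S` under random permutation of (continuous) data against
#' a reference with tie groups of sizes `n_1, ..., n_g`. The statistic is a
#' Jonckheere-Terpstra sum over successive tie groups, whose exact null
#' factorizes into independent Mann-Whitney components (the q-binomial
#' factorization underlying Harding's algorithm); the per-factor count
#' distributions are exact and are convolved as normalized probabilities.
#' Beyond `exact_limit` samples a normal approximation with continuity
#' correction is used.
#'
#' @param ref_ranks A reference rank vector (one row of
#'   [jtk_references()]`$ranks`), or a `jtk_refs` object (its first row).
#' @param exact_limit Maximum number of samples for the exact computation.
#' @return A list of class `jtk_null`: `S` (support, step 2), `prob`,
#'   `max_S`, `exact`.
#' @export
jtk_null <- function(ref_ranks, exact_limit = 50) {
  if (inherits(ref_ranks, "jtk_refs")) ref_ranks <- ref_ranks$ranks[1, ]
  sizes <- as.integer(table(ref_ranks))
  N <- sum(sizes)
  max_S <- (N^2 - sum(sizes^2)) / 2
  if (max_S == 0) {
    return(structure(list(S = 0, prob = 1, max_S = 0, exact = TRUE),
                     class = "jtk_null"))
  }
  if (N <= exact_limit) {
    probs <- 1
    cum <- sizes[1]
    for (g in sizes[-1]) {
      f <- mw_counts(cum, g)
      probs <- convolve_probs(probs, f / sum(f))
      cum <- cum + g
    }
    structure(list(S = 2 * (0:max_S) - max_S, prob = probs, max_S = max_S,
                   exact = TRUE),
              class = "jtk_null")
  } else {
    # moments of JT under H0 (sum of independent MW components)
    mu <- max_S / 2
    var <- 0
    cum <- sizes[1]
    for (g in sizes[-1]) {
      var <- var + cum * g * (cum + g + 1) / 12
      cum <- cum + g
    }
    structure(list(S = NULL, prob = NULL, max_S = max_S, exact = FALSE,
                   mean_jt = mu, var_jt = var),
              class = "jtk_null")
  }
}

convolve_probs <- function(a, b) {
  out <- rep(0, length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    if (a[i] > 0) {
      out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
    }
  }
  out
}

# two-sided exact p for an observed S
jtk_pvalue <- function(null, S_obs) {
  if (null$max_S == 0) return(1)
  if (null$exact) {
    min(1, sum(null$prob[abs(null$S) >= abs(S_obs) - 1e-9]))
  } else {
    # S = 2*JT - max_S; two-sided normal with continuity correction
    jt <- (abs(S_obs) + null$max_S) / 2
    z <- (jt - 0.5 - null$mean_jt) / sqrt(null$var_jt)
    min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  }
}

#' JTK rhythmicity scan of an expression matrix
#'
#' For every gene, scans all candidate (period, lag) reference waveforms,
#' keeps the best-concordant one (maximum `|tau|`, ties resolved toward
#' positive concordance and then the earlier lag), and computes a two-sided
#' exact permutation p-value for the observed `S` from [jtk_null()] with a
#' Bonferroni adjustment over the number of (period, lag) hypotheses tested.
#' The reported amplitude is half the Hodges-Lehmann estimate of the
#' peak-to-trough difference at the best lag (the median of all pairwise
#' differences between samples in the reference's peak half and samples in
#' its trough half), on the expression scale of `mat`.
#'
#' @param mat Genes x samples matrix (cpm scale), e.g. from [cpm_filter()].
#' @param samples Sample annotation tibble with columns `sample` matching
#'   `colnames(mat)` and `timepoint_h`.
#' @param periods_h Candidate periods in hours; default a single 24-h period
#'   (a one-cycle, six-timepoint design cannot resolve a period scan).
#' @param lag_resolution_h Lag grid spacing; see [jtk_references()].
#' @return A tibble of class `jtk_result`: `gene`, `period_h`, `lag_h`,
#'   `tau`, `S`, `p`, `adj_p` (Bonferroni), `amplitude`. Degenerate
#'   (all-tied) genes get `p = 1`, `amplitude = 0`.
#' @export
jtk_scan <- function(mat, samples, periods_h = 24, lag_resolution_h = NULL) {
  if (is.null(colnames(mat)) || !all(colnames(mat) %in% samples$sample)) {
    stop_invalid("all matrix columns must appear in `samples$sample`")
  }
  tp <- samples$timepoint_h[match(colnames(mat), samples$sample)]
  refs <- purrr::map(periods_h, function(P) {
    jtk_references(tp, period_h = P, lag_resolution_h = lag_resolution_h)
  })
  # precompute per-reference sign matrices and nulls (cached by tie structure)
  null_cache <- list()
  ref_tbl <- purrr::map(refs, function(rf) {
    purrr::map(seq_along(rf$lags_h), function(li) {
      r <- rf$ranks[li, ]
      sr <- sign(outer(r, r, "-"))
      key <- paste(sort(table(r)), collapse = ",")
      if (is.null(null_cache[[key]])) {
        null_cache[[key]] <<- jtk_null(r)
      }
      cosref <- cos(2 * pi * (tp - rf$lags_h[li]) / rf$period_h)
      list(period_h = rf$period_h, lag_h = rf$lags_h[li], sr = sr,
           null = null_cache[[key]], peak = cosref > 1e-9,
           trough = cosref < -1e-9)
    })
  }) |> purrr::list_flatten()
  n_hyp <- length(ref_tbl)

  res <- purrr::map(seq_len(nrow(mat)), function(gi) {
    y <- mat[gi, ]
    sdm <- sign(outer(y, y, "-"))
    if (all(sdm == 0)) {
      return(tibble(gene = rownames(mat)[gi], period_h = NA_real_,
                    lag_h = NA_real_, tau = NA_real_, S = 0, p = 1,
                    adj_p = 1, amplitude = 0))
    }
    best <- NULL
    for (rf in ref_tbl) {
      S <- sum(sdm * rf$sr) / 2
      n_pairs <- sum(sdm != 0 & rf$sr != 0) / 2
      tau <- if (n_pairs > 0) S / n_pairs else 0
      if (is.null(best) ||
          abs(tau) > abs(best$tau) + 1e-12 ||
          (abs(abs(tau) - abs(best$tau)) <= 1e-12 && tau > best$tau)) {
        best <- list(rf = rf, S = S, tau = tau)
      }
    }
    p <- jtk_pvalue(best$rf$null, best$S)
    amp <- hl_amplitude(y, best$rf$peak, best$rf$trough)
    tibble(gene = rownames(mat)[gi] %||% as.character(gi),
           period_h = best$rf$period_h, lag_h = best$rf$lag_h,
           tau = best$tau, S = best$S, p = p,
           adj_p = min(1, p * n_hyp), amplitude = amp)
  }) |> list_rbind()
  class(res) <- c("jtk_result", class(res))
  res
}

# half the Hodges-Lehmann peak-to-trough estimate
hl_amplitude <- function(y, peak, trough) {
  if (!any(peak) || !any(trough)) return(0)
  diffs <- outer(y[peak], y[trough], "-")
  max(median(diffs) / 2, 0)
}

#' Select rhythmic genes from a JTK scan
#'
#' The selection rule for calling a gene circadian: Bonferroni-adjusted
#' p-value below `p_max` and amplitude above `amp_min` (defaults
#' `p < 0.01`, amplitude > 10 on the cpm scale).
#'
#' @param res A [jtk_scan()] result.
#' @param p_max Maximum adjusted p-value (exclusive).
#' @param amp_min Minimum amplitude (exclusive).
#' @return Character vector of selected gene ids.
#' @export
select_rhythmic <- function(res, p_max = 0.01, amp_min = 10) {
  res$gene[res$adj_p < p_max & res$amplitude > amp_min]
}

#' Day/night phase distribution of rhythmic genes
#'
#' Splits gene peak times (JTK lags mod 24) into the light/day half
#' `[0, 12)` and the dark/night half `[12, 24)` (a lag of exactly 12 h
#' counts as night), and bins them on a 2-h grid for polar phase diagrams.
#'
#' @param lag_h Peak times in hours of the selected rhythmic genes; a
#'   [jtk_scan()] result may be given (its `lag_h` is used).
#' @param bin_h Histogram bin width (hours).
#' @return One-row tibble `n`, `day_fraction`, `night_fraction`, `empty`,
#'   with the binned histogram in the `bins` list-column (`bin_start_h`,
#'   `bin_mid_h`, `count`). Day and night fractions sum to 1 when `n > 0`.
#' @export
phase_day_night <- function(lag_h, bin_h = 2) {
  if (is.data.frame(lag_h)) lag_h <- lag_h$lag_h
  lag_h <- lag_h[!is.na(lag_h)]
  if (!length(lag_h)) {
    return(tibble(n = 0L, day_fraction = NA_real_, night_fraction = NA_real_,
                  empty = TRUE, bins = list(tibble())))
  }
  h <- wrap_24(lag_h)
  day <- mean(h < 12)
  starts <- seq(0, 24 - bin_h, by = bin_h)
  counts <- vapply(starts, function(b) sum(h >= b & h < b + bin_h),
                   integer(1))
  tibble(n = length(h), day_fraction = day, night_fraction = 1 - day,
         empty = FALSE,
         bins = list(tibble(bin_start_h = starts,
                            bin_mid_h = starts + bin_h / 2,
                            count = counts)))
}

#' Exclusive overlap (Venn) counts of gene sets
#'
#' Cardinalities of every exclusive region of the Venn partition of two or
#' more sets (e.g. rhythmic genes per condition).
#'
#' @param sets Named list of character vectors.
#' @return Tibble with one logical membership column per set, plus `region`
#'   (e.g. `"HL&LH"`) and the exclusive `count`.
#' @export
set_overlaps <- function(sets) {
  if (length(sets) < 2) stop_invalid("need at least 2 sets")
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_along(sets)]
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0) {
    member <- matrix(logical(0), 0, length(sets),
                     dimnames = list(NULL, names(sets)))
  }
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(combos) <- names(sets)
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  counts <- vapply(seq_len(nrow(combos)), function(i) {
    patt <- as.logical(combos[i, ])
    if (nrow(member) == 0) return(0L)
    sum(apply(member, 1, function(m) all(m == patt)))
  }, integer(1))
  out <- as_tibble(combos)
  out$region <- vapply(seq_len(nrow(combos)), function(i) {
    paste(names(sets)[as.logical(combos[i, ])], collapse = "&")
  }, character(1))
  out$count <- counts
  arrange(out, dplyr::desc(rowSums(combos)), .data$region)
}

#' Phase-ordered, per-gene scaled matrix for rhythmic-gene heatmaps
#'
#' For each selected gene, the mean temporal profile across replicates is
#' min-max scaled to `[-1, 1]` (a constant profile maps to all zeros), and
#' genes are ordered by their estimated peak time (JTK lag) ascending, the
#' standard presentation of a phase-ordered rhythmic-transcriptome heatmap.
#'
#' @param mat Genes x samples cpm matrix.
#' @param samples Sample annotations (`sample`, `timepoint_h`).
#' @param res A [jtk_scan()] result providing lags.
#' @param genes Genes to include (non-empty; e.g. from [select_rhythmic()]).
#' @return A long tibble `gene` (factor ordered by lag), `lag_h`,
#'   `timepoint_h`, `scaled`.
#' @export
heatmap_matrix <- function(mat, samples, res, genes) {
  if (!length(genes)) stop_invalid("`genes` must be non-empty")
  genes <- intersect(genes, rownames(mat))
  tp <- samples$timepoint_h[match(colnames(mat), samples$sample)]
  lag <- res$lag_h[match(genes, res$gene)]
  ord <- order(lag)
  genes <- genes[ord]; lag <- lag[ord]
  purrr::map(seq_along(genes), function(i) {
    y <- mat[genes[i], ]
    prof <- tapply(y, tp, mean)
    lo <- min(prof); hi <- max(prof)
    scaled <- if (hi > lo) 2 * (prof - lo) / (hi - lo) - 1 else prof * 0
    tibble(gene = genes[i], lag_h = lag[i],
           timepoint_h = as.numeric(names(prof)), scaled = as.numeric(scaled))
  }) |>
    list_rbind() |>
    mutate(gene = factor(.data$gene, levels = genes))
}

#' Differentially expressed genes by ANOVA on mean temporal profiles
#'
#' For every gene, the replicate-mean expression profile (one value per
#' timepoint and condition) is compared across conditions by one-way ANOVA;
#' genes passing `p_anova` are then assigned to specific condition contrasts
#' by Tukey's honest-significant-difference multiple-comparison test at
#' `p_posthoc`.
#'
#' @param mat Genes x samples cpm matrix covering >= 2 conditions.
#' @param samples Sample annotations with `sample`, `timepoint_h`,
#'   `condition`.
#' @param p_anova ANOVA significance threshold (default 0.01).
#' @param p_posthoc Tukey per-contrast threshold (default 0.05).
#' @return A tibble `gene`, `p_anova`, `contrast`, `p_tukey`, `significant`
#'   (one row per gene x pairwise contrast); a gene is a DEG for a contrast
#'   when `p_anova < p_anova` threshold and `p_tukey < p_posthoc`.
#' @export
deg_anova <- function(mat, samples, p_anova = 0.01, p_posthoc = 0.05) {
  cond <- samples$condition[match(colnames(mat), samples$sample)]
  tp <- samples$timepoint_h[match(colnames(mat), samples$sample)]
  if (length(unique(cond)) < 2) stop_invalid("need >= 2 conditions")
  purrr::map(seq_len(nrow(mat)), function(gi) {
    y <- mat[gi, ]
    prof <- as_tibble(expand.grid(timepoint_h = sort(unique(tp)),
                                  condition = unique(cond),
                                  stringsAsFactors = FALSE)) |>
      mutate(value = purrr::map2_dbl(.data$timepoint_h, .data$condition,
                                     function(t, cc) {
                                       mean(y[tp == t & cond == cc])
                                     }))
    fit <- aov(value ~ condition, data = prof)
    pa <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$condition
    sig <- !is.na(pa) & pa < p_anova & tk[, "p adj"] < p_posthoc
    tibble(gene = rownames(mat)[gi] %||% as.character(gi),
           p_anova = pa,
           contrast = rownames(tk),
           p_tukey = tk[, "p adj"],
           significant = unname(sig))
  }) |> list_rbind()
}
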