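test_that("cpm filter keeps exactly the genes passing the rule", {
  m <- rbind(
    boundary = c(1, 1, 1, rep(0.5, 21)),   # >= 1 cpm in exactly 3 samples
    allzero  = rep(0, 24),
    high     = rep(50, 24)
  )
  colnames(m) <- sprintf("s%02d", 1:24)
  out <- cpm_filter(m)
  expect_setequal(rownames(out), c("boundary", "high"))
  expect_equal(attr(out, "n_dropped"), 1)
  # oracle equality on a random matrix
  withr::local_seed(2)
  mm <- matrix(rexp(200 * 24, rate = 0.5), 200,
               dimnames = list(sprintf("g%03d", 1:200), colnames(m)))
  kept <- rownames(cpm_filter(mm, min_cpm = 1, min_samples = 3))
  oracle <- rownames(mm)[vapply(seq_len(nrow(mm)), function(i) {
    sum(mm[i, ] >= 1) >= 3
  }, logical(1))]
  expect_identical(kept, oracle)
})

test_that("cosine reference ranks have the expected shape and lag grid", {
  tp <- rep(seq(0, 20, by = 4), each = 4)
  refs <- jtk_references(tp, period_h = 24)
  # default lag resolution is half the 4-h sampling: 12 lags over 24 h
  expect_length(refs$lags_h, 12)
  expect_equal(refs$lags_h, seq(0, 22, by = 2))
  # lag 0: t = 0 ranks highest, t = 12 lowest
  r0 <- refs$ranks[1, ]
  expect_true(all(r0[tp == 0] == max(r0)))
  expect_true(all(r0[tp == 12] == min(r0)))
  # shifting the lag by one sampling interval cyclically shifts the pattern:
  # ref_4(t) = ref_0(t - 4), so r4 at time t equals r0 at (t - 4) mod 24
  r4 <- refs$ranks[refs$lags_h == 4, ]
  expect_equal(unname(r4[order(tp)]), unname(r0[order((tp + 4) %% 24)]))
  expect_error(jtk_references(tp, period_h = 24, lag_resolution_h = 100),
               class = "circaflux_invalid_input")
})

test_that("concordance statistic matches its brute-force double loop", {
  ref <- rank(cos(2 * pi * seq(0, 20, 4) / 24))
  expect_equal(jt_statistic(ref, ref)$tau, 1)
  expect_equal(jt_statistic(-ref, ref)$tau, -1)  # reversed ordering
  withr::local_seed(6)
  for (i in 1:10) {
    v <- rnorm(8)
    r <- rank(sample(1:5, 8, replace = TRUE))
    got <- jt_statistic(v, r)
    expect_equal(got$S, brute_S(v, r))
  }
  deg <- jt_statistic(rep(1, length(ref)), ref)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$tau))
})

test_that("exact null equals full permutation enumeration (n = 6 distinct)", {
  null <- jtk_null(1:6)
  oracle <- enum_null(1:6)
  keep <- null$prob > 0
  expect_equal(null$S[keep], oracle$S)
  expect_equal(null$prob[keep], oracle$prob, tolerance = 1e-12)
  expect_equal(sum(null$prob), 1, tolerance = 1e-12)
  # symmetric about zero
  expect_equal(null$prob, rev(null$prob), tolerance = 1e-12)
})

test_that("exact null matches enumeration for random tie structures, n <= 8", {
  withr::local_seed(13)
  for (i in 1:4) {
    n <- sample(5:8, 1)
    r <- rank(sample(1:4, n, replace = TRUE), ties.method = "average")
    null <- jtk_null(r)
    oracle <- enum_null(r)
    got <- setNames(null$prob, null$S)[as.character(oracle$S)]
    expect_equal(unname(got), oracle$prob, tolerance = 1e-12)
    expect_equal(sum(null$prob), 1, tolerance = 1e-12)
  }
})

test_that("JTK scan nails a noiseless cosine at the 6x4 design", {
  samples <- design_6x4()
  tp <- samples$timepoint_h
  jitter <- rep(c(0, 0.01, 0.02, 0.03), times = 6)
  mat <- rbind(
    cos6  = 100 * (1 + 0.5 * cos(2 * pi * (tp - 6) / 24)) + jitter,
    flat  = rep(100, 24)
  )
  colnames(mat) <- samples$sample
  res <- jtk_scan(mat, samples)
  cos6 <- res[res$gene == "cos6", ]
  expect_lt(cos6$adj_p, 0.01)
  expect_equal(cos6$lag_h, 6)
  expect_equal(cos6$tau, 1)
  flat <- res[res$gene == "flat", ]
  expect_equal(flat$p, 1)
  expect_equal(flat$amplitude, 0)
})

test_that("lag recovery is exact over the whole lag grid for noiseless
           cosines", {
  samples <- design_6x4()
  tp <- samples$timepoint_h
  jitter <- rep(c(0, 0.001, 0.002, 0.003), times = 6)
  for (lag in seq(0, 22, by = 2)) {
    y <- 100 * (1 + 0.4 * cos(2 * pi * (tp - lag) / 24)) + jitter
    m <- matrix(y, nrow = 1, dimnames = list("g", samples$sample))
    res <- jtk_scan(m, samples)
    expect_equal(res$lag_h, lag)
  }
})

test_that("p-values on flat negative-binomial genes are conservative", {
  truth <- expr_truth(n_genes = 500, frac_rhythmic = 0, baseline_cpm = 100,
                      dispersion = 0.05, seed = 31)
  sim <- sim_expr_counts(truth)
  mat <- cpm(sim$counts, lib_sizes = rep(5e6, ncol(sim$counts)))
  res <- jtk_scan(mat, sim$samples)
  # raw best-hypothesis p stochastically dominates uniform after the
  # Bonferroni correction; the adjusted rejection rate at 0.01 stays tiny
  expect_lte(mean(res$adj_p < 0.01), 0.015)
  # and raw p is not anticonservative at conventional levels once adjusted
  for (q in c(0.05, 0.25)) {
    expect_lte(mean(res$adj_p < q), q + 2.58 * sqrt(q * (1 - q) / 500))
  }
})

test_that("rhythmic-gene selection is correct, monotone and sensitive", {
  res <- tibble::tibble(gene = c("a", "b", "c"),
                        adj_p = c(0.005, 0.005, 0.5),
                        amplitude = c(12, 5, 50))
  expect_identical(select_rhythmic(res), "a")
  # monotone: relaxing either threshold never removes genes
  s1 <- select_rhythmic(res, p_max = 0.01, amp_min = 10)
  s2 <- select_rhythmic(res, p_max = 0.05, amp_min = 10)
  s3 <- select_rhythmic(res, p_max = 0.01, amp_min = 1)
  expect_true(all(s1 %in% s2) && all(s1 %in% s3))
  # truth-based sensitivity at strong amplitude / low dispersion
  truth <- expr_truth(n_genes = 300, frac_rhythmic = 0.5,
                      rel_amplitude = 0.5, baseline_cpm = 100,
                      dispersion = 0.02, seed = 17)
  sim <- sim_expr_counts(truth)
  mat <- cpm(sim$counts, lib_sizes = rep(5e6, ncol(sim$counts)))
  sel <- select_rhythmic(jtk_scan(mat, sim$samples))
  sens <- mean(truth$gene[truth$rhythmic] %in% sel)
  expect_gte(sens, 0.9)
})

test_that("day/night phase binning splits the 24-h clock at noon", {
  d1 <- phase_day_night(c(4, 6, 8))
  expect_equal(d1$day_fraction, 1)
  d2 <- phase_day_night(c(4, 18))
  expect_equal(d2$day_fraction, 0.5)
  expect_equal(d2$night_fraction, 0.5)
  # boundary: lag 12 counts as night
  expect_equal(phase_day_night(c(12))$night_fraction, 1)
  expect_true(phase_day_night(numeric(0))$empty)
  # uniform lags -> day fraction near 1/2 within binomial error
  withr::local_seed(9)
  u <- runif(2000, 0, 24)
  du <- phase_day_night(u)
  expect_lt(abs(du$day_fraction - 0.5), 3 * sqrt(0.25 / 2000))
  expect_equal(sum(du$bins[[1]]$count), 2000)
})

test_that("Venn region counts equal brute-force enumeration", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = c("c", "e"))
  ov <- set_overlaps(sets)
  expect_equal(ov$count[ov$region == "A&B&C"], 1)
  expect_equal(ov$count[ov$region == "A&B"], 1)   # exclusive: just "b"
  disj <- set_overlaps(list(X = "a", Y = "b"))
  expect_equal(disj$count[disj$region == "X&Y"], 0)
  # random sets vs region enumeration oracle
  withr::local_seed(14)
  rs <- lapply(1:3, function(i) sample(letters, sample(5:15, 1)))
  names(rs) <- c("P", "Q", "R")
  ov2 <- set_overlaps(rs)
  for (i in seq_len(nrow(ov2))) {
    patt <- unlist(ov2[i, c("P", "Q", "R")])
    oracle <- sum(vapply(letters, function(el) {
      all(vapply(rs, function(s) el %in% s, logical(1)) == patt)
    }, logical(1)))
    expect_equal(ov2$count[i], oracle)
  }
})

test_that("heatmap scaling is [-1,1] per gene, phase-ordered, monotone", {
  samples <- design_6x4()
  tp <- samples$timepoint_h
  mat <- rbind(
    late  = 100 * (1 + 0.5 * cos(2 * pi * (tp - 16) / 24)),
    early = 100 * (1 + 0.5 * cos(2 * pi * (tp - 4) / 24)),
    const = rep(7, 24)
  )
  colnames(mat) <- samples$sample
  res <- jtk_scan(mat, samples)
  hm <- heatmap_matrix(mat, samples, res, rownames(mat))
  expect_equal(range(hm$scaled[hm$gene == "early"]), c(-1, 1))
  expect_true(all(hm$scaled[hm$gene == "const"] == 0))
  # rows ordered by lag ascending
  expect_equal(levels(hm$gene)[1:2], c("early", "late"))
  # scaling preserves each gene's argmax position
  for (g in c("early", "late")) {
    sub <- hm[hm$gene == g, ]
    prof <- tapply(mat[g, ], tp, mean)
    expect_equal(sub$timepoint_h[which.max(sub$scaled)],
                 as.numeric(names(which.max(prof))))
  }
  expect_error(heatmap_matrix(mat, samples, res, character(0)),
               class = "circaflux_invalid_input")
})

test_that("ANOVA DEG rule matches the textbook F and detects shifts", {
  # 3-group toy, n = 3 each: hand-computed one-way ANOVA
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  vals <- unlist(g)
  grand <- mean(vals)
  ss_between <- sum(vapply(g, function(x) 3 * (mean(x) - grand)^2, numeric(1)))
  ss_within <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  F_hand <- (ss_between / 2) / (ss_within / 6)
  p_hand <- stats::pf(F_hand, 2, 6, lower.tail = FALSE)
  fit <- stats::aov(v ~ cond, data = data.frame(
    v = vals, cond = rep(names(g), each = 3)))
  expect_equal(summary(fit)[[1]][["Pr(>F)"]][1], p_hand, tolerance = 1e-12)

  # through deg_anova: identical conditions never selected, a strong shift is
  tp <- rep(seq(0, 20, 4), each = 2)
  samples <- tibble::tibble(
    sample = sprintf("s%02d", seq_len(3 * length(tp))),
    timepoint_h = rep(tp, 3),
    replicate = rep(rep(1:2, 6), 3),
    condition = rep(c("HL", "LH", "HH"), each = length(tp)))
  withr::local_seed(12)
  base <- 100 + rnorm(length(tp), 0, 1)
  mat <- rbind(
    same = rep(base, 3),
    shifted = c(base, base, base + 50)
  )
  colnames(mat) <- samples$sample
  deg <- deg_anova(mat, samples)
  expect_false(any(deg$significant[deg$gene == "same"]))
  sig <- deg[deg$gene == "shifted" & deg$significant, ]
  expect_true(all(grepl("HH", sig$contrast)))
  expect_gte(nrow(sig), 2)
  expect_error(deg_anova(mat, dplyr::mutate(samples, condition = "HL")),
               class = "circaflux_invalid_input")
})
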