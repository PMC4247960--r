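test_that("rank-sum exact branch matches hand and enumeration values", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 6)
  expect_equal(r$p_value, 0.1)
  expect_match(r$method, "exact")
  # identical multisets are exchangeable: p = 1
  expect_equal(rank_sum_test(c(1, 2, 5), c(1, 2, 5))$p_value, 1)
  # label swap leaves the p-value unchanged
  set.seed(14)
  a <- rnorm(6); b <- rnorm(5)
  expect_equal(rank_sum_test(a, b)$p_value, rank_sum_test(b, a)$p_value)
  # fully degenerate samples
  expect_equal(rank_sum_test(rep(2, 4), rep(2, 3))$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("exact branch equals the enumeration oracle for all small splits", {
  set.seed(21)
  pooled_sets <- list(
    rnorm(8),                       # tie-free
    rnorm(10),                      # tie-free, larger
    c(1, 1, 2, 3, 3, 4, 5, 5),     # heavy ties
    sample(1:4, 9, replace = TRUE)  # ties, unbalanced sizes
  )
  for (pooled in pooled_sets) {
    n <- length(pooled)
    for (na in 1:(n - 1)) {
      a <- pooled[seq_len(na)]
      b <- pooled[-seq_len(na)]
      got <- rank_sum_test(a, b)
      if (stats::sd(pooled) == 0) next
      expect_equal(got$p_value, enumerate_ranksum_p(a, b), tolerance = 1e-12,
                   info = sprintf("n=%d na=%d", n, na))
    }
  }
})

test_that("large-sample branch approximates the exact tail", {
  set.seed(3)
  a <- rnorm(15); b <- rnorm(12) + 0.5
  r <- rank_sum_test(a, b)
  expect_match(r$method, "normal")
  ref <- stats::wilcox.test(a, b, exact = FALSE)$p.value
  expect_equal(r$p_value, ref, tolerance = 0.02)
})

simulate_long <- function(n_per_group, k = 3, group_shift = 0,
                          stim_shift = rep(0, k), sd = 1) {
  subj <- sprintf("S%02d", seq_len(2 * n_per_group))
  g <- rep(c("control", "PD"), each = n_per_group)
  do.call(rbind, lapply(seq_along(subj), function(i) {
    data.frame(
      subject = subj[i], group = g[i], stimulus = paste0("stim", seq_len(k)),
      value = rnorm(k, mean = (g[i] == "PD") * group_shift + stim_shift,
                    sd = sd)
    )
  }))
}

test_that("mixed ANOVA recovers its sums-of-squares partition", {
  set.seed(8)
  d <- simulate_long(8, stim_shift = c(0, 0.5, 1), group_shift = 0.4)
  res <- mixed_anova(d)
  td <- tidy(res)
  expect_identical(td$term, c("group", "stimulus", "group:stimulus"))
  k <- 3
  grand <- mean(d$value)
  ss_total <- sum((d$value - grand)^2)
  subj_means <- tapply(d$value, d$subject, mean)
  ss_bs <- k * sum((subj_means - grand)^2)
  # brute-force partition: between-subject stratum and within-subject stratum
  expect_equal(td$sumsq[1] + res$residuals$sumsq[1], ss_bs,
               tolerance = 1e-8)
  expect_equal(sum(td$sumsq[2:3]) + res$residuals$sumsq[2],
               ss_total - ss_bs, tolerance = 1e-8)
  # GG epsilon present for three within levels and bounded by 1/(k-1), 1
  expect_true(res$gg_epsilon >= 1 / (k - 1) - 1e-9 && res$gg_epsilon <= 1)
  expect_true(all(is.finite(td$p_gg[2:3]) & td$p_gg[2:3] > 0 &
                    td$p_gg[2:3] <= 1))
  gl <- glance(res)
  expect_equal(gl$n_subjects, 16)
})

test_that("identical values across balanced groups give a zero group F", {
  d <- simulate_long(5)
  d$value <- rep(c(1, 2, 3), times = 10)  # same per-stimulus values everywhere
  res <- mixed_anova(d)
  td <- tidy(res)
  # the group sum of squares vanishes (up to floating residue)
  expect_lt(td$sumsq[td$term == "group"], 1e-12)
  expect_gt(td$sumsq[td$term == "stimulus"], 1)
})

test_that("incomplete subjects are dropped with a warning; tiny designs error", {
  set.seed(4)
  d <- simulate_long(4)
  d <- d[!(d$subject == "S01" & d$stimulus == "stim3"), ]
  expect_warning(res <- mixed_anova(d), "S01")
  expect_equal(res$n_dropped, 1)
  expect_equal(res$n_subjects, 7)
  d2 <- simulate_long(1)
  expect_error(mixed_anova(d2), "two groups")
})

test_that("mixed ANOVA holds its nominal size under the null", {
  set.seed(515)
  n_sim <- 400
  rej <- matrix(FALSE, n_sim, 3)
  for (s in seq_len(n_sim)) {
    d <- simulate_long(10)
    td <- tidy(mixed_anova(d))
    rej[s, ] <- td$p_value < 0.05
  }
  rates <- colMeans(rej)
  for (r in rates) {
    expect_gt(r, 0.02)
    expect_lt(r, 0.08)
  }
})

test_that("a pure stimulus effect drives the stimulus F, not the interaction", {
  set.seed(99)
  p_inter <- replicate(40, {
    d <- simulate_long(8, stim_shift = c(0, 1.5, 3))
    td <- tidy(mixed_anova(d))
    c(stim = td$p_value[2], inter = td$p_value[3])
  })
  expect_true(all(p_inter["stim", ] < 0.01))
  # interaction p-values stay roughly uniform: around 5 percent rejections
  expect_lt(mean(p_inter["inter", ] < 0.05), 0.2)
})

test_that("post-hoc pairwise tests behave on degenerate and shifted designs", {
  # three identical stimulus columns: all adjusted p-values are one
  d <- simulate_long(6)
  d$value <- ave(d$value, d$subject, FUN = function(v) rep(v[1], length(v)))
  ph <- posthoc_pairwise(d)
  expect_true(all(ph$p_adj == 1))
  # adjusted p is never below unadjusted
  set.seed(10)
  d2 <- simulate_long(8, stim_shift = c(0, 0.3, 2))
  ph2 <- posthoc_pairwise(d2)
  expect_true(all(ph2$p_adj >= ph2$p_value - 1e-12))
  expect_equal(nrow(ph2), 3)
  # a strongly shifted stimulus is flagged in nearly every simulation
  hits <- replicate(40, {
    d3 <- simulate_long(8, stim_shift = c(0, 0, 2.5))
    ph3 <- posthoc_pairwise(d3)
    any(ph3$p_adj[ph3$stimulus_1 == "stim1" & ph3$stimulus_2 == "stim3" |
                    ph3$stimulus_1 == "stim3" & ph3$stimulus_2 == "stim1"]
        < 0.05)
  })
  expect_gte(mean(hits), 0.95)
})
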