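# Group-level statistics: two-sample Wilcoxon rank-sum with an exact branch,
# two-way mixed-design ANOVA (group between, stimulus within) and Bonferroni
# post-hoc paired comparisons.

#' Two-sided Wilcoxon rank-sum test
#'
#' The statistic is the rank sum of the first sample in the pooled midranks.
#' For combined sample sizes up to 20 the p-value is exact: from the
#' closed-form null distribution when there are no ties, and by complete
#' enumeration of all group assignments (tail mass of `|W - E[W]|`) when
#' ties are present. Larger samples use the normal approximation with the
#' tie-corrected variance and continuity correction. Two samples with no
#' variation at all are degenerate and return p = 1.
#'
#' @param a,b Numeric samples (both non-empty).
#' @return One-row tibble: `statistic` (rank sum of `a`), `p_value`,
#'   `method`, `n_a`, `n_b`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
rank_sum_test <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    abort("Both samples must be non-empty.")
  }
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) {
    abort("Both samples must contain finite values.")
  }
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  w <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  ties <- any(duplicated(pooled))

  if (sd(pooled) == 0) {
    p <- 1
    method <- "degenerate"
  } else if (n <= 20L && !ties) {
    u <- w - na * (na + 1) / 2
    p_lo <- pwilcox(u, na, nb)
    p_hi <- pwilcox(u - 1, na, nb, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else if (n <= 20L) {
    sums <- colSums(matrix(r[combn(n, na)], nrow = na))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    method <- "exact (enumeration, ties)"
  } else {
    tie_tab <- table(pooled)
    correction <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    v <- na * nb / 12 * ((n + 1) - correction)
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(v)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  tibble(statistic = w, p_value = p, method = method, n_a = na, n_b = nb)
}

#' Two-way mixed-design ANOVA (group x stimulus)
#'
#' Classical repeated-measures ANOVA with one between-subjects factor
#' (group) and one within-subject factor (stimulus), fitted by the standard
#' error-strata decomposition: the group effect is tested against the
#' between-subjects residual, stimulus and the interaction against the
#' within-subject residual. Subjects missing any stimulus level are dropped
#' with a warning (mirroring discarded-sensor bookkeeping). When the within
#' factor has more than two levels a Greenhouse-Geisser sphericity
#' correction is also reported for the within-subject terms.
#'
#' @param data Long data frame, one value per subject-by-stimulus.
#' @param variable Optional name of a `variable` column value to filter on
#'   (for stacked long tables holding several measures).
#' @param value,subject,group,stimulus Column names (tidy-eval; defaults
#'   `value`, `subject`, `group`, `stimulus`).
#' @return A `facexpr_anova` object; `tidy()` gives the term table (`term`,
#'   `df1`, `df2`, `sumsq`, `statistic` = F, `p_value`, and for
#'   within-subject terms `gg_epsilon`, `p_gg`), `glance()` the bookkeeping.
#' @export
mixed_anova <- function(data, variable = NULL, value = value,
                        subject = subject, group = group,
                        stimulus = stimulus) {
  stopifnot(is.data.frame(data))
  d <- tibble(
    subject = as.character(dplyr::pull(data, {{ subject }})),
    group = as.character(dplyr::pull(data, {{ group }})),
    stimulus = as.character(dplyr::pull(data, {{ stimulus }})),
    value = as.numeric(dplyr::pull(data, {{ value }}))
  )
  if (!is.null(variable)) {
    if (!"variable" %in% names(data)) {
      abort("`variable` filtering requires a `variable` column.")
    }
    d <- d[as.character(data$variable) == variable, ]
  }
  d <- d[is.finite(d$value), ]
  levels_w <- sort(unique(d$stimulus))
  k <- length(levels_w)
  if (k < 2L) abort("Need at least two stimulus levels.")

  counts <- d |>
    dplyr::distinct(.data$subject, .data$stimulus) |>
    dplyr::count(.data$subject)
  complete <- counts$subject[counts$n == k]
  dropped <- setdiff(unique(d$subject), complete)
  if (length(dropped) > 0L) {
    warn(sprintf("Dropping %d subject(s) with incomplete stimulus coverage: %s",
                 length(dropped), paste(dropped, collapse = ", ")))
    d <- d[d$subject %in% complete, ]
  }
  per_group <- d |>
    dplyr::distinct(.data$subject, .data$group) |>
    dplyr::count(.data$group)
  if (nrow(per_group) < 2L || any(per_group$n < 2L)) {
    abort("Need at least two groups with at least two complete subjects each.")
  }

  d$subject <- factor(d$subject)
  d$group <- factor(d$group)
  d$stimulus <- factor(d$stimulus)
  fit <- aov(value ~ group * stimulus + Error(subject), data = d)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: subject"]][[1L]])
  within <- as.data.frame(s[["Error: Within"]][[1L]])
  rn <- function(x) trimws(rownames(x))

  pick <- function(tab, term) {
    i <- match(term, rn(tab))
    res <- match("Residuals", rn(tab))
    tibble(
      term = term,
      df1 = tab$Df[i], df2 = tab$Df[res],
      sumsq = tab$`Sum Sq`[i],
      statistic = tab$`F value`[i],
      p_value = tab$`Pr(>F)`[i]
    )
  }
  terms <- dplyr::bind_rows(
    pick(between, "group"),
    pick(within, "stimulus"),
    pick(within, "group:stimulus")
  )
  res_b <- match("Residuals", rn(between))
  res_w <- match("Residuals", rn(within))
  residuals <- tibble(
    stratum = c("between_subjects", "within_subjects"),
    df = c(between$Df[res_b], within$Df[res_w]),
    sumsq = c(between$`Sum Sq`[res_b], within$`Sum Sq`[res_w])
  )

  eps <- NA_real_
  if (k > 2L) {
    wide <- d |>
      dplyr::select("subject", "group", "stimulus", "value") |>
      tidyr::pivot_wider(names_from = "stimulus", values_from = "value")
    y <- as.matrix(wide[, levels_w])
    g <- wide$group
    centered <- y
    for (gl in unique(g)) {
      idx <- g == gl
      centered[idx, ] <- sweep(y[idx, , drop = FALSE], 2,
                               colMeans(y[idx, , drop = FALSE]))
    }
    S <- crossprod(centered) / (nrow(y) - length(unique(g)))
    C <- qr.Q(qr(stats::contr.helmert(k)))
    M <- t(C) %*% S %*% C
    eps <- min(1, sum(diag(M))^2 / ((k - 1) * sum(M^2)))
    terms$gg_epsilon <- c(NA_real_, eps, eps)
    terms$p_gg <- c(
      NA_real_,
      pf(terms$statistic[2L], terms$df1[2L] * eps, terms$df2[2L] * eps,
         lower.tail = FALSE),
      pf(terms$statistic[3L], terms$df1[3L] * eps, terms$df2[3L] * eps,
         lower.tail = FALSE)
    )
  }

  structure(
    list(terms = terms, residuals = residuals,
         n_subjects = length(unique(d$subject)),
         n_dropped = length(dropped), dropped = dropped,
         stimulus_levels = levels_w, gg_epsilon = eps, data = d),
    class = "facexpr_anova"
  )
}

#' @export
print.facexpr_anova <- function(x, ...) {
  cat(sprintf("Mixed-design ANOVA: %d complete subjects (%d dropped), %d stimulus levels\n",
              x$n_subjects, x$n_dropped, length(x$stimulus_levels)))
  print(x$terms)
  invisible(x)
}

#' Post-hoc pairwise stimulus comparisons
#'
#' Paired t tests between every pair of stimulus levels (within subjects,
#' pooled across groups), with Bonferroni adjustment by default.
#'
#' @inheritParams mixed_anova
#' @param adjust P-value adjustment method (see [stats::p.adjust()]);
#'   `"bonferroni"` by default, `"none"` for unadjusted values.
#' @return Tibble with one row per stimulus pair: `stimulus_1`, `stimulus_2`,
#'   `estimate` (mean paired difference), `statistic`, `df`, `p_value`,
#'   `p_adj`.
#' @export
posthoc_pairwise <- function(data, variable = NULL, value = value,
                             subject = subject, stimulus = stimulus,
                             adjust = "bonferroni") {
  d <- tibble(
    subject = as.character(dplyr::pull(data, {{ subject }})),
    stimulus = as.character(dplyr::pull(data, {{ stimulus }})),
    value = as.numeric(dplyr::pull(data, {{ value }}))
  )
  if (!is.null(variable)) {
    if (!"variable" %in% names(data)) {
      abort("`variable` filtering requires a `variable` column.")
    }
    d <- d[as.character(data$variable) == variable, ]
  }
  wide <- d |>
    tidyr::pivot_wider(names_from = "stimulus", values_from = "value")
  levels_w <- sort(setdiff(names(wide), "subject"))
  pairs <- combn(levels_w, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    s1 <- pairs[1L, j]; s2 <- pairs[2L, j]
    diffs <- wide[[s1]] - wide[[s2]]
    diffs <- diffs[is.finite(diffs)]
    m <- length(diffs)
    if (m < 2L) abort("Need at least two paired observations per comparison.")
    est <- mean(diffs)
    se <- sd(diffs) / sqrt(m)
    stat <- if (se == 0) 0 else est / se
    p <- if (se == 0 && est == 0) 1 else 2 * pt(-abs(stat), df = m - 1L)
    tibble(stimulus_1 = s1, stimulus_2 = s2, estimate = est,
           statistic = stat, df = m - 1L, p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- pmin(1, stats::p.adjust(out$p_value, method = adjust))
  out
}
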