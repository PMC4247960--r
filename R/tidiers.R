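# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Platt calibration fit
#'
#' @param x A `facexpr_platt` object.
#' @param ... Unused.
#' @return Tibble with one row per coefficient (`A`, `B`).
#' @method tidy facexpr_platt
#' @export
tidy.facexpr_platt <- function(x, ...) {
  tibble(term = c("A", "B"), estimate = c(x$A, x$B))
}

#' @rdname tidy.facexpr_platt
#' @return For `glance()`: one-row tibble with the achieved objective
#'   (regularized negative log-likelihood), class counts, iteration count and
#'   convergence flag.
#' @method glance facexpr_platt
#' @export
glance.facexpr_platt <- function(x, ...) {
  tibble(objective = x$objective, n_pos = x$n_pos, n_neg = x$n_neg,
         iterations = x$iterations, converged = x$converged)
}

#' Tidy a mixed-design ANOVA
#'
#' @param x A `facexpr_anova` object.
#' @param ... Unused.
#' @return The term table: `term`, `df1`, `df2`, `sumsq`, `statistic`,
#'   `p_value` and (within-subject terms, three or more levels)
#'   `gg_epsilon`, `p_gg`.
#' @method tidy facexpr_anova
#' @export
tidy.facexpr_anova <- function(x, ...) {
  x$terms
}

#' @rdname tidy.facexpr_anova
#' @method glance facexpr_anova
#' @export
glance.facexpr_anova <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_dropped = x$n_dropped,
         n_stimuli = length(x$stimulus_levels), gg_epsilon = x$gg_epsilon)
}

#' Tidy detected R peaks
#'
#' @param x A `facexpr_rpeaks` tibble.
#' @param ... Unused.
#' @return Tibble of `time`, `prominence` and the trailing RR interval `rr`
#'   (`NA` for the first peak).
#' @method tidy facexpr_rpeaks
#' @export
tidy.facexpr_rpeaks <- function(x, ...) {
  tibble(time = x$time, prominence = x$prominence,
         rr = c(NA_real_, diff(x$time)))
}
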