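#' Binary decision from a classifier score
#'
#' The upstream per-AU support vector machines emit a signed distance `h` to
#' the separating hyperplane; the hard classification is its sign. A score of
#' exactly zero is a measure-zero tie and is assigned to the positive class.
#'
#' @param h Numeric vector of decision values (finite).
#' @return Integer vector of `+1` / `-1`.
#' @export
#' @examples
#' hard_decision(c(2.3, -0.1, 0))
hard_decision <- function(h) {
  if (!is.numeric(h) || any(!is.finite(h))) {
    abort("`h` must be a finite numeric vector.")
  }
  ifelse(h >= 0, 1L, -1L)
}

#' Sigmoid probability for a calibrated decision value
#'
#' Maps decision values to posterior probabilities of the positive class with
#' the sigmoid `P(y = +1 | h) = 1 / (1 + exp(A * h + B))`. Note the sign
#' convention: with slope `A < 0` (the fitted direction whenever larger scores
#' mean stronger evidence for the AU) the probability increases with `h`.
#' Evaluation is overflow-safe for arbitrarily large `|A * h + B|`.
#'
#' @param model A `facexpr_platt` object (from [fit_platt()]), or a numeric
#'   vector/list with named elements `A` and `B`.
#' @param h Numeric vector of decision values.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
#' @examples
#' platt_probability(c(A = -1, B = 0), h = log(3))  # 0.75
platt_probability <- function(model, h) {
  ab <- platt_coefs(model)
  if (!is.numeric(h) || any(!is.finite(h))) {
    abort("`h` must be a finite numeric vector.")
  }
  sigmoid_stable(-(ab[["A"]] * h + ab[["B"]]))
}

platt_coefs <- function(model) {
  if (inherits(model, "facexpr_platt")) {
    c(A = model$A, B = model$B)
  } else if ((is.numeric(model) || is.list(model)) &&
             all(c("A", "B") %in% names(model))) {
    a <- as.numeric(model[["A"]]); b <- as.numeric(model[["B"]])
    if (!is.finite(a) || !is.finite(b)) abort("Platt coefficients must be finite.")
    c(A = a, B = b)
  } else {
    abort("`model` must be a facexpr_platt fit or have named elements A and B.")
  }
}

#' Fit a Platt calibration sigmoid by maximum likelihood
#'
#' Estimates `(A, B)` of `P(y = +1 | h) = 1 / (1 + exp(A * h + B))` from
#' labelled decision values by minimizing the cross-entropy against the
#' regularized targets `t+ = (N+ + 1) / (N+ + 2)` and `t- = 1 / (N- + 2)`
#' (the standard smoothing that keeps the likelihood bounded), using Newton
#' iterations with backtracking line search. The fit is deterministic given
#' the data. When both classes are present and scores separate in the usual
#' direction (larger `h`, likelier positive), the fitted slope is negative.
#'
#' @param data Data frame of calibration samples, one row per scored frame.
#' @param score,label Columns of `data` holding the decision value and the
#'   class label (tidy-eval; defaults `score` and `label`). Labels may be
#'   `+1`/`-1`, `0`/`1`, or logical.
#' @param max_iter Maximum Newton iterations.
#' @param grad_tol Gradient infinity-norm at which to declare convergence.
#' @return A `facexpr_platt` object: coefficients `A`, `B`, the achieved
#'   negative log-likelihood (`objective`), class counts, iteration count and
#'   a convergence flag. Supports [generics::tidy()], [generics::glance()],
#'   `predict()` and `autoplot()`.
#' @export
#' @examples
#' set.seed(1)
#' h <- rnorm(500)
#' y <- ifelse(runif(500) < platt_probability(c(A = -2, B = 0.5), h), 1, -1)
#' fit <- fit_platt(data.frame(score = h, label = y))
#' tidy(fit)
fit_platt <- function(data, score = score, label = label,
                      max_iter = 200L, grad_tol = 1e-8) {
  stopifnot(is.data.frame(data))
  h <- dplyr::pull(data, {{ score }})
  y <- dplyr::pull(data, {{ label }})
  if (!is.numeric(h) || any(!is.finite(h))) {
    abort("Calibration scores must be finite numbers.")
  }
  y <- normalize_labels(y)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == -1L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("fit_platt() needs at least one sample of each class; the likelihood is unbounded otherwise.")
  }

  hi <- (n_pos + 1) / (n_pos + 2)
  lo <- 1 / (n_neg + 2)
  t <- ifelse(y == 1L, hi, lo)

  obj <- function(A, B) {
    f <- A * h + B
    # t*f + log(1 + exp(-f)), stable in both tails
    sum(t * f + log1pexp(-f))
  }

  A <- 0
  B <- log((n_neg + 1) / (n_pos + 1))
  fval <- obj(A, B)
  ridge <- 1e-12
  min_step <- 1e-10
  converged <- FALSE
  it <- 0L

  while (it < max_iter) {
    it <- it + 1L
    f <- A * h + B
    p <- sigmoid_stable(-f)          # P(y = +1)
    d1 <- t - p
    g1 <- sum(h * d1)
    g2 <- sum(d1)
    if (max(abs(g1), abs(g2)) < grad_tol) {
      converged <- TRUE
      break
    }
    d2 <- p * (1 - p)
    h11 <- sum(h * h * d2) + ridge
    h22 <- sum(d2) + ridge
    h21 <- sum(h * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB

    step <- 1
    accepted <- FALSE
    while (step >= min_step) {
      newA <- A + step * dA
      newB <- B + step * dB
      newf <- obj(newA, newB)
      if (newf < fval + 1e-4 * step * gd) {
        A <- newA; B <- newB; fval <- newf
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break  # line search stalled at numerical precision
  }

  structure(
    list(A = A, B = B, objective = fval,
         n_pos = n_pos, n_neg = n_neg,
         iterations = it, converged = converged || it < max_iter),
    class = "facexpr_platt"
  )
}

normalize_labels <- function(y) {
  if (is.logical(y)) return(ifelse(y, 1L, -1L))
  if (is.numeric(y)) {
    u <- sort(unique(y))
    if (all(u %in% c(-1, 1))) return(as.integer(y))
    if (all(u %in% c(0, 1))) return(ifelse(y == 1, 1L, -1L))
  }
  abort("Labels must be +1/-1, 0/1, or logical.")
}

#' Negative log-likelihood of a Platt model on calibration data
#'
#' Evaluates the same regularized cross-entropy objective that [fit_platt()]
#' minimizes, for arbitrary `(A, B)`. Useful for verifying that a fit attains
#' at least the likelihood of any reference parameter pair.
#'
#' @inheritParams fit_platt
#' @param A,B Sigmoid coefficients.
#' @return The objective value (lower is better).
#' @export
platt_objective <- function(data, A, B, score = score, label = label) {
  h <- dplyr::pull(data, {{ score }})
  y <- normalize_labels(dplyr::pull(data, {{ label }}))
  n_pos <- sum(y == 1L); n_neg <- sum(y == -1L)
  t <- ifelse(y == 1L, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  f <- A * h + B
  sum(t * f + log1pexp(-f))
}

#' @export
print.facexpr_platt <- function(x, ...) {
  cat("Platt calibration sigmoid  P(y=+1|h) = 1 / (1 + exp(A*h + B))\n")
  cat(sprintf("  A = %.6g, B = %.6g\n", x$A, x$B))
  cat(sprintf("  fitted on %d positive / %d negative samples; objective %.6g (%s, %d iterations)\n",
              x$n_pos, x$n_neg, x$objective,
              if (isTRUE(x$converged)) "converged" else "not converged",
              x$iterations))
  invisible(x)
}

#' @export
predict.facexpr_platt <- function(object, h, ...) {
  platt_probability(object, h)
}
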