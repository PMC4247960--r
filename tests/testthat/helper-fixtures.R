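# Shared fixtures, built in code at test time.

# Intensity tibble for one or more AUs from named lists of smoothed values
# and active masks.
make_intensity <- function(smoothed, active = NULL) {
  aus <- names(smoothed)
  dplyr::bind_rows(lapply(aus, function(a) {
    s <- smoothed[[a]]
    act <- if (is.null(active)) rep(TRUE, length(s)) else active[[a]]
    tibble::tibble(au = a, frame = seq_along(s) - 1L, smoothed = s,
                   active = act)
  }))
}

# Decision-value sample calibrated to a known sigmoid.
calibrated_sample <- function(n, A, B, seed, score_sd = 2) {
  set.seed(seed)
  h <- stats::rnorm(n, 0, score_sd)
  p <- facexpr::platt_probability(c(A = A, B = B), h)
  y <- ifelse(stats::runif(n) < p, 1, -1)
  tibble::tibble(score = h, label = y)
}

# SNR of an error signal against a known clean component, in dB.
snr_db <- function(clean, estimate) {
  10 * log10(mean(clean^2) / mean((estimate - clean)^2))
}

# Sensitivity / positive predictivity of detected peak times against truth
# with a matching tolerance in seconds.
match_peaks <- function(detected, truth, tol = 0.05) {
  sens <- mean(vapply(truth, function(bt) any(abs(detected - bt) <= tol), TRUE))
  ppv <- mean(vapply(detected, function(pt) any(abs(truth - pt) <= tol), TRUE))
  c(sensitivity = sens, ppv = ppv)
}

# Independent enumeration oracle for the two-sided rank-sum p-value
# (tail mass of |W - E W| over all group assignments).
enumerate_ranksum_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  sums <- colSums(matrix(r[utils::combn(n, na)], nrow = na))
  mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
}
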