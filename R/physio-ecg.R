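# R-peak detection by piecewise-linear change-point segmentation, and
# HR / HRV extraction from the detected RR series.

# Sum-of-squares cost of the least-squares degree-1 fit on samples [i, j],
# computed in O(1) from prefix sums.
make_segment_cost <- function(y) {
  n <- length(y)
  t <- as.numeric(seq_len(n))
  cy <- cumsum(y); cyy <- cumsum(y * y)
  ct <- cumsum(t); ctt <- cumsum(t * t); cty <- cumsum(t * y)
  rng <- function(c, i, j) c[j] - if (i > 1L) c[i - 1L] else 0
  function(i, j) {
    m <- j - i + 1L
    if (m < 3L) return(0)
    sy <- rng(cy, i, j); syy <- rng(cyy, i, j)
    st <- rng(ct, i, j); stt <- rng(ctt, i, j); sty <- rng(cty, i, j)
    dt <- stt - st * st / m
    slope <- if (dt > 0) (sty - st * sy / m) / dt else 0
    max(syy - sy * sy / m - slope * slope * dt, 0)
  }
}

# Bottom-up merge of adjacent degree-1 segments: repeatedly merge the pair
# whose merge raises the fit cost least, until that rise exceeds `penalty`.
# Returns the interior breakpoints (sample indices starting each segment).
bottom_up_breakpoints <- function(y, chunk, penalty) {
  n <- length(y)
  starts <- seq.int(1L, n, by = chunk)
  if (length(starts) < 3L) return(integer())
  cost_fn <- make_segment_cost(y)
  ends <- c(starts[-1L] - 1L, n)
  k <- length(starts)
  cost <- vapply(seq_len(k), function(i) cost_fn(starts[i], ends[i]), 0)
  # merge gain for joining segment i with i+1
  gain <- vapply(seq_len(k - 1L), function(i) {
    cost_fn(starts[i], ends[i + 1L]) - cost[i] - cost[i + 1L]
  }, 0)
  while (length(starts) > 2L) {
    i <- which.min(gain)
    if (gain[i] > penalty) break
    merged <- cost_fn(starts[i], ends[i + 1L])
    starts <- starts[-(i + 1L)]
    ends <- ends[-i]
    cost <- cost[-(i + 1L)]
    cost[i] <- merged
    gain <- gain[-i]
    if (i > 1L) {
      gain[i - 1L] <- cost_fn(starts[i - 1L], ends[i]) - cost[i - 1L] - cost[i]
    }
    if (i <= length(gain)) {
      gain[i] <- cost_fn(starts[i], ends[i + 1L]) - cost[i] - cost[i + 1L]
    }
  }
  starts[-1L]
}

#' R-peak detection via piecewise-linear change-point segmentation
#'
#' Candidate change points are found by bottom-up merging of degree-1
#' least-squares segments under a noise-scaled penalty; each candidate is
#' refined to the local signal maximum, scored by its amplitude prominence
#' (peak height above the local median), filtered by `amplitude_threshold`,
#' and deduplicated with a refractory rule that keeps the more prominent of
#' any two peaks closer than `refractory_s`.
#'
#' @param x Numeric ECG series (typically denoised via [emd_denoise()]), or a
#'   data frame with a `value` column as produced by [read_signal()].
#' @param rate Sampling rate in Hz.
#' @param amplitude_threshold Minimum prominence for a retained peak. Default
#'   `NULL` uses 60 percent of the 99th percentile of the candidate prominences.
#' @param chunk_s Initial segment length in seconds for the bottom-up merge.
#' @param refractory_s Minimum separation between retained peaks (seconds).
#' @param search_s Half-width of the local-maximum refinement window.
#' @param baseline_s Half-width of the local-median window used as the
#'   prominence baseline.
#' @return A tibble of class `facexpr_rpeaks` with columns `time` (seconds,
#'   strictly increasing) and `prominence`; the sampling rate is carried in
#'   the `rate` attribute. RR intervals are `diff(time)`.
#' @export
detect_r_peaks <- function(x, rate, amplitude_threshold = NULL,
                           chunk_s = 0.016, refractory_s = 0.3,
                           search_s = 0.03, baseline_s = 0.2) {
  if (is.data.frame(x)) x <- x$value
  assert_number(rate, "rate", lower = 1e-9)
  if (!is.null(amplitude_threshold)) {
    assert_number(amplitude_threshold, "amplitude_threshold", lower = 1e-12)
  }
  n <- length(x)
  if (n < 8L) abort("Signal too short for R-peak detection.")
  chunk <- max(4L, as.integer(round(chunk_s * rate)))
  sigma <- mad(diff(x)) / sqrt(2)
  penalty <- 6 * sigma^2 * log(n)
  cand <- bottom_up_breakpoints(x, chunk, penalty)
  if (length(cand) == 0L) abort("No change-point candidates found (flat signal?).")

  w <- max(1L, as.integer(round(search_s * rate)))
  b <- max(w + 1L, as.integer(round(baseline_s * rate)))
  refine <- vapply(cand, function(c0) {
    lo <- max(1L, c0 - w); hi <- min(n, c0 + w)
    lo + which.max(x[lo:hi]) - 1L
  }, 0L)
  refine <- sort(unique(refine))
  prom <- vapply(refine, function(pk) {
    lo <- max(1L, pk - b); hi <- min(n, pk + b)
    x[pk] - median(x[lo:hi])
  }, 0)
  keep <- prom > 0
  refine <- refine[keep]; prom <- prom[keep]
  if (length(refine) == 0L) abort("No positive-prominence candidates; cannot locate R peaks.")

  thr <- amplitude_threshold %||%
    (0.6 * quantile(prom, 0.99, names = FALSE, type = 7))
  sel <- prom > thr
  peaks <- refine[sel]; pprom <- prom[sel]

  # refractory deduplication: among peaks closer than refractory_s keep the
  # more prominent one
  min_gap <- refractory_s * rate
  repeat {
    if (length(peaks) < 2L) break
    gaps <- diff(peaks)
    v <- which(gaps < min_gap)
    if (length(v) == 0L) break
    i <- v[1L]
    drop <- if (pprom[i] >= pprom[i + 1L]) i + 1L else i
    peaks <- peaks[-drop]; pprom <- pprom[-drop]
  }
  if (length(peaks) < 2L) {
    abort("Fewer than two R peaks retained; RR intervals undefined.")
  }
  out <- tibble(time = (peaks - 1L) / rate, prominence = pprom)
  class(out) <- c("facexpr_rpeaks", class(out))
  attr(out, "rate") <- rate
  out
}

#' Heart rate and heart-rate variability from detected R peaks
#'
#' Each RR interval yields an instantaneous heart rate `60 / RR` (beats per
#' minute); HR is the mean of that series and HRV its dispersion — by default
#' the sample standard deviation of the instantaneous HR, alternatively the
#' RMSSD of successive instantaneous-HR differences. RR intervals outside the
#' physiologic bounds are discarded first.
#'
#' @param peaks A `facexpr_rpeaks` tibble, a data frame with a `time` column,
#'   or a numeric vector of peak times in seconds (strictly increasing).
#' @param rr_bounds Physiologic RR bounds in seconds; intervals outside are
#'   dropped.
#' @param method HRV summary: `"sd"` (default) or `"rmssd"`.
#' @return One-row tibble: `hr` (bpm), `hrv` (bpm; `NA` when fewer than two
#'   RR intervals survive), `n_beats`.
#' @export
#' @examples
#' hr_hrv(c(0, 1, 2, 3))  # 60 bpm, HRV 0
hr_hrv <- function(peaks, rr_bounds = c(0.3, 2.0), method = c("sd", "rmssd")) {
  method <- match.arg(method)
  times <- if (is.data.frame(peaks)) peaks$time else peaks
  if (!is.numeric(times) || length(times) < 2L) {
    abort("Need at least two peak times to define an RR interval.")
  }
  if (any(diff(times) <= 0)) abort("Peak times must be strictly increasing.")
  rr <- diff(times)
  rr <- rr[rr >= rr_bounds[1L] & rr <= rr_bounds[2L]]
  if (length(rr) < 1L) {
    abort("No RR intervals within physiologic bounds; HR undefined.")
  }
  inst <- 60 / rr
  hrv <- if (length(inst) >= 2L) {
    if (method == "sd") sd(inst) else sqrt(mean(diff(inst)^2))
  } else {
    NA_real_
  }
  tibble(hr = mean(inst), hrv = hrv, n_beats = length(times))
}
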