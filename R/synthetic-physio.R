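# Synthetic ECG and facial-EMG generators with recorded ground truth.

# Beat template: sum of Gaussians for the P, Q, R, S and T deflections, with
# the dominant R wave centred at the beat time.
ecg_template <- function(tau) {
  0.12 * exp(-((tau + 0.22) / 0.030)^2 / 2) -
    0.12 * exp(-((tau + 0.028) / 0.010)^2 / 2) +
    1.00 * exp(-(tau / 0.012)^2 / 2) -
    0.22 * exp(-((tau - 0.030) / 0.012)^2 / 2) +
    0.28 * exp(-((tau - 0.26) / 0.055)^2 / 2)
}

#' Generate a synthetic ECG with known beat times
#'
#' Places a fixed PQRST template (unit R amplitude) at beat times whose
#' intervals follow `RR_k = 60 / HR_k`, `HR_k ~ Normal(mean_hr, hr_sd)`
#' (truncated to 30–200 bpm); the first beat sits half an interval into the
#' record, so `mean_hr = 60`, `hr_sd = 0` gives beats at 0.5 s, 1.5 s, ...
#' Additive white Gaussian noise is controlled either directly by `noise_sd`
#' or via a target `snr_db` relative to the clean signal power.
#'
#' @param duration Record length in seconds; must hold at least two beats.
#' @param rate Sampling rate in Hz (>= 128).
#' @param mean_hr,hr_sd Mean and SD of the instantaneous heart rate (bpm).
#' @param noise_sd Additive noise standard deviation (signal units).
#' @param snr_db Optional target signal-to-noise ratio in dB; overrides
#'   `noise_sd`.
#' @param seed Integer seed for reproducibility.
#' @return List with `signal` (tibble `time_s`, `value`), `clean` (noise-free
#'   series) and `truth` (list: `beat_times` seconds, `beat_samples` 1-based
#'   indices, `mean_hr`, `hr_sd`, `noise_sd`, `seed`).
#' @export
#' @examples
#' ecg <- generate_ecg(10, rate = 256, mean_hr = 60, hr_sd = 0, noise_sd = 0)
#' head(ecg$truth$beat_times)
generate_ecg <- function(duration, rate = 512, mean_hr = 60, hr_sd = 3,
                         noise_sd = 0.05, snr_db = NULL, seed = NULL) {
  assert_number(duration, "duration", lower = 1e-9)
  assert_number(rate, "rate", lower = 128)
  assert_number(mean_hr, "mean_hr", lower = 30, upper = 200)
  assert_number(hr_sd, "hr_sd", lower = 0)
  if (duration < 2 * 60 / mean_hr) {
    abort("`duration` is shorter than two beats; heart rate undefined.")
  }
  n <- as.integer(round(duration * rate))
  ts <- (seq_len(n) - 1L) / rate

  with_seed(seed, {
    draw_hr <- function() {
      if (hr_sd == 0) return(mean_hr)
      min(max(rnorm(1, mean_hr, hr_sd), 30), 200)
    }
    beats <- numeric()
    t <- 60 / draw_hr() / 2
    while (t < duration) {
      beats <- c(beats, t)
      t <- t + 60 / draw_hr()
    }
    if (length(beats) < 2L) {
      abort("`duration` is shorter than two beats; heart rate undefined.")
    }

    clean <- numeric(n)
    half <- as.integer(ceiling(0.4 * rate))
    for (bt in beats) {
      c0 <- as.integer(round(bt * rate)) + 1L
      lo <- max(1L, c0 - half); hi <- min(n, c0 + half)
      clean[lo:hi] <- clean[lo:hi] + ecg_template(ts[lo:hi] - bt)
    }
    if (!is.null(snr_db)) {
      noise_sd <- sqrt(mean(clean^2) / 10^(snr_db / 10))
    }
    value <- clean + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0

    list(
      signal = tibble(time_s = ts, value = value),
      clean = clean,
      truth = list(
        beat_times = beats,
        beat_samples = as.integer(round(beats * rate)) + 1L,
        mean_hr = mean_hr, hr_sd = hr_sd,
        noise_sd = noise_sd, rate = rate, seed = seed
      )
    )
  })
}

#' Generate burst-modulated synthetic facial EMG
#'
#' Zero-mean Gaussian noise whose envelope is `baseline_sd` outside the
#' burst windows and `burst_ratio * baseline_sd` inside them, mimicking
#' muscle-contraction bursts over a tonic baseline. Because the AMV of
#' Gaussian noise is proportional to its SD, a window fully covered by
#' bursts has AMV exactly `burst_ratio` times the baseline AMV in
#' expectation.
#'
#' @param duration Record length in seconds.
#' @param rate Sampling rate in Hz.
#' @param baseline_sd Baseline envelope SD (signal units).
#' @param burst_ratio Burst-to-baseline amplitude ratio (>= 1).
#' @param burst_windows Data frame with `start`/`end` columns in seconds
#'   (non-overlapping), or `NULL` for no bursts.
#' @param seed Integer seed.
#' @return List with `signal` (tibble `time_s`, `value`) and `truth` (list:
#'   `burst_ratio`, `burst_windows`, `baseline_sd`, `rate`, `seed`).
#' @export
generate_emg <- function(duration, rate = 2000, baseline_sd = 1,
                         burst_ratio = 1, burst_windows = NULL, seed = NULL) {
  assert_number(duration, "duration", lower = 1e-9)
  assert_number(rate, "rate", lower = 1e-9)
  assert_number(baseline_sd, "baseline_sd", lower = 1e-12)
  assert_number(burst_ratio, "burst_ratio", lower = 1)
  if (!is.null(burst_windows) && nrow(burst_windows) > 0L) {
    bw <- dplyr::arrange(as_tibble(burst_windows), .data$start)
    if (any(bw$end <= bw$start)) abort("Burst windows must have end > start.")
    if (nrow(bw) > 1L && any(bw$start[-1L] < bw$end[-nrow(bw)])) {
      abort("Burst windows must not overlap.")
    }
  } else {
    bw <- tibble(start = numeric(), end = numeric())
  }
  n <- as.integer(round(duration * rate))
  ts <- (seq_len(n) - 1L) / rate
  env <- rep(baseline_sd, n)
  for (i in seq_len(nrow(bw))) {
    env[ts >= bw$start[i] & ts < bw$end[i]] <- baseline_sd * burst_ratio
  }
  with_seed(seed, {
    value <- rnorm(n) * env
    list(
      signal = tibble(time_s = ts, value = value),
      truth = list(burst_ratio = burst_ratio, burst_windows = bw,
                   baseline_sd = baseline_sd, rate = rate, seed = seed)
    )
  })
}
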