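#' Absolute mean value (AMV) of an EMG window
#'
#' The rectified mean `AMV = (1/N) * sum(|x_t|)`, the standard amplitude
#' feature for surface EMG. Because raw EMG is zero-mean, rectification is
#' what makes the mean measure contraction strength; the literal signed mean
#' is available with `rectify = FALSE` for auditability (it is approximately
#' zero on real recordings).
#'
#' @param x Numeric EMG samples, or a data frame with a `value` column.
#' @param rectify Take absolute values before averaging (default `TRUE`).
#' @return Scalar AMV; scales linearly with the signal amplitude.
#' @export
#' @examples
#' emg_amv(c(1, -1, 2, -2))  # 1.5
emg_amv <- function(x, rectify = TRUE) {
  if (is.data.frame(x)) x <- x$value
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    abort("`x` must be a non-empty finite numeric series.")
  }
  if (rectify) mean(abs(x)) else mean(x)
}

#' Physiological features of a stimulus window relative to a neutral baseline
#'
#' Computes heart rate and heart-rate variability deltas (stimulus minus
#' neutral, via EMD denoising, change-point R-peak detection and
#' [hr_hrv()]) and, per EMG channel, the window AMV expressed as a
#' percentage of the neutral-baseline AMV
#' (`AMV% = 100 * AMV_stim / AMV_neutral`) — the normalization that makes
#' widely different per-subject EMG amplitudes comparable.
#'
#' @param stim,neutral Lists describing the two windows. Recognized elements:
#'   `ecg` (numeric or `time_s`/`value` data frame), `ecg_rate` (Hz), `emg`
#'   (named list of numeric channels, e.g. `lls`, `oo`), `emg_rate` (Hz,
#'   carried along for provenance). Either branch may be absent.
#' @param denoise Denoise the ECG with [emd_denoise()] before peak detection.
#' @param amplitude_threshold Passed to [detect_r_peaks()].
#' @param hrv_method Passed to [hr_hrv()].
#' @return One-row tibble with whichever of `hr_delta`, `hrv_delta` (bpm) and
#'   `amv_pct_<channel>` (percent) the inputs support.
#' @export
physio_features <- function(stim, neutral, denoise = TRUE,
                            amplitude_threshold = NULL,
                            hrv_method = c("sd", "rmssd")) {
  hrv_method <- match.arg(hrv_method)
  out <- list()

  if (!is.null(stim$ecg) && !is.null(neutral$ecg)) {
    rate <- stim$ecg_rate %||% neutral$ecg_rate
    if (is.null(rate)) abort("`ecg_rate` must be supplied with ECG data.")
    one <- function(sig) {
      x <- if (is.data.frame(sig)) sig$value else sig
      if (denoise) x <- emd_denoise(x)
      hr_hrv(detect_r_peaks(x, rate, amplitude_threshold),
             method = hrv_method)
    }
    fs <- one(stim$ecg)
    fn <- one(neutral$ecg)
    out$hr_delta <- fs$hr - fn$hr
    out$hrv_delta <- fs$hrv - fn$hrv
  }

  if (!is.null(stim$emg) && !is.null(neutral$emg)) {
    chans <- intersect(names(stim$emg), names(neutral$emg))
    if (length(chans) == 0L) abort("No common EMG channels between windows.")
    for (ch in chans) {
      base <- emg_amv(neutral$emg[[ch]])
      if (base == 0) {
        abort(sprintf("Neutral-baseline AMV is zero for channel %s; percentage undefined.", ch))
      }
      out[[paste0("amv_pct_", ch)]] <- 100 * emg_amv(stim$emg[[ch]]) / base
    }
  }

  if (length(out) == 0L) {
    abort("Neither ECG nor EMG present in both windows.")
  }
  tibble::as_tibble(out)
}
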