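test_that("EMD reconstructs the input exactly and separates scales", {
  set.seed(3)
  fs <- 256; n <- 2048
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 2 * t) + 0.3 * sin(2 * pi * 40 * t)
  dec <- emd(x)
  expect_gt(length(dec$imfs), 1)
  recon <- Reduce(`+`, dec$imfs) + dec$residue
  expect_equal(recon, x, tolerance = 1e-12)
  # the fast component concentrates in the earliest IMFs
  fast <- 0.3 * sin(2 * pi * 40 * t)
  expect_gt(cor(dec$imfs[[1]], fast), 0.9)
})

test_that("denoising preserves a clean low-frequency tone", {
  fs <- 512; n <- 4096
  t <- (0:(n - 1)) / fs
  clean <- sin(2 * pi * 2 * t)
  out <- emd_denoise(clean)
  expect_gte(cor(out, clean), 0.99)
  # zero and constant signals pass through unchanged
  expect_identical(emd_denoise(rep(0, 64)), rep(0, 64))
  expect_identical(emd_denoise(rep(1.3, 64)), rep(1.3, 64))
  expect_error(emd_denoise(1:8), "length")
})

test_that("denoising improves SNR on a noisy tone and never amplifies the tone bin", {
  fs <- 512; n <- 4096
  t <- (0:(n - 1)) / fs
  clean <- sin(2 * pi * 2 * t)
  bin <- 2 * n / fs + 1  # FFT bin of the 2 Hz tone
  for (snr_in in c(0, 10)) {
    improved <- 0
    for (s in 1:5) {
      set.seed(1000 + s)
      nsd <- sqrt(mean(clean^2) / 10^(snr_in / 10))
      noisy <- clean + rnorm(n, 0, nsd)
      den <- emd_denoise(noisy)
      if (snr_db(clean, den) > snr_db(clean, noisy)) improved <- improved + 1
      expect_lte(Mod(stats::fft(den)[bin]),
                 Mod(stats::fft(noisy)[bin]) * 1.05)
    }
    expect_gte(improved, 4)
  }
})

test_that("R peaks are recovered exactly on clean synthetic ECG", {
  e <- generate_ecg(10, rate = 512, mean_hr = 60, hr_sd = 0, noise_sd = 0,
                    seed = 1)
  expect_equal(e$truth$beat_times, seq(0.5, 9.5, by = 1))
  pk <- detect_r_peaks(e$signal$value, 512)
  expect_equal(nrow(pk), 10)
  det_samples <- round(pk$time * 512) + 1
  expect_true(all(abs(det_samples - e$truth$beat_samples) <= 2))
  # flat signal carries no events
  expect_error(detect_r_peaks(rep(0, 5000), 512))
})

test_that("peak detection stays accurate at moderate noise after denoising", {
  e <- generate_ecg(30, rate = 512, mean_hr = 70, hr_sd = 3, snr_db = 10,
                    seed = 3)
  den <- emd_denoise(e$signal$value)
  pk <- detect_r_peaks(den, 512)
  m <- match_peaks(pk$time, e$truth$beat_times, tol = 0.05)
  expect_gte(m["sensitivity"], 0.99)
  expect_gte(m["ppv"], 0.99)
  ht <- hr_hrv(e$truth$beat_times)
  hd <- hr_hrv(pk)
  expect_lt(abs(hd$hr - ht$hr), 1)
  expect_lt(abs(hd$hrv - ht$hrv) / ht$hrv, 0.1)
})

test_that("HR and HRV follow their definitions on hand series", {
  r <- hr_hrv(c(0, 1, 2))
  expect_equal(r$hr, 60)
  expect_equal(r$hrv, 0)
  # RR = 1.0, 0.9, 1.1 s: instantaneous HR 60, 66.67, 54.55; sample SD 6.07
  r2 <- hr_hrv(cumsum(c(0, 1.0, 0.9, 1.1)))
  inst <- 60 / c(1.0, 0.9, 1.1)
  expect_equal(r2$hr, mean(inst))
  expect_equal(r2$hrv, sd(inst))
  expect_equal(round(r2$hrv, 2), 6.07)
  # RMSSD alternative
  r3 <- hr_hrv(cumsum(c(0, 1.0, 0.9, 1.1)), method = "rmssd")
  expect_equal(r3$hrv, sqrt(mean(diff(inst)^2)))
  # physiologic bound filtering drops absurd intervals
  r4 <- hr_hrv(c(0, 1, 1.1, 2.1))
  expect_equal(r4$hr, 60)
  expect_error(hr_hrv(1.5), "two peak")
  expect_error(hr_hrv(c(1, 1)), "increasing")
})

test_that("AMV is the rectified mean and scales homogeneously", {
  expect_equal(emg_amv(c(1, -1, 2, -2)), 1.5)
  expect_equal(emg_amv(rep(0, 10)), 0)
  set.seed(5)
  x <- rnorm(500)
  expect_equal(emg_amv(3.7 * x), 3.7 * emg_amv(x))
  # literal signed mean is available and near zero for zero-mean noise
  expect_equal(emg_amv(x, rectify = FALSE), mean(x))
})

test_that("window features contrast stimulus against neutral baseline", {
  # identical windows: zero deltas, AMV at exactly 100 percent
  e <- generate_ecg(20, rate = 256, mean_hr = 65, hr_sd = 2, noise_sd = 0.03,
                    seed = 8)
  m <- generate_emg(5, rate = 500, baseline_sd = 1, seed = 9)
  win <- list(ecg = e$signal$value, ecg_rate = 256,
              emg = list(lls = m$signal$value))
  f <- physio_features(win, win)
  expect_equal(f$hr_delta, 0)
  expect_equal(f$hrv_delta, 0)
  expect_equal(f$amv_pct_lls, 100)

  # burst-covered stimulus window: AMV percent tracks the burst ratio
  base <- generate_emg(10, rate = 500, baseline_sd = 1, seed = 10)
  burst <- generate_emg(10, rate = 500, baseline_sd = 1, burst_ratio = 3,
                        burst_windows = data.frame(start = 0, end = 10),
                        seed = 11)
  f2 <- physio_features(list(emg = list(lls = burst$signal$value)),
                        list(emg = list(lls = base$signal$value)))
  expect_gt(f2$amv_pct_lls, 285)
  expect_lt(f2$amv_pct_lls, 315)

  # elevated stimulus heart rate shows up as a positive delta
  es <- generate_ecg(60, rate = 256, mean_hr = 70, hr_sd = 2, noise_sd = 0.02,
                     seed = 12)
  en <- generate_ecg(60, rate = 256, mean_hr = 60, hr_sd = 2, noise_sd = 0.02,
                     seed = 13)
  f3 <- physio_features(list(ecg = es$signal$value, ecg_rate = 256),
                        list(ecg = en$signal$value, ecg_rate = 256))
  expect_lt(abs(f3$hr_delta -
                  (hr_hrv(es$truth$beat_times)$hr -
                     hr_hrv(en$truth$beat_times)$hr)), 1)
  expect_error(
    physio_features(list(emg = list(lls = c(1, 2))),
                    list(emg = list(lls = c(0, 0)))), "zero")
  expect_error(physio_features(list(), list()), "Neither")
})
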