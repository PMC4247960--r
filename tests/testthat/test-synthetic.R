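test_that("archetype table satisfies its invariants", {
  p <- archetype_params()
  expect_identical(p$group_label, c("C", "LP", "IP", "MP"))
  expect_true(all(p$apex_intensity_mean > 0 & p$apex_intensity_mean < 1))
  expect_true(all(p$neutral_persistent_level < p$apex_intensity_mean))
  expect_true(all(p$onset_frames >= 1 & p$apex_frames >= 1 &
                    p$offset_frames >= 1))
  expect_identical(archetype_params("IP")$group_label, "IP")
})

test_that("score generation honors the no-episode and determinism contracts", {
  p <- archetype_params("C")
  p$episode_rate <- 0
  p$score_noise_sd <- 0
  p$neutral_persistent_level <- 0.3
  p$persistent_aus <- NULL  # drop the column: persistence applies to all AUs
  calib <- c(A = -2, B = 0.4)
  g <- generate_au_scores(p, aus = c("AU1", "AU4"), n_frames = 50,
                          calib = calib, seed = 4, role = "neutral")
  # noise-free, episode-free: the sigmoid recovers the persistent level exactly
  rec <- platt_probability(calib, g$scores$score)
  expect_equal(rec, rep(0.3, 100), tolerance = 1e-12)
  expect_equal(nrow(g$truth$episodes), 0)
  # stimulus role uses the probability floor instead
  g2 <- generate_au_scores(p, aus = "AU1", n_frames = 20, calib = calib,
                           seed = 4, role = "stimulus")
  expect_equal(unique(round(platt_probability(calib, g2$scores$score), 10)),
               0.02)

  # identical seeds give identical output
  a <- generate_au_scores(archetype_params("LP"), n_frames = 200, seed = 99)
  b <- generate_au_scores(archetype_params("LP"), n_frames = 200, seed = 99)
  expect_identical(a, b)
  c <- generate_au_scores(archetype_params("LP"), n_frames = 200, seed = 100)
  expect_false(identical(a$scores$score, c$scores$score))
})

test_that("episode counts stay within the Poisson band and never overlap", {
  p <- archetype_params("C")
  g <- generate_au_scores(p, n_frames = 750, seed = 1)
  counts <- table(factor(g$truth$episodes$au, levels = au_names()))
  band <- stats::qpois(c(0.005, 0.995), p$episode_rate)
  expect_true(all(counts >= band[1] & counts <= band[2]))
  # per AU: boundaries sorted and non-overlapping
  for (a in unique(g$truth$episodes$au)) {
    e <- g$truth$episodes[g$truth$episodes$au == a, ]
    expect_true(all(diff(e$start_frame) > 0))
    expect_true(all(e$end_frame > e$start_frame))
    if (nrow(e) > 1) {
      expect_true(all(e$start_frame[-1] >= e$end_frame[-nrow(e)]))
    }
  }
})

test_that("generator rejects invalid calibration and degenerate parameters", {
  p <- archetype_params("C")
  expect_error(generate_au_scores(p, calib = c(A = 1, B = 0)), "negative")
  expect_error(generate_au_scores(p, n_frames = 100, frame_rate = 0), "frame_rate")
  bad <- p; bad$neutral_persistent_level <- 0.9
  expect_error(generate_au_scores(bad), "below")
})

test_that("applying the known sigmoid to generated scores recovers the profile", {
  p <- archetype_params("C")
  p$disgust_sync_prob <- 0
  calib <- c(A = -1.5, B = 0.2)
  g <- generate_au_scores(p, aus = "AU6", n_frames = 600, calib = calib,
                          seed = 21)
  rec <- platt_probability(calib, g$scores$score)
  # inside apex plateaus the recovered intensity sits near the recorded apex
  eps <- g$truth$episodes
  for (j in seq_len(nrow(eps))) {
    on_end <- eps$start_frame[j] + (eps$end_frame[j] - eps$start_frame[j]) %/% 2
    mid <- rec[g$scores$frame == on_end]
    expect_lt(abs(mid - eps$apex[j]), 0.2)
  }
  # noise-free version recovers it exactly
  p0 <- p; p0$score_noise_sd <- 0
  g0 <- generate_au_scores(p0, aus = "AU6", n_frames = 600, calib = calib,
                           seed = 21)
  rec0 <- platt_probability(calib, g0$scores$score)
  for (j in seq_len(nrow(g0$truth$episodes))) {
    e <- g0$truth$episodes[j, ]
    apex_frames <- (e$start_frame + 1):(e$end_frame)
    expect_equal(max(rec0[apex_frames]), e$apex, tolerance = 1e-9)
  }
})

test_that("ECG truth matches its construction and argmax on clean beats", {
  e <- generate_ecg(10, rate = 256, mean_hr = 60, hr_sd = 0, noise_sd = 0,
                    seed = 2)
  expect_equal(e$truth$beat_times, seq(0.5, 9.5, 1))
  expect_equal(mean(diff(e$truth$beat_times)), 1)
  # argmax within each beat window lands on the true beat sample
  for (bs in e$truth$beat_samples) {
    win <- (bs - 20):(bs + 20)
    expect_equal(win[which.max(e$signal$value[win])], bs)
  }
  expect_error(generate_ecg(1.2, rate = 256, mean_hr = 60), "two beats")
  expect_identical(generate_ecg(10, rate = 256, seed = 5),
                   generate_ecg(10, rate = 256, seed = 5))
})

test_that("EMG envelope honors burst windows and rejects overlap", {
  base <- generate_emg(4, rate = 500, baseline_sd = 1, seed = 1)
  same <- generate_emg(4, rate = 500, baseline_sd = 1, burst_ratio = 1,
                       burst_windows = data.frame(start = 1, end = 2),
                       seed = 1)
  # ratio one: identical distribution (identical realization under one seed)
  expect_equal(base$signal$value, same$signal$value)
  expect_error(
    generate_emg(4, rate = 500, burst_ratio = 2,
                 burst_windows = data.frame(start = c(0, 1), end = c(1.5, 2))),
    "overlap")
  # rectified-mean oracle: burst samples scale by the ratio
  b <- generate_emg(6, rate = 500, baseline_sd = 0.8, burst_ratio = 3,
                    burst_windows = data.frame(start = 2, end = 4), seed = 3)
  ts <- b$signal$time_s
  inside <- ts >= 2 & ts < 4
  r_hat <- emg_amv(b$signal$value[inside]) / emg_amv(b$signal$value[!inside])
  expect_lt(abs(r_hat - 3) / 3, 0.1)
})

test_that("cohort bookkeeping: counts, determinism, file layout", {
  d1 <- withr::local_tempdir()
  m_path <- generate_cohort(d1, n_per_group = 1, seed = 7,
                            include_physio = FALSE)
  man <- read_cohort_manifest(m_path)
  expect_equal(nrow(man$subjects), 4)
  expect_equal(nrow(man$windows), 12)
  expect_true(all(file.exists(man$windows$scores)))
  expect_setequal(unique(man$windows$stimulus),
                  c("disgust#1", "disgust#2", "neutral#2"))

  # regenerating with the same seed reproduces the manifest byte for byte
  d2 <- withr::local_tempdir()
  m2 <- generate_cohort(d2, n_per_group = 1, seed = 7, include_physio = FALSE)
  expect_identical(readLines(m_path), readLines(m2))
  f <- man$windows$scores[1]
  f2 <- read_cohort_manifest(m2)$windows$scores[1]
  expect_identical(unname(tools::md5sum(f)), unname(tools::md5sum(f2)))

  # physio files appear when requested (reduced rates keep the fixture small)
  d3 <- withr::local_tempdir()
  m3 <- generate_cohort(d3, n_per_group = 1, seed = 3, include_physio = TRUE,
                        ecg_rate = 128, emg_rate = 200)
  man3 <- read_cohort_manifest(m3)
  expect_true(all(file.exists(man3$windows$ecg)))
  expect_true(all(file.exists(man3$windows$emg_lls)))
  sig <- read_signal(man3$windows$ecg[1])
  expect_equal(nrow(sig), 30 * 128)
  expect_true(file.exists(file.path(d3, "truth",
                                    paste0(man3$windows$subject[1], "_",
                                           "disgust1_episodes.csv"))))
})
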