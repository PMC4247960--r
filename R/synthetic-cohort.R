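# Whole-cohort simulation: AU scores, ECG and facial EMG for every subject
# and stimulus window, with ground truth carried alongside.

cohort_stimuli <- function() c("disgust#1", "disgust#2", "neutral#2")

stimulus_slug <- function(stimulus) gsub("#", "", stimulus, fixed = TRUE)

# Per-group physiological wiring: disgust windows raise heart rate a few bpm
# and modulate EMG bursts; attenuated in the Parkinson archetypes.
physio_archetype <- function(group) {
  i <- match(group, c("C", "LP", "IP", "MP"))
  list(
    neutral_hr = 62,
    disgust_hr = c(68, 66, 66, 64)[i],
    hr_sd = 3,
    lls_ratio = c(3.2, 1.7, 2.3, 1.3)[i],
    oo_ratio = c(2.4, 1.4, 1.9, 1.2)[i]
  )
}

# Non-overlapping burst windows for a disgust EMG record.
draw_burst_windows <- function(duration, n_bursts = 6L, burst_s = 1.5) {
  starts <- sort(runif(n_bursts, 0, duration - burst_s))
  keep <- numeric()
  last_end <- -Inf
  for (s in starts) {
    if (s >= last_end) {
      keep <- c(keep, s)
      last_end <- s + burst_s
    }
  }
  tibble(start = keep, end = keep + burst_s)
}

#' Simulate a full synthetic cohort in memory
#'
#' Draws `n_per_group` subjects per archetype (C, LP, IP, MP) and, for each
#' subject, the three stimulus windows (disgust#1, disgust#2, neutral#2):
#' per-frame AU decision values via [generate_au_scores()] and, optionally,
#' ECG and two-channel facial EMG via [generate_ecg()] / [generate_emg()].
#' All randomness derives from `seed`, so identical seeds give identical
#' cohorts.
#'
#' @param n_per_group Subjects per group (>= 1).
#' @param seed Integer master seed.
#' @param frame_rate Video frame rate (fps); windows span `window_s` seconds.
#' @param window_s Thin-slice window length in seconds.
#' @param calib Known Platt coefficients used to encode intensities as
#'   decision values.
#' @param include_physio Also simulate ECG/EMG (heavier; disable for purely
#'   facial experiments).
#' @param ecg_rate,emg_rate Sampling rates in Hz.
#' @param params Archetype table (default [archetype_params()]); must contain
#'   one row per group label used.
#' @return List with `info` (rates, calibration, seed), `subjects` tibble and
#'   a nested `windows` tibble: one row per subject-by-stimulus window with
#'   list columns `scores`, `episodes` (AU ground truth) and, when
#'   `include_physio` is set, `ecg`, `ecg_truth`, `emg` (named channel list)
#'   and `emg_truth`.
#' @export
simulate_cohort_data <- function(n_per_group = 5L, seed = 1L,
                                 frame_rate = 25, window_s = 30,
                                 calib = c(A = -2, B = 0),
                                 include_physio = TRUE,
                                 ecg_rate = 512, emg_rate = 2000,
                                 params = archetype_params()) {
  assert_number(n_per_group, "n_per_group", lower = 1)
  n_per_group <- as.integer(n_per_group)
  n_frames <- as.integer(round(window_s * frame_rate))
  groups <- params$group_label
  subjects <- tibble(
    subject = unlist(lapply(groups, function(g) {
      sprintf("%s%02d", g, seq_len(n_per_group))
    })),
    group = rep(groups, each = n_per_group)
  )
  stimuli <- cohort_stimuli()
  grid <- tidyr::expand_grid(subjects, stimulus = stimuli)
  seeds <- child_seeds(seed, nrow(grid) * 5L)
  seed_mat <- matrix(seeds, ncol = 5L)

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$group[i]
    stim <- grid$stimulus[i]
    p <- params[params$group_label == g, ]
    is_neutral <- grepl("^neutral", stim)
    p_win <- p
    if (is_neutral) p_win$episode_rate <- p$episode_rate * 0.3
    au <- generate_au_scores(
      p_win, n_frames = n_frames, frame_rate = frame_rate, calib = calib,
      seed = seed_mat[i, 1L], role = if (is_neutral) "neutral" else "stimulus"
    )
    row <- tibble(
      subject = grid$subject[i], group = g, stimulus = stim,
      seed = seed_mat[i, 1L],
      scores = list(au$scores), episodes = list(au$truth$episodes)
    )
    if (include_physio) {
      ph <- physio_archetype(g)
      mean_hr <- if (is_neutral) ph$neutral_hr else ph$disgust_hr
      ecg <- generate_ecg(window_s, rate = ecg_rate, mean_hr = mean_hr,
                          hr_sd = ph$hr_sd, noise_sd = 0.05,
                          seed = seed_mat[i, 2L])
      scale <- with_seed(seed_mat[i, 3L], exp(rnorm(1, 0, 0.3)))
      mk_emg <- function(ratio, s) {
        if (is_neutral) {
          generate_emg(window_s, rate = emg_rate, baseline_sd = scale,
                       burst_ratio = 1, seed = s)
        } else {
          bw <- with_seed(s, draw_burst_windows(window_s))
          generate_emg(window_s, rate = emg_rate, baseline_sd = scale,
                       burst_ratio = ratio, burst_windows = bw,
                       seed = s + 1L)
        }
      }
      lls <- mk_emg(ph$lls_ratio, seed_mat[i, 4L])
      oo <- mk_emg(ph$oo_ratio, seed_mat[i, 5L])
      row$ecg <- list(ecg$signal)
      row$ecg_truth <- list(ecg$truth)
      row$emg <- list(list(lls = lls$signal, oo = oo$signal))
      row$emg_truth <- list(list(lls = lls$truth, oo = oo$truth))
    }
    row
  })

  list(
    info = list(seed = seed, n_per_group = n_per_group,
                frame_rate = frame_rate, window_s = window_s,
                n_frames = n_frames, ecg_rate = ecg_rate,
                emg_rate = emg_rate,
                calibration = as.list(platt_coefs(calib))),
    subjects = subjects,
    windows = dplyr::bind_rows(rows)
  )
}

#' Write a synthetic cohort to disk with its manifest
#'
#' Materializes [simulate_cohort_data()] as the on-disk interchange layout:
#' one wide score CSV per subject-by-window, one `time_s`/`value` CSV per
#' signal channel, ground-truth CSVs under `truth/` (episode boundaries and
#' apex intensities, beat times, EMG burst ratios), and a YAML manifest tying
#' subjects, group labels, stimuli, rates, seeds and file paths together.
#'
#' @param dir Output directory (created if needed; must be writable).
#' @inheritParams simulate_cohort_data
#' @return The manifest path, invisibly; read back with
#'   [read_cohort_manifest()] and analyse with [run_pipeline()].
#' @export
generate_cohort <- function(dir, n_per_group = 5L, seed = 1L,
                            frame_rate = 25, window_s = 30,
                            calib = c(A = -2, B = 0),
                            include_physio = TRUE,
                            ecg_rate = 512, emg_rate = 2000,
                            params = archetype_params()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L) {
    abort(sprintf("Target directory is not writable: %s", dir))
  }
  for (sub in c("scores", "signals", "truth")) {
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  }
  cohort <- simulate_cohort_data(
    n_per_group = n_per_group, seed = seed, frame_rate = frame_rate,
    window_s = window_s, calib = calib, include_physio = include_physio,
    ecg_rate = ecg_rate, emg_rate = emg_rate, params = params
  )

  win_entries <- lapply(seq_len(nrow(cohort$windows)), function(i) {
    w <- cohort$windows[i, ]
    tag <- sprintf("%s_%s", w$subject, stimulus_slug(w$stimulus))
    scores_rel <- file.path("scores", paste0(tag, ".csv"))
    write_au_scores(w$scores[[1L]], file.path(dir, scores_rel))
    readr::write_csv(w$episodes[[1L]],
                     file.path(dir, "truth", paste0(tag, "_episodes.csv")),
                     progress = FALSE)
    entry <- list(subject = w$subject, stimulus = w$stimulus,
                  scores = scores_rel, seed = w$seed)
    if (include_physio) {
      ecg_rel <- file.path("signals", paste0(tag, "_ecg.csv"))
      write_signal(w$ecg[[1L]], file.path(dir, ecg_rel))
      readr::write_csv(tibble(beat_time_s = w$ecg_truth[[1L]]$beat_times),
                       file.path(dir, "truth", paste0(tag, "_beats.csv")),
                       progress = FALSE)
      emg <- w$emg[[1L]]
      lls_rel <- file.path("signals", paste0(tag, "_emg_lls.csv"))
      oo_rel <- file.path("signals", paste0(tag, "_emg_oo.csv"))
      write_signal(emg$lls, file.path(dir, lls_rel))
      write_signal(emg$oo, file.path(dir, oo_rel))
      et <- w$emg_truth[[1L]]
      readr::write_csv(
        tibble(channel = c("lls", "oo"),
               burst_ratio = c(et$lls$burst_ratio, et$oo$burst_ratio),
               baseline_sd = c(et$lls$baseline_sd, et$oo$baseline_sd)),
        file.path(dir, "truth", paste0(tag, "_emg.csv")), progress = FALSE
      )
      entry$ecg <- ecg_rel
      entry$emg_lls <- lls_rel
      entry$emg_oo <- oo_rel
    }
    entry
  })

  manifest <- list(
    cohort = cohort$info,
    subjects = lapply(seq_len(nrow(cohort$subjects)), function(i) {
      list(id = cohort$subjects$subject[i], group = cohort$subjects$group[i])
    }),
    windows = win_entries
  )
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}
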