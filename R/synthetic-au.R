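# Synthetic AU score generator: trapezoidal activation episodes in intensity
# space, mapped back to classifier decision values through a known Platt
# sigmoid, plus Gaussian score noise.

# Probability floor/ceiling used when inverting the sigmoid.
P_FLOOR <- 0.02
P_CEIL <- 0.98

#' Default archetype parameters for the synthetic cohort
#'
#' One row per group describing how that phenotype expresses (and fails to
#' relax): `C` controls, `LP` least-severe, `IP` intermediate and `MP`
#' most-severe Parkinson archetypes. `episode_rate` is the expected number of
#' activation episodes per AU per 30 s stimulus window;
#' `apex_intensity_mean`/`_sd` set the episode apex probability;
#' `neutral_persistent_level` is the tonic activation probability that the
#' AUs in `persistent_aus` hold throughout *neutral* windows (the
#' cannot-relax facet of facial masking: prominent for IP, subthreshold for
#' LP); `*_frames` are mean phase durations at 25 fps; `score_noise_sd` is
#' the decision-value noise; `disgust_sync_prob` is the chance of one
#' coordinated AU4+AU6+AU7+AU9 episode in a disgust window. The defaults are
#' calibrated so that, in expectation, group-mean FE orders C > IP > LP > MP
#' while baseline-corrected EFE orders C > LP > IP > MP — the IP/LP inversion
#' that motivates the baseline correction.
#'
#' @param group Character vector of group labels to return (default all).
#' @return Tibble with one row per requested group.
#' @export
#' @examples
#' archetype_params()
archetype_params <- function(group = c("C", "LP", "IP", "MP")) {
  group <- match.arg(group, c("C", "LP", "IP", "MP"), several.ok = TRUE)
  all <- tibble(
    group_label = c("C", "LP", "IP", "MP"),
    episode_rate = c(1.5, 0.9, 1.0, 0.5),
    apex_intensity_mean = c(0.85, 0.65, 0.80, 0.62),
    apex_intensity_sd = c(0.06, 0.07, 0.06, 0.08),
    neutral_persistent_level = c(0.02, 0.30, 0.75, 0.55),
    onset_frames = c(12, 15, 12, 18),
    apex_frames = c(25, 20, 22, 15),
    offset_frames = c(15, 18, 15, 20),
    score_noise_sd = c(0.25, 0.25, 0.25, 0.25),
    persistent_aus = list(character(), c("AU4", "AU25"),
                          c("AU4", "AU6", "AU25"), c("AU4", "AU25", "AU9")),
    disgust_sync_prob = c(0.9, 0.0, 0.15, 0.0)
  )
  all[match(group, all$group_label), ]
}

validate_archetype <- function(params) {
  stopifnot(is.data.frame(params), nrow(params) == 1L)
  p <- as.list(params)
  assert_number(p$episode_rate, "episode_rate", lower = 0)
  assert_number(p$apex_intensity_mean, "apex_intensity_mean")
  if (p$apex_intensity_mean <= 0 || p$apex_intensity_mean >= 1) {
    abort("`apex_intensity_mean` must lie in (0, 1).")
  }
  assert_number(p$apex_intensity_sd, "apex_intensity_sd", lower = 0)
  assert_number(p$neutral_persistent_level, "neutral_persistent_level", lower = 0)
  if (p$neutral_persistent_level >= p$apex_intensity_mean) {
    abort("`neutral_persistent_level` must be below `apex_intensity_mean`.")
  }
  for (f in c("onset_frames", "apex_frames", "offset_frames")) {
    assert_number(p[[f]], f, lower = 1)
  }
  assert_number(p$score_noise_sd, "score_noise_sd", lower = 0)
  invisible(p)
}

# Duration draw around a mean, at least one frame.
draw_duration <- function(k, mean_frames) {
  1L + rpois(k, max(mean_frames - 1, 0))
}

#' Generate per-frame AU decision-value series with known ground truth
#'
#' Simulates one subject-by-window block of classifier scores. Each AU gets
#' a Poisson number of activation episodes with trapezoidal intensity
#' profiles (linear onset ramp, flat apex, linear offset ramp) over a
#' baseline level; in neutral windows, AUs listed in `persistent_aus` hold
#' the archetype's tonic `neutral_persistent_level` instead of the floor.
#' Intensities are converted to decision values by inverting the known Platt
#' sigmoid and perturbed with Gaussian score noise, so applying the same
#' sigmoid downstream recovers the intended intensity profile up to noise.
#'
#' @param params One-row archetype tibble (see [archetype_params()]); extra
#'   columns `persistent_aus` and `disgust_sync_prob` are honored when
#'   present.
#' @param aus AU names to simulate (default the standard eleven), or a count.
#' @param n_frames Frames per window (default 750 = 30 s at 25 fps).
#' @param frame_rate Frames per second (> 0).
#' @param calib Known sigmoid coefficients `c(A =, B =)`; `A` must be
#'   negative so that larger decision values map to larger probabilities.
#' @param seed Integer seed; identical seeds give identical output.
#' @param role `"stimulus"` or `"neutral"`: controls the baseline level and
#'   whether a coordinated disgust episode may be injected.
#' @return List with `scores` (tibble `frame` 0-based, `au`, `score`) and
#'   `truth` (list: `episodes` tibble with half-open 0-based frame bounds
#'   and apex intensities, plus the parameters, calibration and seed used).
#' @export
generate_au_scores <- function(params, aus = au_names(), n_frames = 750L,
                               frame_rate = 25, calib = c(A = -2, B = 0),
                               seed = NULL, role = c("stimulus", "neutral")) {
  role <- match.arg(role)
  p <- validate_archetype(params)
  if (is.numeric(aus) && length(aus) == 1L) {
    aus <- paste0("SIM", seq_len(aus))
  }
  assert_number(n_frames, "n_frames", lower = 1)
  assert_number(frame_rate, "frame_rate", lower = 1e-9)
  ab <- platt_coefs(calib)
  if (ab[["A"]] >= 0) {
    abort("Calibration slope A must be negative (probability increasing in the score).")
  }
  n_frames <- as.integer(n_frames)
  persistent <- if (!is.null(p$persistent_aus)) unlist(p$persistent_aus) else aus
  sync_prob <- if (!is.null(p$disgust_sync_prob)) p$disgust_sync_prob else 0

  with_seed(seed, {
    sync_eps <- NULL
    if (role == "stimulus" && sync_prob > 0 && runif(1) < sync_prob) {
      on <- draw_duration(1L, p$onset_frames)
      ap <- draw_duration(1L, p$apex_frames)
      off <- draw_duration(1L, p$offset_frames)
      dur <- on + ap + off
      if (dur <= n_frames) {
        start <- sample.int(n_frames - dur + 1L, 1L)
        sync_eps <- list(start = start, onset = on, apex = ap, offset = off,
                         level = min(max(stats::rnorm(1, p$apex_intensity_mean,
                                                      p$apex_intensity_sd),
                                         P_FLOOR + 0.05), P_CEIL))
      }
    }

    per_au <- lapply(aus, function(au) {
      base <- if (role == "neutral" && au %in% persistent) {
        max(p$neutral_persistent_level, P_FLOOR)
      } else {
        P_FLOOR
      }
      prof <- rep(base, n_frames)
      eps <- list()

      k <- rpois(1L, p$episode_rate)
      if (k > 0L) {
        on <- draw_duration(k, p$onset_frames)
        ap <- draw_duration(k, p$apex_frames)
        off <- draw_duration(k, p$offset_frames)
        dur <- on + ap + off
        ok <- dur <= n_frames
        if (any(ok)) {
          starts <- vapply(dur[ok], function(d) {
            sample.int(n_frames - d + 1L, 1L)
          }, 0L)
          ord <- order(starts)
          starts <- starts[ord]
          on <- on[ok][ord]; ap <- ap[ok][ord]; off <- off[ok][ord]
          dur <- dur[ok][ord]
          last_end <- 0L
          for (j in seq_along(starts)) {
            if (starts[j] <= last_end) next  # overlap with previous: drop
            eps[[length(eps) + 1L]] <-
              list(start = starts[j], onset = on[j], apex = ap[j],
                   offset = off[j],
                   level = min(max(stats::rnorm(1, p$apex_intensity_mean,
                                                p$apex_intensity_sd),
                                   base + 0.05), P_CEIL))
            last_end <- starts[j] + dur[j]
          }
        }
      }
      if (!is.null(sync_eps) && au %in% c("AU4", "AU6", "AU7", "AU9")) {
        s0 <- sync_eps$start
        s1 <- s0 + sync_eps$onset + sync_eps$apex + sync_eps$offset
        clash <- vapply(eps, function(e) {
          e0 <- e$start; e1 <- e0 + e$onset + e$apex + e$offset
          e0 < s1 && s0 < e1
        }, TRUE)
        eps <- c(eps[!clash], list(sync_eps))
      }

      rows <- lapply(eps, function(e) {
        a <- e$level
        ramp_up <- base + (a - base) * seq_len(e$onset) / e$onset
        ramp_dn <- a - (a - base) * seq_len(e$offset) / e$offset
        vals <- c(ramp_up, rep(a, e$apex), ramp_dn)
        idx <- e$start:(e$start + length(vals) - 1L)
        prof[idx] <<- vals
        tibble(au = au, start_frame = e$start - 1L,
               end_frame = e$start - 1L + length(vals), apex = a)
      })
      episodes <- if (length(rows)) {
        dplyr::arrange(dplyr::bind_rows(rows), .data$start_frame)
      } else {
        tibble(au = character(), start_frame = integer(),
               end_frame = integer(), apex = numeric())
      }

      h <- (log((1 - prof) / prof) - ab[["B"]]) / ab[["A"]]
      if (p$score_noise_sd > 0) {
        h <- h + rnorm(n_frames, 0, p$score_noise_sd)
      }
      list(scores = tibble(frame = seq_len(n_frames) - 1L, au = au, score = h),
           episodes = episodes)
    })

    list(
      scores = dplyr::bind_rows(lapply(per_au, `[[`, "scores")),
      truth = list(
        episodes = dplyr::bind_rows(lapply(per_au, `[[`, "episodes")),
        group_label = p$group_label,
        role = role,
        calib = ab,
        frame_rate = frame_rate,
        n_frames = n_frames,
        seed = seed
      )
    )
  })
}
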