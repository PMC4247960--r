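# Per-window expressivity statistics: displayed AUs, AI, AMC, FE, EFE, and
# the four-way "disgust" AU co-occurrence count.

# Per-AU activity summary: active-frame count N', mean smoothed intensity over
# active frames, and the movement-change sum over consecutive active frames.
au_activity_summary <- function(intensity, within_runs = TRUE) {
  stopifnot(is.data.frame(intensity))
  need <- c("au", "frame", "smoothed", "active")
  if (!all(need %in% names(intensity))) {
    abort("`intensity` must have columns au, frame, smoothed, active (see au_intensity()).")
  }
  ord <- order(intensity$au, intensity$frame)
  au <- intensity$au[ord]
  sm <- intensity$smoothed[ord]
  act <- intensity$active[ord]
  idx_by_au <- split(seq_along(au), factor(au, levels = unique(au)))
  rows <- lapply(idx_by_au, function(idx) {
    a <- act[idx]
    s <- sm[idx]
    n_act <- sum(a)
    c(n_active = n_act,
      mean_active = if (n_act > 0) mean(s[a]) else NA_real_,
      change_sum = amc_change_sum(s, a, within_runs))
  })
  m <- do.call(rbind, rows)
  tibble(au = names(idx_by_au),
         n_active = as.integer(m[, "n_active"]),
         mean_active = m[, "mean_active"],
         change_sum = m[, "change_sum"])
}

# Sum over active frames t of |I~_t - I~_{t+1}|. By default only pairs within
# a contiguous active run contribute; with within_runs = FALSE every active
# frame that has a successor frame contributes (the literal reading).
amc_change_sum <- function(smoothed, active, within_runs = TRUE) {
  idx <- which(active)
  if (length(idx) < 1L) return(0)
  n <- length(smoothed)
  if (within_runs) {
    pair <- idx[c(diff(idx) == 1L, FALSE)]
  } else {
    pair <- idx[idx < n]
  }
  if (length(pair) == 0L) return(0)
  sum(abs(smoothed[pair] - smoothed[pair + 1L]))
}

#' Displayed action units in a stimulus window
#'
#' An AU counts as displayed when it is active on at least
#' `min_active_frames` frames of the window. The size of the returned set is
#' the total facial activity (TFA).
#'
#' @param intensity Per-frame intensity tibble from [au_intensity()].
#' @param min_active_frames Minimum active-frame count (>= 1).
#' @return Character vector of displayed AU names (sorted as in the input).
#' @export
displayed_aus <- function(intensity, min_active_frames = 1L) {
  assert_number(min_active_frames, "min_active_frames", lower = 1)
  s <- au_activity_summary(intensity)
  s$au[s$n_active >= min_active_frames]
}

#' Intensity of displayed AUs (AI)
#'
#' Sum over displayed AUs of the mean smoothed intensity over that AU's
#' active frames: `AI = sum_i (1/N_i') sum_{t in T_i} I~_t(AU_i)`.
#'
#' @inheritParams displayed_aus
#' @param daus Displayed-AU set; computed via [displayed_aus()] when `NULL`.
#' @return Non-negative scalar; 0 for an empty displayed set.
#' @export
ai <- function(intensity, daus = NULL, min_active_frames = 1L) {
  if (is.null(daus)) daus <- displayed_aus(intensity, min_active_frames)
  if (length(daus) == 0L) return(0)
  s <- au_activity_summary(intensity)
  s <- s[s$au %in% daus, ]
  if (any(s$n_active == 0L) || length(setdiff(daus, s$au)) > 0L) {
    abort("Every displayed AU must have at least one active frame.")
  }
  sum(s$mean_active)
}

#' Amount of movement change (AMC)
#'
#' Sum over displayed AUs of the mean absolute first difference of the
#' smoothed intensity over that AU's active frames:
#' `AMC = sum_i (1/N_i') sum_{t in T_i} |I~_t - I~_{t+1}|`. The absolute
#' value is essential: the signed telescoping sum would collapse to a
#' boundary difference and measure no movement. By default, differences are
#' taken only between consecutive frames inside the same active run; set
#' `within_runs = FALSE` for the literal all-active-frames variant.
#'
#' @inheritParams ai
#' @param within_runs Restrict first differences to contiguous active runs.
#' @return Non-negative scalar; 0 for an empty displayed set.
#' @export
amc <- function(intensity, daus = NULL, min_active_frames = 1L,
                within_runs = TRUE) {
  if (is.null(daus)) daus <- displayed_aus(intensity, min_active_frames)
  if (length(daus) == 0L) return(0)
  s <- au_activity_summary(intensity, within_runs = within_runs)
  s <- s[s$au %in% daus, ]
  if (any(s$n_active == 0L) || length(setdiff(daus, s$au)) > 0L) {
    abort("Every displayed AU must have at least one active frame.")
  }
  sum(s$change_sum / s$n_active)
}

#' Facial expressivity without baseline correction (FE)
#'
#' `FE = AMC_e + AI_e`, the movement-change and intensity statistics of the
#' emotional (disgust) window alone.
#'
#' @param amc_e,ai_e Emotional-window AMC and AI (non-negative).
#' @return `amc_e + ai_e`.
#' @export
fe <- function(amc_e, ai_e) {
  stopifnot(all(amc_e >= 0), all(ai_e >= 0))
  amc_e + ai_e
}

#' Baseline-corrected facial expressivity (EFE)
#'
#' `EFE = (AMC_e + AI_e) - (AMC_n + AI_n)`: the emotional-window expressivity
#' minus the same statistic over the neutral window. Persistent activity in
#' the neutral state (failure to relax the facial muscles) therefore lowers
#' EFE even when the emotional response itself looks strong; the value may be
#' negative.
#'
#' @param amc_e,ai_e Emotional-window AMC and AI.
#' @param amc_n,ai_n Neutral-window AMC and AI.
#' @return `(amc_e + ai_e) - (amc_n + ai_n)`.
#' @export
efe <- function(amc_e, ai_e, amc_n, ai_n) {
  stopifnot(all(amc_e >= 0), all(ai_e >= 0), all(amc_n >= 0), all(ai_n >= 0))
  (amc_e + ai_e) - (amc_n + ai_n)
}

#' Frames showing the canonical disgust AU combination
#'
#' Counts the frames on which the brow lowerer (AU4), cheek raiser (AU6),
#' lid tightener (AU7) and nose wrinkler (AU9) are simultaneously active —
#' the AU pattern expected during a felt disgust expression.
#'
#' @inheritParams displayed_aus
#' @return Integer frame count.
#' @export
disgust_pattern_frames <- function(intensity) {
  need <- c("AU4", "AU6", "AU7", "AU9")
  have <- unique(intensity$au)
  if (!all(need %in% have)) {
    abort(sprintf("Missing required AU series: %s.",
                  paste(setdiff(need, have), collapse = ", ")))
  }
  masks <- lapply(need, function(a) {
    d <- intensity[intensity$au == a, ]
    d$active[order(d$frame)]
  })
  if (length(unique(lengths(masks))) != 1L) {
    abort("All four disgust AU series must cover the same frames.")
  }
  sum(masks[[1L]] & masks[[2L]] & masks[[3L]] & masks[[4L]])
}

#' Per-window expressivity metrics
#'
#' Computes the displayed-AU set, TFA, AMC, AI and the disgust-pattern frame
#' count for one subject-by-stimulus window.
#'
#' @inheritParams amc
#' @return One-row tibble: `tfa`, `amc`, `ai`, `disgust_frames` (`NA` when
#'   the four disgust AUs are not all scored), `n_frames`, and the displayed
#'   set as a list column `daus`.
#' @export
window_metrics <- function(intensity, min_active_frames = 1L,
                           within_runs = TRUE) {
  assert_number(min_active_frames, "min_active_frames", lower = 1)
  s <- au_activity_summary(intensity, within_runs = within_runs)
  disp <- s$n_active >= min_active_frames
  daus <- s$au[disp]
  dis <- if (all(c("AU4", "AU6", "AU7", "AU9") %in% s$au)) {
    disgust_pattern_frames(intensity)
  } else {
    NA_integer_
  }
  tibble(
    tfa = length(daus),
    amc = if (any(disp)) sum(s$change_sum[disp] / s$n_active[disp]) else 0,
    ai = if (any(disp)) sum(s$mean_active[disp]) else 0,
    disgust_frames = dis,
    n_frames = length(unique(intensity$frame)),
    daus = list(daus)
  )
}

#' Expressivity contrast between an emotional and a neutral window
#'
#' @param emotion,neutral Per-frame intensity tibbles (see [au_intensity()])
#'   for the emotional and neutral windows of one subject.
#' @inheritParams amc
#' @return One-row tibble: `amc_e`, `ai_e`, `amc_n`, `ai_n`, `fe`, `efe`.
#' @export
expressivity_scores <- function(emotion, neutral, min_active_frames = 1L,
                                within_runs = TRUE) {
  me <- window_metrics(emotion, min_active_frames, within_runs)
  mn <- window_metrics(neutral, min_active_frames, within_runs)
  tibble(
    amc_e = me$amc, ai_e = me$ai,
    amc_n = mn$amc, ai_n = mn$ai,
    fe = fe(me$amc, me$ai),
    efe = efe(me$amc, me$ai, mn$amc, mn$ai)
  )
}
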