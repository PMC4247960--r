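#' Gaussian smoothing of a per-frame intensity series
#'
#' Discrete Gaussian convolution with reflective boundary handling; the kernel
#' is truncated at four standard deviations and renormalized, so constants are
#' preserved exactly. Output is clipped to `[0, 1]` (a no-op for inputs
#' already in the unit interval).
#'
#' @param x Numeric vector of per-frame intensities.
#' @param sigma_frames Kernel standard deviation in frames (> 0). As
#'   `sigma_frames` approaches zero the kernel collapses to a delta and the
#'   series is returned unchanged.
#' @return Numeric vector, same length as `x`.
#' @export
#' @examples
#' smooth_intensity(c(0, 0, 1, 0, 0), sigma_frames = 1)
smooth_intensity <- function(x, sigma_frames = 3) {
  if (length(x) == 0L) abort("`x` must be a non-empty numeric series.")
  if (!is.numeric(x) || any(!is.finite(x))) abort("`x` must be finite numeric.")
  assert_number(sigma_frames, "sigma_frames")
  if (sigma_frames <= 0) abort("`sigma_frames` must be > 0.")
  n <- length(x)
  r <- max(1L, as.integer(ceiling(4 * sigma_frames)))
  k <- dnorm(seq(-r, r), sd = sigma_frames)
  k <- k / sum(k)
  xp <- x[mirror_index(seq.int(1L - r, n + r), n)]
  out <- stats::convolve(xp, k, type = "filter")
  pmin(pmax(out, 0), 1)
}

#' Active-frame detection on a smoothed intensity series
#'
#' A frame is active when its smoothed intensity reaches the activation
#' threshold (inclusive: a series sitting exactly at the threshold is active
#' everywhere). The default threshold 0.5 is the natural decision boundary of
#' the calibrated classifier.
#'
#' @param x Numeric vector of smoothed intensities.
#' @param threshold Activation threshold in (0, 1).
#' @return Logical vector marking active frames. The set `T_i` of active
#'   frames (0-based) is `which(mask) - 1L`; its size is the active-frame
#'   count `N_i'`.
#' @export
#' @examples
#' detect_active_frames(c(0.1, 0.6, 0.7, 0.2))
detect_active_frames <- function(x, threshold = 0.5) {
  if (!is.numeric(x)) abort("`x` must be numeric.")
  assert_number(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must lie in (0, 1).")
  x >= threshold
}

#' Temporal phase labels for an intensity series
#'
#' Splits the frames of one AU into activation episodes (maximal runs of
#' active frames) and labels every frame with its temporal phase: inactive
#' frames are `neutral`; within an episode, frames before the apex plateau
#' are `onset`, frames within `plateau_tol` (relative) of the episode maximum
#' around the peak are `apex`, and frames after the plateau are `offset`.
#' A single-frame episode is pure apex.
#'
#' @param x Numeric vector of smoothed intensities.
#' @param active Logical mask, same length as `x` (e.g. from
#'   [detect_active_frames()]).
#' @param plateau_tol Relative tolerance defining the apex plateau (default
#'   5 percent of the episode maximum).
#' @return A tibble with one row per frame: `frame` (0-based), `phase`
#'   (factor `neutral`/`onset`/`apex`/`offset`) and `segment` (episode id,
#'   `NA` for neutral frames). Summarize episodes with
#'   [activation_segments()].
#' @export
segment_phases <- function(x, active, plateau_tol = 0.05) {
  if (length(active) != length(x)) {
    abort("`active` must match the length of `x`.")
  }
  n <- length(x)
  phase <- rep("neutral", n)
  segment <- rep(NA_integer_, n)
  if (any(active)) {
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seg_id <- 0L
    for (j in which(r$values)) {
      seg_id <- seg_id + 1L
      idx <- starts[j]:ends[j]
      vals <- x[idx]
      m <- length(idx)
      i_max <- which.max(vals)
      lim <- max(vals) * (1 - plateau_tol)
      lo <- i_max
      while (lo > 1L && vals[lo - 1L] >= lim) lo <- lo - 1L
      hi <- i_max
      while (hi < m && vals[hi + 1L] >= lim) hi <- hi + 1L
      ph <- rep("apex", m)
      if (lo > 1L) ph[1:(lo - 1L)] <- "onset"
      if (hi < m) ph[(hi + 1L):m] <- "offset"
      phase[idx] <- ph
      segment[idx] <- seg_id
    }
  }
  tibble(
    frame = seq_len(n) - 1L,
    phase = factor(phase, levels = c("neutral", "onset", "apex", "offset")),
    segment = segment
  )
}

#' Summarize activation episodes
#'
#' @param phases Per-frame tibble from [segment_phases()] (optionally with an
#'   `au` column when frames from several AUs are stacked).
#' @return One row per episode: `segment`, `start_frame`, `end_frame`
#'   (half-open, 0-based), `n_frames`, and per-phase frame counts.
#' @export
activation_segments <- function(phases) {
  grp <- intersect(c("au", "segment"), names(phases))
  phases |>
    dplyr::filter(!is.na(.data$segment)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      start_frame = min(.data$frame),
      end_frame = max(.data$frame) + 1L,
      n_frames = dplyr::n(),
      onset_frames = sum(.data$phase == "onset"),
      apex_frames = sum(.data$phase == "apex"),
      offset_frames = sum(.data$phase == "offset"),
      .groups = "drop"
    )
}

#' Calibrate, smooth and segment per-frame AU scores
#'
#' The per-AU front end of the expressivity pipeline: maps raw decision
#' values to probabilities with the Platt sigmoid, smooths each AU's series
#' with a Gaussian kernel, thresholds activity and labels temporal phases.
#'
#' @param scores Long data frame with columns `frame`, `au`, `score` (one row
#'   per frame per AU), e.g. from [read_au_scores()] or
#'   [generate_au_scores()].
#' @param model Platt calibration: a single `facexpr_platt`/`c(A=, B=)`
#'   shared by all AUs, or a named list with one model per AU.
#' @param sigma_frames Gaussian smoothing bandwidth in frames.
#' @param threshold Activation threshold on the smoothed probability.
#' @param plateau_tol Apex plateau tolerance, see [segment_phases()].
#' @param activation Activation rule: `"smoothed"` (default) thresholds the
#'   smoothed probability; `"decision"` uses the binary decision
#'   `sign(score)` directly.
#' @return A tibble with columns `au`, `frame` (0-based), `score`,
#'   `intensity` (raw calibrated probability), `smoothed`, `active`, `phase`,
#'   `segment`.
#' @export
au_intensity <- function(scores, model, sigma_frames = 3, threshold = 0.5,
                         plateau_tol = 0.05,
                         activation = c("smoothed", "decision")) {
  activation <- match.arg(activation)
  stopifnot(is.data.frame(scores))
  need <- c("frame", "au", "score")
  if (!all(need %in% names(scores))) {
    abort("`scores` must have columns frame, au, score.")
  }
  per_au_model <- is.list(model) && !inherits(model, "facexpr_platt") &&
    !all(c("A", "B") %in% names(model))
  ord <- order(scores$au, scores$frame)
  au <- scores$au[ord]
  frame <- scores$frame[ord]
  score <- scores$score[ord]
  idx_by_au <- split(seq_along(au), factor(au, levels = unique(au)))
  parts <- lapply(idx_by_au, function(idx) {
    this_au <- au[idx[1L]]
    m <- if (per_au_model) {
      mm <- model[[this_au]]
      if (is.null(mm)) abort(sprintf("No Platt model supplied for %s.", this_au))
      mm
    } else {
      model
    }
    p <- platt_probability(m, score[idx])
    sm <- smooth_intensity(p, sigma_frames)
    act <- if (activation == "smoothed") {
      detect_active_frames(sm, threshold)
    } else {
      hard_decision(score[idx]) == 1L
    }
    ph <- segment_phases(sm, act, plateau_tol)
    list(intensity = p, smoothed = sm, active = act,
         phase = ph$phase, segment = ph$segment)
  })
  tibble(
    au = au, frame = frame, score = score,
    intensity = unlist(lapply(parts, `[[`, "intensity"), use.names = FALSE),
    smoothed = unlist(lapply(parts, `[[`, "smoothed"), use.names = FALSE),
    active = unlist(lapply(parts, `[[`, "active"), use.names = FALSE),
    phase = factor(
      unlist(lapply(parts, function(q) as.character(q$phase)),
             use.names = FALSE),
      levels = c("neutral", "onset", "apex", "offset")),
    segment = unlist(lapply(parts, `[[`, "segment"), use.names = FALSE)
  )
}
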