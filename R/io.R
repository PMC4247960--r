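# Readers and writers for the on-disk cohort interchange formats: wide
# per-window AU score CSVs, two-column signal CSVs, calibration tables and
# the YAML cohort manifest.

#' Read a per-window AU score CSV
#'
#' Expects the wide layout `frame_index` followed by one column per AU name,
#' one row per video frame.
#'
#' @param path CSV file path.
#' @return Long tibble with columns `frame` (0-based), `au`, `score`.
#' @export
read_au_scores <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"frame_index" %in% names(wide)) {
    abort(sprintf("%s: expected a frame_index column.", path))
  }
  wide |>
    tidyr::pivot_longer(-"frame_index", names_to = "au",
                        values_to = "score") |>
    dplyr::transmute(frame = as.integer(.data$frame_index),
                     au = .data$au, score = .data$score) |>
    dplyr::arrange(.data$au, .data$frame)
}

#' Write a per-window AU score CSV
#'
#' @param scores Long tibble (`frame`, `au`, `score`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_au_scores <- function(scores, path) {
  scores |>
    dplyr::select("frame", "au", "score") |>
    tidyr::pivot_wider(names_from = "au", values_from = "score") |>
    dplyr::rename(frame_index = "frame") |>
    readr::write_csv(path, progress = FALSE)
  invisible(path)
}

#' Read a two-column signal CSV
#'
#' @param path CSV with columns `time_s`, `value`.
#' @return Tibble with those columns.
#' @export
read_signal <- function(path) {
  sig <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_s", "value") %in% names(sig))) {
    abort(sprintf("%s: expected columns time_s, value.", path))
  }
  sig[c("time_s", "value")]
}

#' @rdname read_signal
#' @param signal Tibble with `time_s` and `value` columns.
#' @export
write_signal <- function(signal, path) {
  readr::write_csv(signal[c("time_s", "value")], path, progress = FALSE)
  invisible(path)
}

#' Read a Platt calibration table
#'
#' @param path CSV with columns `h` (decision value) and `y` (label, +1/-1).
#' @return Tibble with columns `score`, `label`, ready for [fit_platt()].
#' @export
read_calibration_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("h", "y") %in% names(d))) {
    abort(sprintf("%s: expected columns h, y.", path))
  }
  tibble(score = d$h, label = d$y)
}

#' Read a cohort manifest
#'
#' Parses the YAML manifest written by [generate_cohort()] (or assembled by
#' hand for real recordings): cohort-level rates and calibration, the subject
#' table with group labels, and one entry per subject-by-stimulus window with
#' relative file paths.
#'
#' @param path Manifest YAML path.
#' @return List with `info` (rates, calibration, seed), `subjects` tibble
#'   (`subject`, `group`) and `windows` tibble (`subject`, `group`,
#'   `stimulus`, `seed` and resolved file-path columns, `NA` when a modality
#'   is absent).
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("Manifest not found: %s", path))
  m <- yaml::read_yaml(path)
  if (is.null(m$cohort) || is.null(m$subjects) || is.null(m$windows)) {
    abort(sprintf("%s: manifest must have cohort, subjects and windows blocks.", path))
  }
  root <- dirname(normalizePath(path))
  subjects <- dplyr::bind_rows(lapply(m$subjects, function(s) {
    if (is.null(s$id) || is.null(s$group)) {
      abort(sprintf("%s: subject entry missing id or group.", path))
    }
    tibble(subject = s$id, group = s$group)
  }))
  windows <- dplyr::bind_rows(lapply(seq_along(m$windows), function(i) {
    w <- m$windows[[i]]
    if (is.null(w$subject) || is.null(w$stimulus) || is.null(w$scores)) {
      abort(sprintf("%s: window entry %d missing subject, stimulus or scores.",
                    path, i))
    }
    resolve <- function(p) if (is.null(p)) NA_character_ else file.path(root, p)
    tibble(
      subject = w$subject, stimulus = w$stimulus,
      scores = resolve(w$scores), ecg = resolve(w$ecg),
      emg_lls = resolve(w$emg_lls), emg_oo = resolve(w$emg_oo),
      seed = if (is.null(w$seed)) NA_integer_ else as.integer(w$seed)
    )
  }))
  bad <- setdiff(windows$subject, subjects$subject)
  if (length(bad) > 0L) {
    abort(sprintf("%s: window subject(s) %s not in subject table.",
                  path, paste(unique(bad), collapse = ", ")))
  }
  windows <- dplyr::left_join(windows, subjects, by = "subject") |>
    dplyr::relocate("subject", "group", "stimulus")
  list(info = m$cohort, subjects = subjects, windows = windows, path = path)
}
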