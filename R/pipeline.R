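# Manifest-driven orchestration: calibration -> intensity -> expressivity
# plus the physiological branch per subject-by-window, then group statistics.

#' Trailing thin slice of a timed series
#'
#' Behavioral coding uses the last `window_s` seconds of each record as a
#' representative thin slice; this returns exactly that trailing window.
#'
#' @param x A data frame with a `time_s` column (regular sampling assumed) or
#'   a numeric vector.
#' @param window_s Window length in seconds.
#' @param rate Sampling rate in Hz; required for numeric `x`, inferred from
#'   `time_s` otherwise.
#' @return Same type as `x`, containing the trailing `round(window_s * rate)`
#'   samples; an input exactly one window long is returned unchanged. Errors
#'   if the series is shorter than the window.
#' @export
extract_thin_slice <- function(x, window_s, rate = NULL) {
  assert_number(window_s, "window_s", lower = 1e-9)
  if (is.data.frame(x)) {
    if (!"time_s" %in% names(x)) abort("`x` must have a time_s column.")
    if (is.null(rate)) {
      dt <- median(diff(x$time_s))
      if (!is.finite(dt) || dt <= 0) abort("Cannot infer sampling rate from time_s.")
      rate <- 1 / dt
    }
    n_keep <- as.integer(round(window_s * rate))
    if (n_keep > nrow(x)) {
      abort(sprintf("Series (%d samples) shorter than the %g s window (%d samples).",
                    nrow(x), window_s, n_keep))
    }
    x[(nrow(x) - n_keep + 1L):nrow(x), ]
  } else {
    if (is.null(rate)) abort("`rate` is required for a bare numeric series.")
    n_keep <- as.integer(round(window_s * rate))
    if (n_keep > length(x)) {
      abort(sprintf("Series (%d samples) shorter than the %g s window (%d samples).",
                    length(x), window_s, n_keep))
    }
    x[(length(x) - n_keep + 1L):length(x)]
  }
}

#' Run the expressivity pipeline over a cohort manifest
#'
#' For every manifest window: read the AU score CSV, take the trailing thin
#' slice, calibrate with the Platt sigmoid, smooth, threshold and segment
#' ([au_intensity()]), and compute the window metrics (TFA, AMC, AI,
#' disgust-pattern frames). Per subject, each disgust window is contrasted
#' with that subject's neutral window to obtain FE and EFE; a subject without
#' a neutral window keeps FE but gets `NA` EFE. When ECG/EMG files are
#' present, heart-rate and EMG amplitude features are computed against the
#' same subject's neutral window ([physio_features()]). Every manifest window
#' ends up either in the results or in the `skipped` table with a reason —
#' never silently dropped. Group-level statistics (control-versus-patients
#' rank-sum tests per stimulus, mixed ANOVA and post-hoc stimulus contrasts)
#' are run on the assembled tables when the cohort supports them.
#'
#' @param manifest Manifest path or the result of [read_cohort_manifest()].
#' @param out_dir Optional output directory; when given, the result tables
#'   are written as CSV plus a provenance block (`report.json`).
#' @param platt Calibration override: a `c(A =, B =)` pair, a
#'   `facexpr_platt` fit, or a named per-AU list. Default: the manifest's
#'   calibration block.
#' @param activation_threshold,min_active_frames,sigma_frames,plateau_tol
#'   Intensity-stage settings, see [au_intensity()] and [displayed_aus()].
#' @param window_s Thin-slice length in seconds.
#' @param within_runs AMC differencing rule, see [amc()].
#' @param physio Process ECG/EMG channels when present.
#' @param denoise_ecg Denoise ECG via [emd_denoise()] before peak detection.
#' @param amplitude_threshold Passed to [detect_r_peaks()].
#' @param scale_pct Report AMC/AI/FE/EFE multiplied by 100 (display scaling
#'   only; all internal computation stays in probability units).
#' @param neutral_stimulus Stimulus label serving as the within-subject
#'   baseline.
#' @return A `facexpr_report` list: `metrics` (per window), `expressivity`
#'   (per subject-by-disgust-window, with FE/EFE), `physio`, `skipped`,
#'   `stats`, and the effective `config`.
#' @export
run_pipeline <- function(manifest, out_dir = NULL, platt = NULL,
                         activation_threshold = 0.5, min_active_frames = 1L,
                         sigma_frames = 3, plateau_tol = 0.05,
                         window_s = 30, within_runs = TRUE,
                         physio = TRUE, denoise_ecg = TRUE,
                         amplitude_threshold = NULL, scale_pct = FALSE,
                         neutral_stimulus = "neutral#2") {
  if (is.character(manifest)) manifest <- read_cohort_manifest(manifest)
  info <- manifest$info
  frame_rate <- info$frame_rate %||% 25
  ecg_rate <- info$ecg_rate %||% 512
  emg_rate <- info$emg_rate %||% 2000
  model <- platt %||% c(A = info$calibration$A, B = info$calibration$B)

  wins <- manifest$windows
  skipped <- tibble(subject = character(), stimulus = character(),
                    reason = character())
  skip <- function(sub, stim, why) {
    skipped <<- dplyr::bind_rows(skipped,
                                 tibble(subject = sub, stimulus = stim, reason = why))
  }

  intens <- vector("list", nrow(wins))
  metrics <- vector("list", nrow(wins))
  signals <- vector("list", nrow(wins))
  for (i in seq_len(nrow(wins))) {
    w <- wins[i, ]
    if (is.na(w$scores) || !file.exists(w$scores)) {
      skip(w$subject, w$stimulus, "score file missing")
      next
    }
    res <- tryCatch({
      sc <- read_au_scores(w$scores)
      n_keep <- as.integer(round(window_s * frame_rate))
      sc <- sc |>
        dplyr::group_by(.data$au) |>
        dplyr::group_modify(function(d, key) {
          if (nrow(d) < n_keep) {
            abort(sprintf("window shorter than %g s", window_s))
          }
          tail(d[order(d$frame), ], n_keep)
        }) |>
        dplyr::ungroup()
      ii <- au_intensity(sc, model, sigma_frames = sigma_frames,
                         threshold = activation_threshold,
                         plateau_tol = plateau_tol)
      list(intensity = ii,
           metrics = window_metrics(ii, min_active_frames, within_runs))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skip(w$subject, w$stimulus, res)
      next
    }
    intens[[i]] <- res$intensity
    metrics[[i]] <- dplyr::bind_cols(
      tibble(subject = w$subject, group = w$group, stimulus = w$stimulus),
      res$metrics
    )
    if (physio && !is.na(w$ecg) || physio && !is.na(w$emg_lls)) {
      sigs <- list()
      if (!is.na(w$ecg) && file.exists(w$ecg)) {
        sigs$ecg <- extract_thin_slice(read_signal(w$ecg), window_s,
                                       ecg_rate)$value
        sigs$ecg_rate <- ecg_rate
      }
      emg <- list()
      if (!is.na(w$emg_lls) && file.exists(w$emg_lls)) {
        emg$lls <- extract_thin_slice(read_signal(w$emg_lls), window_s,
                                      emg_rate)$value
      }
      if (!is.na(w$emg_oo) && file.exists(w$emg_oo)) {
        emg$oo <- extract_thin_slice(read_signal(w$emg_oo), window_s,
                                     emg_rate)$value
      }
      if (length(emg)) {
        sigs$emg <- emg
        sigs$emg_rate <- emg_rate
      }
      signals[[i]] <- sigs
    }
  }
  metrics <- dplyr::bind_rows(metrics)

  # expressivity: each disgust window against the subject's neutral window
  expr_rows <- list()
  physio_rows <- list()
  processed <- which(!vapply(intens, is.null, TRUE))
  for (i in processed) {
    w <- wins[i, ]
    if (w$stimulus == neutral_stimulus) next
    j <- which(wins$subject == w$subject &
                 wins$stimulus == neutral_stimulus)
    j <- j[j %in% processed]
    me <- metrics[metrics$subject == w$subject &
                    metrics$stimulus == w$stimulus, ]
    row <- tibble(
      subject = w$subject, group = w$group, stimulus = w$stimulus,
      amc_e = me$amc, ai_e = me$ai,
      amc_n = NA_real_, ai_n = NA_real_,
      fe = fe(me$amc, me$ai), efe = NA_real_
    )
    if (length(j) == 1L) {
      mn <- metrics[metrics$subject == w$subject &
                      metrics$stimulus == neutral_stimulus, ]
      row$amc_n <- mn$amc
      row$ai_n <- mn$ai
      row$efe <- efe(me$amc, me$ai, mn$amc, mn$ai)
      if (!is.null(signals[[i]]) && !is.null(signals[[j]])) {
        pf_row <- tryCatch(
          physio_features(signals[[i]], signals[[j]],
                          denoise = denoise_ecg,
                          amplitude_threshold = amplitude_threshold),
          error = function(e) NULL
        )
        if (!is.null(pf_row)) {
          physio_rows[[length(physio_rows) + 1L]] <- dplyr::bind_cols(
            tibble(subject = w$subject, group = w$group,
                   stimulus = w$stimulus), pf_row
          )
        } else {
          skip(w$subject, w$stimulus, "physiological features failed")
        }
      }
    }
    expr_rows[[length(expr_rows) + 1L]] <- row
  }
  expressivity <- dplyr::bind_rows(expr_rows)
  physio_tbl <- dplyr::bind_rows(physio_rows)

  if (scale_pct && nrow(metrics) > 0L) {
    metrics <- dplyr::mutate(metrics,
                             dplyr::across(c("amc", "ai"), ~ 100 * .x))
    expressivity <- dplyr::mutate(
      expressivity,
      dplyr::across(c("amc_e", "ai_e", "amc_n", "ai_n", "fe", "efe"),
                    ~ 100 * .x))
  }

  stats_out <- cohort_statistics(metrics, physio_tbl)

  config <- list(
    manifest = manifest$path %||% NA_character_,
    activation_threshold = activation_threshold,
    min_active_frames = min_active_frames,
    sigma_frames = sigma_frames, plateau_tol = plateau_tol,
    window_s = window_s, within_runs = within_runs,
    denoise_ecg = denoise_ecg, scale_pct = scale_pct,
    neutral_stimulus = neutral_stimulus,
    platt = as.list(platt_coefs(model)),
    seed = info$seed %||% NA
  )
  report <- structure(
    list(metrics = metrics, expressivity = expressivity,
         physio = physio_tbl, skipped = skipped, stats = stats_out,
         config = config),
    class = "facexpr_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Group statistics over the assembled cohort tables: control-vs-patients
# rank-sum per variable and stimulus, plus mixed ANOVA with post-hoc
# stimulus contrasts where the design allows.
cohort_statistics <- function(metrics, physio_tbl) {
  long <- list()
  if (nrow(metrics) > 0L) {
    long$facial <- metrics |>
      dplyr::select("subject", "group", "stimulus", "tfa", "amc", "ai") |>
      tidyr::pivot_longer(c("tfa", "amc", "ai"), names_to = "variable")
  }
  if (nrow(physio_tbl) > 0L) {
    long$physio <- physio_tbl |>
      tidyr::pivot_longer(-c("subject", "group", "stimulus"),
                          names_to = "variable")
  }
  if (length(long) == 0L) return(list())
  long <- dplyr::bind_rows(long)
  long$pd <- ifelse(long$group == "C", "control", "PD")

  ranksum <- long |>
    dplyr::group_by(.data$variable, .data$stimulus) |>
    dplyr::group_modify(function(d, key) {
      a <- d$value[d$pd == "control"]
      b <- d$value[d$pd == "PD"]
      if (length(a) == 0L || length(b) == 0L) return(tibble())
      rank_sum_test(a, b)
    }) |>
    dplyr::ungroup()

  anova_tbl <- list()
  posthoc_tbl <- list()
  for (v in unique(long$variable)) {
    dv <- long[long$variable == v, ]
    res <- tryCatch(
      suppressWarnings(mixed_anova(dv, value = value, subject = subject,
                                   group = pd, stimulus = stimulus)),
      error = function(e) NULL
    )
    if (!is.null(res)) {
      anova_tbl[[v]] <- dplyr::bind_cols(tibble(variable = v),
                                         generics::tidy(res))
      posthoc_tbl[[v]] <- dplyr::bind_cols(
        tibble(variable = v),
        posthoc_pairwise(dv, value = value, subject = subject,
                         stimulus = stimulus)
      )
    }
  }
  list(
    rank_sum = ranksum,
    anova = dplyr::bind_rows(anova_tbl),
    posthoc = dplyr::bind_rows(posthoc_tbl)
  )
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (is.data.frame(df) && nrow(df) > 0L) {
      df <- dplyr::select(df, -dplyr::any_of("daus"))
      readr::write_csv(df, file.path(out_dir, paste0(name, ".csv")),
                       progress = FALSE)
    }
  }
  wr(report$metrics, "window_metrics")
  wr(report$expressivity, "expressivity")
  wr(report$physio, "physio_features")
  wr(report$skipped, "skipped_windows")
  for (nm in names(report$stats)) wr(report$stats[[nm]], paste0("stats_", nm))
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(report$config, cfg_path)
  prov <- list(
    config = report$config,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_windows = nrow(report$metrics),
    n_skipped = nrow(report$skipped),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("facexpr"))
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(prov, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(prov, file.path(out_dir, "report.yaml"))
  }
  invisible(out_dir)
}

#' @export
print.facexpr_report <- function(x, ...) {
  cat(sprintf("facexpr cohort report: %d windows processed, %d skipped\n",
              nrow(x$metrics), nrow(x$skipped)))
  if (nrow(x$expressivity) > 0L) {
    summ <- x$expressivity |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(mean_fe = mean(.data$fe, na.rm = TRUE),
                       mean_efe = mean(.data$efe, na.rm = TRUE),
                       .groups = "drop")
    cat("Group means:\n")
    print(summ)
  }
  if (nrow(x$skipped) > 0L) {
    cat("Skipped windows:\n")
    print(x$skipped)
  }
  invisible(x)
}
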