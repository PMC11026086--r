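#' Expected extraction direction per task and channel
#'
#' The stable value is a stable *maximum* for channels whose pressure rises
#' during a trial and a stable *minimum* for channels whose pressure falls.
#' Knee channels rise when pressed; both back channels fall as the pelvis
#' lifts. The unloaded knee of a unilateral bridge partially unloads, so its
#' pressure falls slightly and it is extracted as a decrease.
#'
#' @param task One of `"BB"`, `"URB"`, `"ULB"`.
#' @return Named character vector over RK, RB, LK, LB with values
#'   `"increase"` or `"decrease"`.
#' @export
extraction_directions <- function(task) {
  task <- match.arg(task, TASKS)
  dir <- c(RK = "increase", RB = "decrease", LK = "increase", LB = "decrease")
  if (task == "URB") dir["LK"] <- "decrease"
  if (task == "ULB") dir["RK"] <- "decrease"
  dir
}

# first index k > from with sign(v[k]) != ref_sign (exact zeros count),
# scanning no further than `to`; NA if none
first_sign_change <- function(v, from, to, ref_sign) {
  if (to <= from) return(NA_integer_)
  idx <- seq.int(from + 1L, to)
  hit <- which(sign(v[idx]) != ref_sign)
  if (length(hit) == 0L) NA_integer_ else idx[hit[1L]]
}

stable_value_row <- function(task, trial, channel, direction,
                             value = NA_real_, t_peak = NA_real_,
                             t_zc = NA_real_, avg_start = NA_real_,
                             avg_end = NA_real_, valid = FALSE,
                             reason = NA_character_) {
  data.frame(
    task = task, trial = trial, channel = channel, direction = direction,
    value_mmHg = value, t_peak_velocity_s = t_peak, t_zero_cross_s = t_zc,
    avg_start_s = avg_start, avg_end_s = avg_end,
    valid = valid, invalid_reason = reason, stringsAsFactors = FALSE
  )
}

#' Extract the stable pressure of one trial
#'
#' Implements the plateau-detection rule used for the bridging tasks:
#' within the first `peak_search_s` seconds after the movement cue, the
#' signed velocity extremum is located (maximum for an increasing channel,
#' minimum for a decreasing one); the first subsequent sample where the
#' velocity changes sign (exact zeros count) marks the end of the movement
#' ramp; after a `delay_s` delay from that zero-crossing, `avg_duration_s`
#' seconds of filtered pressure are averaged to give the stable value.
#'
#' The trial fails — `valid = FALSE` with a reason — when the peak velocity
#' magnitude is below `movement_threshold` (`"no_movement"`), no
#' zero-crossing is found (`"no_zero_crossing"`), or the averaging window
#' does not fit inside the trial's plateau interval or the trace
#' (`"window_truncated"`).
#'
#' @param filtered A low-pass filtered [pressure_trace()] (see
#'   [filter_dualpass()]).
#' @param velocity Its velocity from [compute_velocity()] (same grid).
#' @param window One-row data frame with `task`, `trial`, `cue_onset_s`,
#'   `ramp_duration_s`, `hold_duration_s` (a row of a session's `windows`).
#' @param direction `"increase"` or `"decrease"`; see
#'   [extraction_directions()].
#' @param movement_threshold Minimum |peak velocity| in mmHg/s for the trial
#'   to count as movement. Default 1.
#' @param peak_search_s Length of the peak-velocity search window after the
#'   cue (s). Default 2.
#' @param delay_s Delay between zero-crossing and averaging window (s).
#'   Default 1.
#' @param avg_duration_s Length of the averaging window (s). Default 4.
#' @param zc_search_limit_s Optional limit (s after the peak) on the
#'   zero-crossing search; `NULL` (default) searches to the end of the
#'   plateau.
#' @return One-row data frame: `task`, `trial`, `channel`, `direction`,
#'   `value_mmHg`, `t_peak_velocity_s`, `t_zero_cross_s`, `avg_start_s`,
#'   `avg_end_s`, `valid`, `invalid_reason`.
#' @export
extract_stable_value <- function(filtered, velocity, window, direction,
                                 movement_threshold = 1,
                                 peak_search_s = 2,
                                 delay_s = 1,
                                 avg_duration_s = 4,
                                 zc_search_limit_s = NULL) {
  stopifnot(inherits(filtered, "pressure_trace"))
  direction <- match.arg(direction, c("increase", "decrease"))
  t <- trace_times(filtered)
  v <- velocity$values
  p <- filtered$values
  cue <- window$cue_onset_s
  plateau_end <- cue + window$ramp_duration_s + window$hold_duration_s
  out <- function(...) stable_value_row(window$task, window$trial,
                                        filtered$channel, direction, ...)

  search <- which(t >= cue & t <= cue + peak_search_s)
  if (length(search) == 0L) {
    return(out(valid = FALSE, reason = "window_truncated"))
  }
  k_peak <- if (direction == "increase") {
    search[which.max(v[search])]
  } else {
    search[which.min(v[search])]
  }
  v_peak <- v[k_peak]
  if (abs(v_peak) < movement_threshold ||
      (direction == "increase" && v_peak <= 0) ||
      (direction == "decrease" && v_peak >= 0)) {
    return(out(t_peak = t[k_peak], valid = FALSE, reason = "no_movement"))
  }

  zc_end_t <- if (is.null(zc_search_limit_s)) plateau_end else
    min(plateau_end, t[k_peak] + zc_search_limit_s)
  k_last <- max(which(t <= zc_end_t), k_peak)
  k_zc <- first_sign_change(v, k_peak, k_last, sign(v_peak))
  if (is.na(k_zc)) {
    return(out(t_peak = t[k_peak], valid = FALSE, reason = "no_zero_crossing"))
  }
  t_zc <- t[k_zc]

  a0 <- t_zc + delay_s
  a1 <- a0 + avg_duration_s
  if (a1 > plateau_end + 1e-9 || a1 > t[length(t)] + 1e-9) {
    return(out(t_peak = t[k_peak], t_zc = t_zc, valid = FALSE,
               reason = "window_truncated"))
  }
  sel <- which(t >= a0 - 1e-9 & t <= a1 + 1e-9)
  out(value = mean(p[sel]), t_peak = t[k_peak], t_zc = t_zc,
      avg_start = a0, avg_end = a1, valid = TRUE)
}

#' Extract stable values for every trial of a session
#'
#' Filters each channel ([filter_dualpass()]), computes its velocity, and
#' runs [extract_stable_value()] on every trial window with the direction
#' given by [extraction_directions()]. A pre-cue baseline (mean filtered
#' pressure over the `baseline_window_s` seconds before the cue) and the
#' change `delta_mmHg = value - baseline` are attached for compliance
#' checking.
#'
#' @param session A `pressure_session` from [simulate_session()], or a list
#'   with elements `traces` (named list of [pressure_trace()]) and `windows`.
#' @param spec A [filter_spec()].
#' @param baseline_window_s Pre-cue baseline window length (s). Default 2.
#' @param ... Passed to [extract_stable_value()] (thresholds, window
#'   lengths, `zc_search_limit_s`).
#' @return Data frame with one row per trial x channel: the columns of
#'   [extract_stable_value()] plus `session_id`, `baseline_mmHg`,
#'   `delta_mmHg`.
#' @export
extract_session <- function(session, spec = filter_spec(),
                            baseline_window_s = 2, ...) {
  windows <- session$windows
  res <- NULL
  for (ch in names(session$traces)) {
    tr <- session$traces[[ch]]
    f <- filter_dualpass(tr, spec)
    v <- compute_velocity(f)
    t <- trace_times(f)
    for (w in seq_len(nrow(windows))) {
      win <- windows[w, , drop = FALSE]
      dir <- extraction_directions(win$task)[[ch]]
      row <- extract_stable_value(f, v, win, dir, ...)
      bsel <- which(t >= win$cue_onset_s - baseline_window_s & t < win$cue_onset_s)
      row$baseline_mmHg <- if (length(bsel) > 0L) mean(f$values[bsel]) else NA_real_
      row$delta_mmHg <- row$value_mmHg - row$baseline_mmHg
      res <- rbind(res, row)
    }
  }
  res$session_id <- if (!is.null(session$session_id)) session$session_id else NA_character_
  res[, c("session_id", setdiff(names(res), "session_id"))]
}

#' Average stable values over trials
#'
#' Aggregates per-trial stable values to one mean per task x channel cell,
#' using valid trials only, mirroring the study's six-trial averaging.
#' Cells with no valid trial are retained with `value_mmHg = NA` and
#' `missing = TRUE` rather than dropped or zeroed.
#'
#' @param values Data frame of stable values from [extract_session()] (or
#'   with at least `task`, `channel`, `value_mmHg`, `valid`).
#' @return Data frame with columns `task`, `channel`, `value_mmHg` (mean
#'   over valid trials), `sd_mmHg`, `n_valid`, `missing`.
#' @export
summarize_trials <- function(values) {
  stopifnot(all(c("task", "channel", "value_mmHg", "valid") %in% names(values)))
  cells <- unique(values[, c("task", "channel")])
  res <- NULL
  for (i in seq_len(nrow(cells))) {
    sel <- values$task == cells$task[i] & values$channel == cells$channel[i]
    ok <- sel & values$valid
    nv <- sum(ok)
    res <- rbind(res, data.frame(
      task = cells$task[i], channel = cells$channel[i],
      value_mmHg = if (nv > 0L) mean(values$value_mmHg[ok]) else NA_real_,
      sd_mmHg = if (nv > 1L) sd(values$value_mmHg[ok]) else NA_real_,
      n_valid = nv, missing = nv == 0L, stringsAsFactors = FALSE
    ))
  }
  rownames(res) <- NULL
  res
}
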