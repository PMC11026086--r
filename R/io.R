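#' Write a session to a bundle of plain-text files
#'
#' Serialises a session as: `traces.csv` (tidy digital stream: `session_id`,
#' `task`, `trial`, `channel`, `time_s`, `pressure_mmHg`; samples outside
#' any trial carry task `"rest"` and trial 0), `analog.csv`, `windows.json`,
#' `config.json`, and — when ground truth is present — `truth.json`.
#'
#' @param session A `pressure_session`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths (the session bundle).
#' @export
write_session_bundle <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    traces = file.path(dir, "traces.csv"),
    analog = file.path(dir, "analog.csv"),
    windows = file.path(dir, "windows.json"),
    config = file.path(dir, "config.json"),
    truth = file.path(dir, "truth.json")
  )
  w <- session$windows
  traces <- do.call(rbind, lapply(session$traces, function(tr) {
    df <- as.data.frame(tr)
    df$session_id <- session$session_id
    # label each sample with the trial whose span contains it
    df$task <- "rest"
    df$trial <- 0L
    for (i in seq_len(nrow(w))) {
      span <- df$time_s >= w$cue_onset_s[i] &
        df$time_s <= w$cue_onset_s[i] + 2 * w$ramp_duration_s[i] + w$hold_duration_s[i]
      df$task[span] <- w$task[i]
      df$trial[span] <- w$trial[i]
    }
    df[, c("session_id", "task", "trial", "channel", "time_s", "pressure_mmHg")]
  }))
  write.csv(traces, paths$traces, row.names = FALSE)
  a <- session$analog
  if (!"session_id" %in% names(a)) {
    a <- cbind(data.frame(session_id = session$session_id, stringsAsFactors = FALSE), a)
  }
  write.csv(a, paths$analog, row.names = FALSE)
  jsonlite::write_json(
    list(session_id = session$session_id, windows = w,
         sampling_rate_hz = session$config$digital_rate_hz,
         schema_version = 1L),
    paths$windows, auto_unbox = TRUE, digits = NA
  )
  cfg <- session$config
  cfg$task_delta_mmHg <- as.data.frame(cfg$task_delta_mmHg)
  jsonlite::write_json(unclass(cfg), paths$config, auto_unbox = TRUE, digits = NA)
  if (!is.null(session$truth)) {
    jsonlite::write_json(session$truth, paths$truth, auto_unbox = TRUE, digits = NA)
  } else {
    paths$truth <- NULL
  }
  invisible(paths)
}

#' Read pressure traces and trial windows from a session bundle
#'
#' Parses and validates a tidy trace CSV plus its windows JSON: required
#' columns present, channel and task labels known, per-channel timestamps
#' uniform to 1 part in 1000 of the sampling interval. Parse errors name
#' the offending row.
#'
#' @param traces_path Path to a tidy trace CSV with columns `session_id`,
#'   `task`, `trial`, `channel`, `time_s`, `pressure_mmHg`.
#' @param windows_path Path to the matching windows JSON.
#' @return A list shaped like a session: `traces` (named [pressure_trace()]
#'   list), `windows`, `session_id`.
#' @export
read_traces <- function(traces_path, windows_path) {
  df <- read.csv(traces_path, stringsAsFactors = FALSE)
  need <- c("session_id", "task", "trial", "channel", "time_s", "pressure_mmHg")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("trace CSV is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  bad_ch <- which(!df$channel %in% CHANNELS)
  if (length(bad_ch) > 0L) {
    stop(sprintf("unknown channel '%s' in trace CSV row %d",
                 df$channel[bad_ch[1]], bad_ch[1]), call. = FALSE)
  }
  bad_tk <- which(!df$task %in% c(TASKS, "rest"))
  if (length(bad_tk) > 0L) {
    stop(sprintf("unknown task '%s' in trace CSV row %d",
                 df$task[bad_tk[1]], bad_tk[1]), call. = FALSE)
  }
  wmeta <- jsonlite::read_json(windows_path, simplifyVector = TRUE)
  fs <- wmeta$sampling_rate_hz
  windows <- as.data.frame(wmeta$windows)
  traces <- list()
  for (ch in unique(df$channel)) {
    sub <- df[df$channel == ch, ]
    sub <- sub[order(sub$time_s), ]
    dt <- diff(sub$time_s)
    step <- 1 / fs
    off <- which(abs(dt - step) > step / 1000)
    if (length(off) > 0L) {
      stop(sprintf(
        "non-uniform sampling for channel %s near time %.4f s (interval %.5f s, expected %.5f s)",
        ch, sub$time_s[off[1]], dt[off[1]], step
      ), call. = FALSE)
    }
    traces[[ch]] <- pressure_trace(sub$pressure_mmHg, fs = fs, channel = ch,
                                   t0 = sub$time_s[1])
  }
  list(traces = traces, windows = windows, session_id = df$session_id[1])
}

#' Read analog gauge readings
#'
#' @param path CSV with columns `session_id`, `task`, `trial`, `channel`,
#'   `analog_mmHg`.
#' @return Validated data frame.
#' @export
read_analog <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("session_id", "task", "trial", "channel", "analog_mmHg")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("analog CSV is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(!df$channel %in% CHANNELS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown channel '%s' in analog CSV row %d",
                 df$channel[bad[1]], bad[1]), call. = FALSE)
  }
  df
}

#' Read a full session bundle
#'
#' @param dir Directory written by [write_session_bundle()].
#' @return A list shaped like a session, with `analog` and (if present)
#'   `truth` attached.
#' @export
read_session_bundle <- function(dir) {
  s <- read_traces(file.path(dir, "traces.csv"), file.path(dir, "windows.json"))
  s$analog <- read_analog(file.path(dir, "analog.csv"))
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    s$truth <- as.data.frame(jsonlite::read_json(truth_path, simplifyVector = TRUE))
  }
  cfg_path <- file.path(dir, "config.json")
  if (file.exists(cfg_path)) {
    s$config <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  }
  s
}
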