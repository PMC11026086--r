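#' Expected pressure-direction pattern of a bridging task
#'
#' In a bilateral bridge both knees press into the foam roll (pressure
#' rises) while both back channels unload (pressure falls). In a unilateral
#' bridge only the instructed knee may rise; the opposite knee must not
#' increase, and both back channels still fall.
#'
#' @param task One of `"BB"`, `"URB"`, `"ULB"`.
#' @return Named character vector over RK, RB, LK, LB with values
#'   `"increase"`, `"decrease"`, or `"no_increase"`.
#' @examples
#' expected_pattern("URB")
#' @export
expected_pattern <- function(task) {
  task <- match.arg(task, TASKS)
  switch(task,
    BB = c(RK = "increase", RB = "decrease", LK = "increase", LB = "decrease"),
    URB = c(RK = "increase", RB = "decrease", LK = "no_increase", LB = "decrease"),
    ULB = c(RK = "no_increase", RB = "decrease", LK = "increase", LB = "decrease")
  )
}

#' Classify one trial's task compliance
#'
#' Compares the per-channel pressure change of a trial (stable value minus
#' pre-cue baseline) against the task's expected direction pattern. An
#' `increase` requirement passes when the change is at least `+threshold`,
#' a `decrease` when it is at most `-threshold`, and `no_increase` when the
#' change stays below `+threshold`. The trial is compliant when every
#' channel passes. A trial with a missing channel delta is *non-assessable*
#' (`assessable = FALSE`, `compliant = NA`), distinct from non-compliant.
#'
#' @param deltas Named numeric vector of pressure changes (mmHg) for RK, RB,
#'   LK, LB; `NA` marks a missing channel.
#' @param task One of `"BB"`, `"URB"`, `"ULB"`.
#' @param threshold_mmHg Direction threshold in mmHg. Default 3, the scale
#'   of digital-analog agreement, so compliance is not asserted on changes
#'   smaller than measurement agreement.
#' @return One-row data frame: `task`, per-channel deltas (`delta_RK`, ...)
#'   and pass flags (`pass_RK`, ...), `assessable`, `compliant`.
#' @examples
#' classify_trial(c(RK = 20, RB = -10, LK = 20, LB = -10), "BB")
#' @export
classify_trial <- function(deltas, task, threshold_mmHg = 3) {
  task <- match.arg(task, TASKS)
  if (!all(CHANNELS %in% names(deltas))) {
    stop("deltas must be named for all four channels RK, RB, LK, LB", call. = FALSE)
  }
  deltas <- deltas[CHANNELS]
  pattern <- expected_pattern(task)
  pass <- vapply(CHANNELS, function(ch) {
    d <- deltas[[ch]]
    if (is.na(d)) return(NA)
    switch(pattern[[ch]],
      increase = d >= threshold_mmHg,
      decrease = d <= -threshold_mmHg,
      no_increase = d < threshold_mmHg
    )
  }, logical(1))
  assessable <- !anyNA(pass)
  res <- data.frame(task = task, stringsAsFactors = FALSE)
  for (ch in CHANNELS) res[[paste0("delta_", ch)]] <- deltas[[ch]]
  for (ch in CHANNELS) res[[paste0("pass_", ch)]] <- pass[[ch]]
  res$assessable <- assessable
  res$compliant <- if (assessable) all(pass) else NA
  res
}

#' Classify every trial of a session
#'
#' Applies [classify_trial()] to each trial of an extracted session, using
#' the `delta_mmHg` column (stable value minus pre-cue baseline) from
#' [extract_session()]. Channels whose extraction failed (`valid = FALSE`)
#' enter as missing, making the trial non-assessable.
#'
#' @param stable Data frame from [extract_session()].
#' @param threshold_mmHg Passed to [classify_trial()]. Default 3.
#' @return Data frame with one row per trial: `session_id`, `trial`, the
#'   [classify_trial()] columns, plus a `summary` attribute with compliant /
#'   non-compliant / non-assessable counts per task.
#' @export
classify_session <- function(stable, threshold_mmHg = 3) {
  trials <- unique(stable[, c("session_id", "task", "trial")])
  res <- NULL
  for (i in seq_len(nrow(trials))) {
    sel <- stable$session_id == trials$session_id[i] &
      stable$task == trials$task[i] & stable$trial == trials$trial[i]
    d <- rep(NA_real_, length(CHANNELS))
    names(d) <- CHANNELS
    sub <- stable[sel & stable$valid, ]
    d[sub$channel] <- sub$delta_mmHg
    row <- classify_trial(d, trials$task[i], threshold_mmHg)
    row <- cbind(data.frame(session_id = trials$session_id[i],
                            trial = trials$trial[i],
                            stringsAsFactors = FALSE), row)
    res <- rbind(res, row)
  }
  tasks_u <- unique(res$task)
  summ <- data.frame(
    task = tasks_u,
    n_trials = vapply(tasks_u, function(tk) sum(res$task == tk), numeric(1)),
    n_compliant = vapply(tasks_u, function(tk)
      sum(res$compliant[res$task == tk], na.rm = TRUE), numeric(1)),
    n_non_assessable = vapply(tasks_u, function(tk)
      sum(!res$assessable[res$task == tk]), numeric(1)),
    stringsAsFactors = FALSE
  )
  attr(res, "summary") <- summ
  res
}
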