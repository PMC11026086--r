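#' Pair digital and analog stable values
#'
#' Aligns per-trial digital stable values with the analog gauge readings by
#' (session, task, trial, channel). At pairing level `"trial"` every valid
#' trial contributes one pair; at level `"participant"` the six trials of a
#' task are first averaged within each session (valid trials only), and one
#' pair per session x task x channel remains.
#'
#' @param stable Data frame from [extract_session()] (rows of several
#'   sessions may be concatenated).
#' @param analog Data frame with `session_id`, `task`, `trial`, `channel`,
#'   `analog_mmHg` (a session's `analog` element, with `session_id` added,
#'   or [session_analog()] output).
#' @param level `"trial"` (default) or `"participant"`.
#' @return Data frame with columns `session_id`, `task`, `trial` (trial
#'   level only), `channel`, `digital_mmHg`, `analog_mmHg`.
#' @export
pair_stable_values <- function(stable, analog, level = c("trial", "participant")) {
  level <- match.arg(level)
  need <- c("session_id", "task", "trial", "channel")
  if (!all(c(need, "analog_mmHg") %in% names(analog))) {
    stop("analog must have columns session_id, task, trial, channel, analog_mmHg",
         call. = FALSE)
  }
  sv <- stable[stable$valid, c(need, "value_mmHg")]
  names(sv)[names(sv) == "value_mmHg"] <- "digital_mmHg"
  pairs <- merge(sv, analog[, c(need, "analog_mmHg")], by = need)
  if (level == "participant") {
    pairs <- aggregate(cbind(digital_mmHg, analog_mmHg) ~ session_id + task + channel,
                       data = pairs, FUN = mean)
  }
  pairs[order(pairs$task, pairs$channel, pairs$session_id), , drop = FALSE]
}

#' Analog readings of one or more sessions, with session ids
#'
#' @param sessions A `pressure_session` or list of them.
#' @return Data frame `session_id`, `task`, `trial`, `channel`, `analog_mmHg`.
#' @export
session_analog <- function(sessions) {
  if (inherits(sessions, "pressure_session")) sessions <- list(sessions)
  do.call(rbind, lapply(sessions, function(s) {
    cbind(data.frame(session_id = s$session_id, stringsAsFactors = FALSE), s$analog)
  }))
}

#' Concurrent-validity report
#'
#' Computes, for every task x channel cell of a paired digital/analog data
#' set: mean and SD per modality; Spearman correlation with 95% confidence
#' interval ([spearman_with_ci()]); and Bland-Altman agreement statistics
#' ([bland_altman()]). Cells whose correlation falls below `min_rho` — the
#' system's acceptability rule — are flagged. Cells with fewer than 4 pairs
#' are retained as missing rather than dropped. No multiplicity correction
#' is applied; the report records the number of cells tested.
#'
#' @param pairs Data frame from [pair_stable_values()].
#' @param min_rho Acceptability threshold on the correlation. Default 0.9.
#' @param ci_method Passed to [spearman_with_ci()].
#' @return Object of class `validity_report`: list with data frames `means`
#'   (task, channel, modality, mean, sd, n), `cells` (per task x channel:
#'   n, rho, ci_low, ci_high, p_value, bias_mmHg, sd_diff_mmHg, loa_low,
#'   loa_high, n_outside_loa, proportional_bias_slope, proportional_bias_p,
#'   flag_low_rho, missing), the `pairing` metadata and `n_tests`.
#' @export
build_validity_report <- function(pairs, min_rho = 0.9,
                                  ci_method = c("fisher", "bootstrap")) {
  ci_method <- match.arg(ci_method)
  need <- c("task", "channel", "digital_mmHg", "analog_mmHg")
  if (!all(need %in% names(pairs))) {
    stop(sprintf("pairs is missing columns: %s",
                 paste(setdiff(need, names(pairs)), collapse = ", ")), call. = FALSE)
  }
  grid <- expand.grid(task = TASKS, channel = CHANNELS,
                      stringsAsFactors = FALSE)
  means <- NULL
  cells <- NULL
  for (i in seq_len(nrow(grid))) {
    tk <- grid$task[i]
    ch <- grid$channel[i]
    sub <- pairs[pairs$task == tk & pairs$channel == ch, ]
    n <- nrow(sub)
    for (mod in c("digital", "analog")) {
      v <- sub[[paste0(mod, "_mmHg")]]
      means <- rbind(means, data.frame(
        task = tk, channel = ch, modality = mod,
        mean_mmHg = if (n > 0) mean(v) else NA_real_,
        sd_mmHg = if (n > 1) sd(v) else NA_real_,
        n = n, stringsAsFactors = FALSE
      ))
    }
    if (n < 4L) {
      cells <- rbind(cells, data.frame(
        task = tk, channel = ch, n = n, rho = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, p_value = NA_real_, bias_mmHg = NA_real_,
        sd_diff_mmHg = NA_real_, loa_low = NA_real_, loa_high = NA_real_,
        n_outside_loa = NA_integer_, proportional_bias_slope = NA_real_,
        proportional_bias_p = NA_real_, flag_low_rho = NA, missing = TRUE,
        stringsAsFactors = FALSE
      ))
      next
    }
    # a degenerate cell (e.g. zero rank variance) is reported, not fatal
    sp <- tryCatch(
      spearman_with_ci(sub$digital_mmHg, sub$analog_mmHg,
                       method = ci_method, label = paste(tk, ch)),
      error = function(e) list(rho = NA_real_, ci_low = NA_real_,
                               ci_high = NA_real_, p_value = NA_real_)
    )
    ba <- bland_altman(sub$digital_mmHg, sub$analog_mmHg)
    cells <- rbind(cells, data.frame(
      task = tk, channel = ch, n = n, rho = sp$rho, ci_low = sp$ci_low,
      ci_high = sp$ci_high, p_value = sp$p_value, bias_mmHg = ba$bias_mmHg,
      sd_diff_mmHg = ba$sd_diff_mmHg, loa_low = ba$loa_low,
      loa_high = ba$loa_high, n_outside_loa = ba$n_outside_loa,
      proportional_bias_slope = ba$proportional_bias_slope,
      proportional_bias_p = ba$proportional_bias_p,
      flag_low_rho = sp$rho < min_rho, missing = FALSE,
      stringsAsFactors = FALSE
    ))
  }
  structure(
    list(means = means, cells = cells, min_rho = min_rho,
         ci_method = ci_method, n_tests = sum(!cells$missing)),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, digits = 3, ...) {
  cat(sprintf("<validity_report> %d task x channel cells (%d with data), CI method: %s\n",
              nrow(x$cells), x$n_tests, x$ci_method))
  cells <- x$cells
  shown <- cells[, c("task", "channel", "n", "rho", "ci_low", "ci_high",
                     "bias_mmHg", "loa_low", "loa_high", "flag_low_rho")]
  num <- vapply(shown, is.numeric, logical(1))
  shown[num] <- lapply(shown[num], round, digits = digits)
  print(shown, row.names = FALSE)
  n_flag <- sum(cells$flag_low_rho, na.rm = TRUE)
  if (n_flag > 0) {
    cat(sprintf("%d cell(s) below the rho >= %.2f acceptability rule\n",
                n_flag, x$min_rho))
  } else {
    cat(sprintf("all assessed cells meet the rho >= %.2f acceptability rule\n",
                x$min_rho))
  }
  cat(sprintf("raw p-values, no multiplicity correction (%d tests)\n", x$n_tests))
  invisible(x)
}
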