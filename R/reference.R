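#' Published mean stable pressures of the four-sensor bridging system
#'
#' Mean and standard deviation of the stable pressures (mmHg) reported in
#' the validation study of the MRI-compatible lumbopelvic pressure system,
#' per bridging task, sensor channel, and readout modality (analog gauge vs.
#' digital sensor), across 23 participants. These values calibrate the
#' default simulator plateaus (see [reference_session_config()]).
#'
#' @return A data frame with columns `task`, `channel`, `modality`
#'   (`"analog"` or `"digital"`), `mean_mmHg`, `sd_mmHg`.
#' @export
reference_pressure_means <- function() {
  g <- expand.grid(
    modality = c("analog", "digital"),
    channel = CHANNELS,
    task = TASKS,
    stringsAsFactors = FALSE
  )[, c("task", "channel", "modality")]
  # column order per row: RK-A, RK-D, RB-A, RB-D, LK-A, LK-D, LB-A, LB-D
  g$mean_mmHg <- c(
    50.55, 50.84, 12.23, 10.60, 48.07, 50.77, 9.70, 9.30,   # BB
    57.43, 57.99, 11.30, 9.46, 40.52, 42.18, 12.10, 11.66,  # URB
    41.02, 40.99, 14.62, 12.94, 54.43, 56.54, 9.22, 8.82    # ULB
  )
  g$sd_mmHg <- c(
    5.39, 5.36, 6.61, 6.64, 5.37, 5.05, 6.33, 6.14,
    6.54, 6.65, 5.51, 5.76, 5.91, 6.36, 6.76, 6.52,
    5.30, 5.72, 7.57, 7.70, 6.80, 6.17, 6.01, 5.97
  )
  g
}

#' Published digital-analog Spearman correlations of the bridging system
#'
#' Spearman rank correlations (with 95% confidence limits) between digital
#' and analog stable pressures reported in the system's validation study,
#' per bridging task and sensor channel. The study's acceptability rule
#' required every correlation to be at least 0.9; the smallest reported
#' value is 0.937.
#'
#' @return A data frame with columns `task`, `channel`, `rho`, `ci_low`,
#'   `ci_high`.
#' @export
reference_validity_correlations <- function() {
  data.frame(
    task = rep(TASKS, each = 4L),
    channel = rep(c("RK", "RB", "LK", "LB"), times = 3L),
    rho = c(
      0.970, 0.962, 0.937, 0.969,
      0.945, 0.974, 0.962, 0.978,
      0.968, 0.983, 0.983, 0.974
    ),
    ci_low = c(
      0.958, 0.946, 0.912, 0.956,
      0.923, 0.963, 0.947, 0.969,
      0.954, 0.976, 0.976, 0.964
    ),
    ci_high = c(
      0.979, 0.973, 0.965, 0.978,
      0.961, 0.981, 0.973, 0.984,
      0.977, 0.988, 0.988, 0.982
    ),
    stringsAsFactors = FALSE
  )
}
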