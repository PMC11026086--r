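#' Simulation configuration for a bridging session
#'
#' Parameters of the synthetic session generator: the resting (pressurised)
#' baseline of each channel, the task-dependent pressure change of each
#' channel, trial timing, the two readout models, and noise sources.
#'
#' The underlying continuous trajectory of each channel is
#' baseline + delta * ramp, where the ramp is a smoothstep sigmoid rising
#' over `ramp_duration_s`, holding at 1 for `hold_duration_s`, and returning
#' over another `ramp_duration_s`, plus an optional integrated random-walk
#' drift. The digital readout samples this trajectory at `digital_rate_hz`
#' with i.i.d. Gaussian sensor noise; the analog readout takes one value per
#' trial — the trajectory averaged over the middle half of the hold, plus
#' Gaussian observer noise, rounded to the nearest multiple of
#' `analog_precision_mmHg` (emulating a trained observer reading a 2 mmHg
#' gauge from video).
#'
#' @param baseline_mmHg Named numeric vector of resting pressures for
#'   channels RK, RB, LK, LB.
#' @param task_delta_mmHg Data frame with columns `task`, `channel`,
#'   `delta_mmHg`: plateau change relative to baseline for every task x
#'   channel cell (positive for a pressed knee, negative for a lifted back,
#'   small negative for the unloaded knee of a unilateral bridge).
#' @param ramp_duration_s Rise/fall time of the movement ramp (s). Default 1.5.
#' @param hold_duration_s Hold time at the plateau (s). Default 10. Holds
#'   shorter than 5 s cannot contain the extraction window (1 s delay +
#'   4 s average); such sessions are generated with a warning flag on the
#'   ground truth.
#' @param n_reps Repetitions per task. Default 6.
#' @param inter_trial_rest_s Rest before each trial cue (s). Default 5.
#' @param digital_rate_hz Digital sampling rate (Hz). Default 28.
#' @param analog_precision_mmHg Gauge precision (mmHg). Default 2.
#' @param analog_rate_hz Video frame rate of the gauge recording (Hz);
#'   metadata only. Default 30.
#' @param noise_sd_mmHg SD of i.i.d. digital sensor noise. Default 0.5.
#' @param drift_sd_mmHg_per_s Random-walk drift scale (mmHg per sqrt-second
#'   rate such that Var(drift at t) = drift_sd^2 * t). Default 0.
#' @param analog_read_sd_mmHg SD of observer noise on the analog reading,
#'   before quantization. Default 1.4.
#' @param rng_seed Integer seed for the session. Default 1.
#' @return An object of class `sim_config`.
#' @seealso [reference_session_config()] for defaults calibrated to the
#'   validation study's digital means, [simulate_session()].
#' @export
sim_config <- function(baseline_mmHg,
                       task_delta_mmHg,
                       ramp_duration_s = 1.5,
                       hold_duration_s = 10,
                       n_reps = 6L,
                       inter_trial_rest_s = 5,
                       digital_rate_hz = 28,
                       analog_precision_mmHg = 2,
                       analog_rate_hz = 30,
                       noise_sd_mmHg = 0.5,
                       drift_sd_mmHg_per_s = 0,
                       analog_read_sd_mmHg = 1.4,
                       rng_seed = 1L) {
  cfg <- structure(
    list(
      baseline_mmHg = baseline_mmHg,
      task_delta_mmHg = task_delta_mmHg,
      ramp_duration_s = ramp_duration_s,
      hold_duration_s = hold_duration_s,
      n_reps = as.integer(n_reps),
      inter_trial_rest_s = inter_trial_rest_s,
      digital_rate_hz = digital_rate_hz,
      analog_precision_mmHg = analog_precision_mmHg,
      analog_rate_hz = analog_rate_hz,
      noise_sd_mmHg = noise_sd_mmHg,
      drift_sd_mmHg_per_s = drift_sd_mmHg_per_s,
      analog_read_sd_mmHg = analog_read_sd_mmHg,
      rng_seed = as.integer(rng_seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!all(CHANNELS %in% names(cfg$baseline_mmHg))) {
    stop("baseline_mmHg must name all four channels RK, RB, LK, LB", call. = FALSE)
  }
  d <- cfg$task_delta_mmHg
  if (!is.data.frame(d) || !all(c("task", "channel", "delta_mmHg") %in% names(d))) {
    stop("task_delta_mmHg must be a data frame with task, channel, delta_mmHg", call. = FALSE)
  }
  need <- expand.grid(task = TASKS, channel = CHANNELS, stringsAsFactors = FALSE)
  have <- paste(d$task, d$channel)
  if (!all(paste(need$task, need$channel) %in% have)) {
    stop("task_delta_mmHg must cover every task x channel cell", call. = FALSE)
  }
  for (fld in c("digital_rate_hz", "analog_rate_hz", "analog_precision_mmHg",
                "ramp_duration_s", "hold_duration_s", "inter_trial_rest_s")) {
    if (!is.numeric(cfg[[fld]]) || length(cfg[[fld]]) != 1L || cfg[[fld]] <= 0) {
      stop(sprintf("'%s' must be a single positive number", fld), call. = FALSE)
    }
  }
  for (fld in c("noise_sd_mmHg", "drift_sd_mmHg_per_s", "analog_read_sd_mmHg")) {
    if (!is.numeric(cfg[[fld]]) || cfg[[fld]] < 0) {
      stop(sprintf("'%s' must be non-negative", fld), call. = FALSE)
    }
  }
  if (cfg$n_reps < 1L) stop("'n_reps' must be at least 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<sim_config> %d reps x %d tasks, %.3g s hold, %.3g s ramp, %.3g s rest\n",
      "  digital %.6g Hz (noise SD %.3g mmHg), analog %.3g mmHg gauge (observer SD %.3g), seed %d\n"
    ),
    x$n_reps, length(TASKS), x$hold_duration_s, x$ramp_duration_s,
    x$inter_trial_rest_s, x$digital_rate_hz, x$noise_sd_mmHg,
    x$analog_precision_mmHg, x$analog_read_sd_mmHg, x$rng_seed
  ))
  invisible(x)
}

#' Session configuration calibrated to the published digital means
#'
#' Builds a [sim_config()] whose noiseless plateaus reproduce the digital
#' mean stable pressures of the system's validation study
#' ([reference_pressure_means()]): e.g. RK reaches 50.84 mmHg in the
#' bilateral bridge and 57.99 mmHg in the unilateral right bridge. Knee
#' channels rest at 44 mmHg (knees resting on the pressurised foam roll) and
#' back channels at 20 mmHg (inflated to support the lumbar curvature), so
#' pressed-knee deltas are positive, back deltas negative, and the unloaded
#' knee of a unilateral bridge carries a small negative delta (partial
#' unloading as the pelvis lifts from one side).
#'
#' @param ... Overrides passed on to [sim_config()] (e.g. `noise_sd_mmHg = 0`,
#'   `rng_seed`).
#' @return A `sim_config`.
#' @examples
#' cfg <- reference_session_config(noise_sd_mmHg = 0, analog_read_sd_mmHg = 0)
#' subset(cfg$task_delta_mmHg, task == "BB")
#' @export
reference_session_config <- function(...) {
  baseline <- c(RK = 44, RB = 20, LK = 44, LB = 20)
  ref <- reference_pressure_means()
  dig <- ref[ref$modality == "digital", c("task", "channel", "mean_mmHg")]
  dig$delta_mmHg <- dig$mean_mmHg - baseline[dig$channel]
  args <- modifyList(
    list(baseline_mmHg = baseline,
         task_delta_mmHg = dig[, c("task", "channel", "delta_mmHg")]),
    list(...)
  )
  do.call(sim_config, args)
}

# Deterministic substream seeds: each channel's noise, drift, and analog
# observer noise get their own seed derived from the session seed, so adding
# or reordering channels never perturbs another channel's realisation.
derive_seed <- function(seed, stream) {
  as.integer((abs(as.numeric(seed)) * 48271 + stream * 104729) %% 2147483647) + 1L
}

# smoothstep activation: 0 before the cue, C1 sigmoid up over the ramp,
# 1 during the hold, C1 sigmoid back down
trial_activation <- function(t, cue, ramp, hold) {
  s <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    u * u * (3 - 2 * u)
  }
  s((t - cue) / ramp) - s((t - (cue + ramp + hold)) / ramp)
}

quantize <- function(x, precision) round(x / precision) * precision

delta_lookup <- function(cfg) {
  d <- cfg$task_delta_mmHg
  m <- matrix(NA_real_, nrow = length(TASKS), ncol = length(CHANNELS),
              dimnames = list(TASKS, CHANNELS))
  for (i in seq_len(nrow(d))) m[d$task[i], d$channel[i]] <- d$delta_mmHg[i]
  m
}

#' Simulate one bridging session
#'
#' Generates a full synthetic session: a continuous underlying pressure
#' trajectory per channel (baseline + smooth ramp to a task-dependent
#' plateau and back per trial + optional drift), rendered through the two
#' readout models — a digital sample stream with sensor noise and one
#' quantized analog gauge reading per trial — together with the trial
#' windows and the ground-truth plateaus implied by the configuration.
#' Identical configuration and seed give bit-identical output.
#'
#' @param config A [sim_config()].
#' @param session_id Identifier stored with the session. Default `"S01"`.
#' @return An object of class `pressure_session`: a list with elements
#'   `traces` (named list of [pressure_trace()], one per channel), `windows`
#'   (data frame: `task`, `trial`, `cue_onset_s`, `ramp_duration_s`,
#'   `hold_duration_s`), `analog` (data frame: `task`, `trial`, `channel`,
#'   `analog_mmHg`), `truth` (data frame: `task`, `trial`, `channel`,
#'   `plateau_mmHg`, `t_move_start_s`, `t_plateau_start_s`,
#'   `t_plateau_end_s`, `hold_sufficient`), `config`, and `session_id`.
#' @examples
#' s <- simulate_session(reference_session_config(rng_seed = 7))
#' s
#' @export
simulate_session <- function(config, session_id = "S01") {
  validate_sim_config(config)
  cfg <- config
  fs <- cfg$digital_rate_hz
  ramp <- cfg$ramp_duration_s
  hold <- cfg$hold_duration_s
  rest <- cfg$inter_trial_rest_s

  # task-blocked layout, cue onsets explicit
  trial_len <- rest + ramp + hold + ramp
  tasks <- rep(TASKS, each = cfg$n_reps)
  trials <- rep(seq_len(cfg$n_reps), times = length(TASKS))
  cues <- rest + (seq_along(tasks) - 1) * trial_len
  windows <- data.frame(
    task = tasks, trial = trials, cue_onset_s = cues,
    ramp_duration_s = ramp, hold_duration_s = hold,
    stringsAsFactors = FALSE
  )

  total_s <- cues[length(cues)] + ramp + hold + ramp + rest
  n <- floor(total_s * fs) + 1L
  t <- (seq_len(n) - 1) / fs

  hold_sufficient <- hold >= 5
  if (!hold_sufficient) {
    warning(sprintf(
      "hold of %.3g s is shorter than the 5 s extraction window (1 s delay + 4 s average); trials will not be extractable",
      hold
    ), call. = FALSE)
  }

  deltas <- delta_lookup(cfg)
  traces <- list()
  analog <- NULL
  truth <- NULL
  for (i in seq_along(CHANNELS)) {
    ch <- CHANNELS[i]
    act_total <- numeric(n)
    plateau_true <- numeric(nrow(windows))
    a_base <- numeric(nrow(windows))
    for (w in seq_len(nrow(windows))) {
      dlt <- deltas[windows$task[w], ch]
      act_total <- act_total + dlt * trial_activation(t, windows$cue_onset_s[w], ramp, hold)
      plateau_true[w] <- cfg$baseline_mmHg[[ch]] + dlt
    }
    traj <- cfg$baseline_mmHg[[ch]] + act_total
    if (cfg$drift_sd_mmHg_per_s > 0) {
      set.seed(derive_seed(cfg$rng_seed, 100L + i))
      traj <- traj + cumsum(rnorm(n, 0, cfg$drift_sd_mmHg_per_s / sqrt(fs)))
    }
    # analog reading: trajectory averaged over the middle half of the hold
    for (w in seq_len(nrow(windows))) {
      h0 <- windows$cue_onset_s[w] + ramp
      sel <- t >= h0 + 0.25 * hold & t <= h0 + 0.75 * hold
      a_base[w] <- mean(traj[sel])
    }
    set.seed(derive_seed(cfg$rng_seed, 200L + i))
    a_read <- a_base + rnorm(nrow(windows), 0, cfg$analog_read_sd_mmHg)
    a_read <- quantize(a_read, cfg$analog_precision_mmHg)

    set.seed(derive_seed(cfg$rng_seed, i))
    digital <- traj + rnorm(n, 0, cfg$noise_sd_mmHg)
    traces[[ch]] <- pressure_trace(digital, fs = fs, channel = ch, t0 = 0)

    analog <- rbind(analog, data.frame(
      task = windows$task, trial = windows$trial, channel = ch,
      analog_mmHg = a_read, stringsAsFactors = FALSE
    ))
    truth <- rbind(truth, data.frame(
      task = windows$task, trial = windows$trial, channel = ch,
      plateau_mmHg = plateau_true,
      t_move_start_s = windows$cue_onset_s,
      t_plateau_start_s = windows$cue_onset_s + ramp,
      t_plateau_end_s = windows$cue_onset_s + ramp + hold,
      hold_sufficient = hold_sufficient,
      stringsAsFactors = FALSE
    ))
  }

  structure(
    list(traces = traces, windows = windows, analog = analog, truth = truth,
         config = cfg, session_id = session_id),
    class = "pressure_session"
  )
}

#' @export
print.pressure_session <- function(x, ...) {
  cat(sprintf(
    "<pressure_session> %s: %d channels x %d samples @ %.6g Hz, %d trials (%d tasks x %d reps)\n",
    x$session_id, length(x$traces), length(x$traces[[1]]$values),
    x$config$digital_rate_hz, nrow(x$windows), length(unique(x$windows$task)),
    x$config$n_reps
  ))
  invisible(x)
}

#' Simulate a cohort of participants
#'
#' Repeats [simulate_session()] for `n_participants` participants, each with
#' individual physiology: per-channel Gaussian baseline offsets (the system
#' is pressurised to each participant's resting posture) and a per-participant,
#' per-channel log-normal effort multiplier on the task deltas (which keeps
#' every delta's sign — back pressure always falls during a bridge). The
#' defaults reproduce between-participant stable-pressure SDs of roughly
#' 5–7 mmHg, the scale reported for this system.
#'
#' @param n_participants Number of participants. Default 23.
#' @param config Base [sim_config()] shared by the cohort. Default
#'   [reference_session_config()].
#' @param between_baseline_sd_mmHg SD of per-participant baseline offsets.
#'   Default 5.
#' @param between_effort_sdlog sdlog of the per-participant x channel effort
#'   multiplier. Default 0.25.
#' @param rng_seed Cohort seed; per-participant session seeds are derived
#'   from it. Default `config$rng_seed`.
#' @return A list of `pressure_session` objects, session ids `"P01"`,
#'   `"P02"`, ...
#' @export
simulate_cohort <- function(n_participants = 23L,
                            config = reference_session_config(),
                            between_baseline_sd_mmHg = 5,
                            between_effort_sdlog = 0.25,
                            rng_seed = config$rng_seed) {
  validate_sim_config(config)
  sessions <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    set.seed(derive_seed(rng_seed, 1000L + p))
    base_off <- rnorm(length(CHANNELS), 0, between_baseline_sd_mmHg)
    names(base_off) <- CHANNELS
    effort <- exp(rnorm(length(CHANNELS), 0, between_effort_sdlog))
    names(effort) <- CHANNELS
    cfg_p <- config
    cfg_p$baseline_mmHg <- config$baseline_mmHg + base_off[names(config$baseline_mmHg)]
    cfg_p$task_delta_mmHg$delta_mmHg <-
      config$task_delta_mmHg$delta_mmHg * effort[config$task_delta_mmHg$channel]
    cfg_p$rng_seed <- derive_seed(rng_seed, 2000L + p)
    sessions[[p]] <- simulate_session(cfg_p, session_id = sprintf("P%02d", p))
  }
  sessions
}
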