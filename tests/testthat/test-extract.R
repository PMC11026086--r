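test_that("a noiseless trial is recovered with correct timing marks", {
  cfg <- flat_config(rk_base = 30, bb_rk_delta = 20,
                     noise_sd_mmHg = 0, analog_read_sd_mmHg = 0)
  s <- simulate_session(cfg)
  st <- extract_session(s)
  row <- st[st$task == "BB" & st$trial == 1 & st$channel == "RK", ]
  w <- s$windows[s$windows$task == "BB" & s$windows$trial == 1, ]
  expect_true(row$valid)
  expect_equal(row$value_mmHg, 50, tolerance = 1e-4)
  # peak velocity mid-ramp, zero-crossing near the ramp end
  expect_gt(row$t_peak_velocity_s, w$cue_onset_s)
  expect_lt(row$t_peak_velocity_s, w$cue_onset_s + w$ramp_duration_s)
  expect_equal(row$t_zero_cross_s, w$cue_onset_s + w$ramp_duration_s, tolerance = 0.5)
  expect_gte(row$t_zero_cross_s, row$t_peak_velocity_s)
  # averaging window: 1 s delay, 4 s duration
  expect_equal(row$avg_start_s, row$t_zero_cross_s + 1)
  expect_equal(row$avg_end_s - row$avg_start_s, 4)
})

test_that("decreasing channels recover their stable minimum", {
  s <- simulate_session(reference_session_config(noise_sd_mmHg = 0))
  st <- extract_session(s)
  lb <- st[st$task == "BB" & st$channel == "LB", ]
  expect_true(all(lb$direction == "decrease"))
  expect_true(all(lb$valid))
  expect_equal(lb$value_mmHg, rep(9.30, 6), tolerance = 1e-3)
})

test_that("a flat trace is rejected as no movement", {
  tr <- pressure_trace(rep(50, 28 * 30), fs = 28, channel = "RK")
  f <- filter_dualpass(tr)
  v <- compute_velocity(f)
  w <- data.frame(task = "BB", trial = 1L, cue_onset_s = 5,
                  ramp_duration_s = 1.5, hold_duration_s = 10)
  res <- extract_stable_value(f, v, w, "increase")
  expect_false(res$valid)
  expect_equal(res$invalid_reason, "no_movement")
})

test_that("monotone drift through the whole trial yields no zero-crossing", {
  t <- (0:(28 * 12)) / 28
  tr <- pressure_trace(30 + 5 * t, fs = 28, channel = "RK")
  f <- filter_dualpass(tr)
  v <- compute_velocity(f)
  w <- data.frame(task = "BB", trial = 1L, cue_onset_s = 1,
                  ramp_duration_s = 1, hold_duration_s = 9)
  res <- extract_stable_value(f, v, w, "increase")
  expect_false(res$valid)
  expect_equal(res$invalid_reason, "no_zero_crossing")
})

test_that("holds too short for the averaging window are flagged truncated", {
  s <- suppressWarnings(simulate_session(reference_session_config(hold_duration_s = 3)))
  st <- extract_session(s)
  expect_false(any(st$valid))
  expect_true(all(st$invalid_reason == "window_truncated"))
})

test_that("extraction is equivariant under constant pressure shifts", {
  cfg <- flat_config(noise_sd_mmHg = 0.3, rng_seed = 17)
  s <- simulate_session(cfg)
  w <- s$windows[5, , drop = FALSE]
  tr <- s$traces$RK
  for (shift in c(-12, 7.5)) {
    f1 <- filter_dualpass(tr)
    tr2 <- tr
    tr2$values <- tr$values + shift
    f2 <- filter_dualpass(tr2)
    r1 <- extract_stable_value(f1, compute_velocity(f1), w, "increase")
    r2 <- extract_stable_value(f2, compute_velocity(f2), w, "increase")
    expect_equal(r2$value_mmHg, r1$value_mmHg + shift, tolerance = 1e-9)
    expect_identical(r2$t_peak_velocity_s, r1$t_peak_velocity_s)
    expect_identical(r2$t_zero_cross_s, r1$t_zero_cross_s)
  }
})

test_that("zero-crossing search matches a brute-force linear scan", {
  brute <- function(v, from, to, ref_sign) {
    k <- from + 1L
    while (k <= to) {
      if (sign(v[k]) != ref_sign) return(k)
      k <- k + 1L
    }
    NA_integer_
  }
  set.seed(99)
  for (case in 1:300) {
    n <- sample(5:2000, 1)
    v <- rnorm(n)
    # sprinkle exact zeros: they count as crossings
    v[sample(n, max(1, n %/% 20))] <- 0
    from <- sample(n - 1L, 1)
    to <- sample(from:n, 1)
    ref <- sample(c(-1, 1), 1)
    expect_identical(bridgepress:::first_sign_change(v, from, to, ref),
                     brute(v, from, to, ref))
  }
})

test_that("an optional limit restricts the zero-crossing search window", {
  # velocity stays positive for 3 s after its peak, then crosses
  fs <- 28
  t <- (0:(fs * 20)) / fs
  p <- 30 + 2 * pmin(t, 5)  # rises 2 mmHg/s for 5 s from t = 0, then flat
  f <- filter_dualpass(pressure_trace(p, fs = fs, channel = "RK"))
  v <- compute_velocity(f)
  w <- data.frame(task = "BB", trial = 1L, cue_onset_s = 0,
                  ramp_duration_s = 1.5, hold_duration_s = 18)
  free <- extract_stable_value(f, v, w, "increase")
  expect_true(free$valid)
  expect_gt(free$t_zero_cross_s, 4.5)
  limited <- extract_stable_value(f, v, w, "increase", zc_search_limit_s = 2)
  expect_false(limited$valid)
  expect_equal(limited$invalid_reason, "no_zero_crossing")
})

test_that("trial summaries average valid trials only and flag empty cells", {
  base <- data.frame(
    task = "BB", channel = "RK", trial = 1:6,
    value_mmHg = rep(50.84, 6), valid = TRUE, stringsAsFactors = FALSE
  )
  s1 <- summarize_trials(base)
  expect_equal(s1$value_mmHg, 50.84)
  expect_equal(s1$n_valid, 6L)

  base$value_mmHg <- c(50, 52, 48, 50, 51, 49)
  expect_equal(summarize_trials(base)$value_mmHg, 50)

  base$valid[3] <- FALSE
  base$value_mmHg[3] <- 999
  s3 <- summarize_trials(base)
  expect_equal(s3$n_valid, 5L)
  expect_equal(s3$value_mmHg, mean(c(50, 52, 50, 51, 49)))

  base$valid <- FALSE
  s4 <- summarize_trials(base)
  expect_true(s4$missing)
  expect_true(is.na(s4$value_mmHg))
})
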