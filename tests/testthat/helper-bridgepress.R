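# least-squares amplitude of a sinusoid at frequency f (interior samples)
fit_amplitude <- function(y, t, f) {
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- coef(lm(y ~ X))
  unname(sqrt(cf[2]^2 + cf[3]^2))
}

# filtered steady-state amplitude of a unit sinusoid through the dual-pass
# filter, measured away from the edges
dualpass_amplitude <- function(f, fs = 28, dur = 30, spec = filter_spec()) {
  t <- (0:(fs * dur)) / fs
  tr <- pressure_trace(sin(2 * pi * f * t), fs = fs, channel = "RK")
  y <- filter_dualpass(tr, spec)$values
  int <- t > 5 & t < dur - 5
  fit_amplitude(y[int], t[int], f)
}

# a small custom config: one baseline/delta layout across all tasks
flat_config <- function(rk_base = 30, bb_rk_delta = 20, ...) {
  base <- c(RK = rk_base, RB = 20, LK = 30, LB = 20)
  grid <- expand.grid(task = c("BB", "URB", "ULB"),
                      channel = c("RK", "RB", "LK", "LB"),
                      stringsAsFactors = FALSE)
  grid$delta_mmHg <- ifelse(grid$channel %in% c("RK", "LK"), 10, -8)
  grid$delta_mmHg[grid$task == "BB" & grid$channel == "RK"] <- bb_rk_delta
  grid$delta_mmHg[grid$task == "URB" & grid$channel == "LK"] <- -2
  grid$delta_mmHg[grid$task == "ULB" & grid$channel == "RK"] <- -2
  sim_config(baseline_mmHg = base, task_delta_mmHg = grid, ...)
}

# join extracted stable values with simulator ground truth
join_truth <- function(stable, sessions) {
  if (inherits(sessions, "pressure_session")) sessions <- list(sessions)
  truth <- do.call(rbind, lapply(sessions, function(s) {
    cbind(data.frame(session_id = s$session_id, stringsAsFactors = FALSE), s$truth)
  }))
  merge(stable, truth, by = c("session_id", "task", "trial", "channel"))
}

# brute-force Spearman for distinct values: 1 - 6*sum(d^2)/(n(n^2-1))
spearman_bruteforce <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# all permutations of 1..n (small n)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (p in sub) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}
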