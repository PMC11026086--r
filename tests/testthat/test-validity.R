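test_that("normality screen separates normal from skewed and degenerate input", {
  set.seed(11)
  expect_true(normality_screen(rnorm(500))$normal)
  set.seed(11)
  expect_false(normality_screen(rexp(500))$normal)
  const <- normality_screen(rep(3.2, 10))
  expect_true(const$degenerate)
  expect_false(const$normal)
  expect_error(normality_screen(c(1, 2, 3)), "at least 4")
})

test_that("rank correlation is exact on monotone and antitone pairs", {
  x <- c(1, 3, 4, 7, 11)
  expect_equal(spearman_with_ci(x, exp(x))$rho, 1)
  expect_equal(spearman_with_ci(x, -x^3)$rho, -1)
  # classic small worked example: rank displacements d = (1, -1, 0)
  expect_equal(bridgepress:::spearman_rho(c(1, 2, 3), c(2, 1, 3)), 0.5)
})

test_that("rank correlation is invariant under strictly monotone transforms", {
  set.seed(5)
  maps <- list(function(z) z, function(z) z^3, function(z) exp(z / 4),
               function(z) atan(z), function(z) 2 * z + 100)
  for (case in 1:50) {
    x <- rnorm(15)
    y <- 0.6 * x + rnorm(15)
    base <- bridgepress:::spearman_rho(x, y)
    f <- maps[[sample(length(maps), 1)]]
    g <- maps[[sample(length(maps), 1)]]
    expect_equal(bridgepress:::spearman_rho(f(x), g(y)), base, tolerance = 1e-12)
  }
})

test_that("preconditions on paired input are enforced with the cell named", {
  expect_error(spearman_with_ci(1:3, 3:1), "at least 4")
  expect_error(spearman_with_ci(1:5, rep(2, 5), label = "BB RK"), "BB RK")
  expect_error(spearman_with_ci(c(1, 2, NA, 4), c(1, 2, 3, 4)), "missing pairs")
  expect_error(spearman_with_ci(1:4, 1:3), "one-to-one")
})

test_that("Fisher-z interval brackets rho and narrows with sample size", {
  set.seed(202)
  # average width over replicates so sampling variation in rho itself
  # cannot mask the 1/sqrt(n - 3) shrinkage
  widths <- vapply(c(10, 40, 160), function(n) {
    mean(vapply(1:30, function(rep) {
      x <- rnorm(n)
      y <- 0.8 * x + 0.6 * rnorm(n)
      r <- spearman_with_ci(x, y)
      expect_lte(r$ci_low, r$rho)
      expect_gte(r$ci_high, r$rho)
      expect_gte(r$ci_low, -1)
      expect_lte(r$ci_high, 1)
      r$ci_high - r$ci_low
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("bootstrap interval is available and brackets the estimate", {
  set.seed(77)
  x <- rnorm(40)
  y <- 0.9 * x + 0.4 * rnorm(40)
  r <- spearman_with_ci(x, y, method = "bootstrap", n_boot = 500)
  expect_equal(r$method, "bootstrap")
  expect_lte(r$ci_low, r$rho)
  expect_gte(r$ci_high, r$rho)
})

test_that("Bland-Altman statistics match their closed forms", {
  # identical pairs: no bias, collapsed limits
  same <- bland_altman(c(50, 52, 48, 51), c(50, 52, 48, 51))
  expect_equal(same$bias_mmHg, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)

  d <- c(1, -1, 2, -2, 0)
  ba <- bland_altman(50 + d, rep(50, 5))
  expect_equal(ba$bias_mmHg, 0)
  expect_equal(ba$sd_diff_mmHg, sqrt(2.5), tolerance = 1e-9)
  expect_equal(ba$loa_high, 3.0990, tolerance = 1e-3)
  expect_equal(ba$loa_low, -3.0990, tolerance = 1e-3)

  # adding a constant to the digital side shifts the bias, not the spread
  set.seed(8)
  dig <- rnorm(30, 50, 5)
  ana <- dig + rnorm(30, 0, 1.5)
  b0 <- bland_altman(dig, ana)
  b1 <- bland_altman(dig + 4, ana)
  expect_equal(b1$bias_mmHg, b0$bias_mmHg + 4)
  expect_equal(b1$sd_diff_mmHg, b0$sd_diff_mmHg, tolerance = 1e-12)
})

test_that("proportional bias is detected when the difference grows with level", {
  set.seed(15)
  m <- runif(80, 20, 60)
  dig <- m + 0.2 * m + rnorm(80, 0, 0.5)
  ba <- bland_altman(dig, m)
  expect_gt(ba$proportional_bias_slope, 0.1)
  expect_lt(ba$proportional_bias_p, 0.01)
})

test_that("correlation power analysis reproduces its design values", {
  expect_identical(required_sample_size(0.9, 0.7, 0.80, 0.05, "one"), 20L)
  expect_identical(required_sample_size(0.9, 0.7, 0.80, 0.05, "two"), 25L)
  expect_gt(required_sample_size(0.9, 0.7, power = 0.90),
            required_sample_size(0.9, 0.7, power = 0.80))
  # larger separation on the Fisher-z scale always needs fewer participants
  n_seq <- vapply(c(0.75, 0.8, 0.85, 0.9), function(r1)
    required_sample_size(r1, 0.7), integer(1))
  expect_true(all(diff(n_seq) < 0))
  expect_error(required_sample_size(0.7, 0.7), "zero effect")
  expect_error(required_sample_size(0.9, 0.7, alpha = 1.2), "alpha")
})

test_that("a noise-free cohort yields a perfect-agreement report", {
  coh <- simulate_cohort(
    5, reference_session_config(noise_sd_mmHg = 0, analog_read_sd_mmHg = 0,
                                analog_precision_mmHg = 1e-9),
    rng_seed = 4
  )
  st <- do.call(rbind, lapply(coh, extract_session))
  # within a participant the six noise-free trials are exact repeats, so
  # pair at participant level, where digital and analog agree exactly
  pairs <- pair_stable_values(st, session_analog(coh), level = "participant")
  rep <- build_validity_report(pairs)
  expect_false(any(rep$cells$missing))
  expect_true(all(abs(rep$cells$bias_mmHg) < 1e-3))
  expect_equal(rep$cells$rho, rep(1, 12), tolerance = 1e-12)
  expect_false(any(rep$cells$flag_low_rho))
})

test_that("reports keep empty cells as missing and validate their input", {
  s <- simulate_session(reference_session_config(rng_seed = 2))
  st <- extract_session(s)
  pairs <- pair_stable_values(st, session_analog(s))
  pairs <- pairs[!(pairs$task == "URB" & pairs$channel == "LB"), ]
  rep <- build_validity_report(pairs)
  cell <- rep$cells[rep$cells$task == "URB" & rep$cells$channel == "LB", ]
  expect_true(cell$missing)
  expect_equal(sum(rep$cells$missing), 1L)
  expect_error(build_validity_report(pairs[, c("task", "channel")]),
               "missing columns.*digital_mmHg")
  expect_error(pair_stable_values(st, st), "analog must have")
})

test_that("participant-level pairing averages the six trials first", {
  coh <- simulate_cohort(6, rng_seed = 14)
  st <- do.call(rbind, lapply(coh, extract_session))
  pt <- pair_stable_values(st, session_analog(coh), level = "participant")
  expect_equal(nrow(pt), 6 * 3 * 4)
  tl <- pair_stable_values(st, session_analog(coh), level = "trial")
  expect_equal(nrow(tl), 6 * 3 * 4 * 6)
  # participant means equal the mean of that participant's trial pairs
  one <- tl[tl$session_id == "P01" & tl$task == "BB" & tl$channel == "RK", ]
  agg <- pt[pt$session_id == "P01" & pt$task == "BB" & pt$channel == "RK", ]
  expect_equal(agg$digital_mmHg, mean(one$digital_mmHg))
  expect_equal(agg$analog_mmHg, mean(one$analog_mmHg))
})
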