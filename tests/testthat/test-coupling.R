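fs <- 1000

test_that("spikes at carrier peaks land in the 90-degree bin with resultant ~1", {
  t <- seq(0, 60, by = 1 / fs)[-1]
  x <- 40 * sin(2 * pi * 12 * t)
  ph <- hilbert_envelope(x)$phase
  # spikes exactly at the oscillation peaks, inside one long spindle window
  pk_times <- (which(diff(sign(diff(x))) < 0) + 1) / fs
  pk_times <- pk_times[pk_times > 10 & pk_times < 50][1:100]
  spin <- data.frame(start_s = 5, end_s = 55)
  res <- spike_phase_histogram(pk_times, ph, fs, spin)
  expect_equal(res$n_spikes, 100L)
  expect_equal(sum(res$counts), 100L)        # conservation
  top_center <- (res$bin_edges_deg[which.max(res$counts)] + 3.6)
  expect_lt(abs(top_center - 90), 10)  # within ~one bin of the peak phase
  expect_gt(res$resultant_length, 0.95)
  expect_lt(res$p_omnibus, 0.001)
})

test_that("uniform spikes show no locking and out-of-spindle spikes are ignored", {
  set.seed(61)
  t <- seq(0, 120, by = 1 / fs)[-1]
  ph <- hilbert_envelope(40 * sin(2 * pi * 12 * t))$phase
  spikes <- sort(runif(2000, 0, 120))
  spin <- data.frame(start_s = c(10, 60), end_s = c(50, 110))
  res <- spike_phase_histogram(spikes, ph, fs, spin)
  in_spin <- sum((spikes >= 10 & spikes < 50) | (spikes >= 60 & spikes < 110))
  expect_equal(res$n_spikes, in_spin)
  expect_equal(sum(res$counts), in_spin)
  expect_lt(res$resultant_length, 0.1)
  expect_gt(res$p_omnibus, 0.05)
  # no in-spindle spikes -> empty result with a notice
  expect_message(
    empty <- spike_phase_histogram(spikes, ph, fs,
                                   data.frame(start_s = numeric(0),
                                              end_s = numeric(0))),
    "no in-spindle")
  expect_equal(empty$n_spikes, 0L)
})

test_that("a bimodal phase injection is flagged by the omnibus test", {
  set.seed(62)
  t <- seq(0, 120, by = 1 / fs)[-1]
  x <- 40 * sin(2 * pi * 12 * t)
  ph <- hilbert_envelope(x)$phase
  deg <- hilbert_envelope(x)$phase_deg
  # sample times whose phase is near 130 or 345 degrees
  cand <- which(t > 5 & t < 115)
  near <- cand[pmin(abs(deg[cand] - 130), abs(deg[cand] - 345)) < 4]
  spikes <- sort(sample(near, 300)) / fs
  res <- spike_phase_histogram(spikes, ph, fs,
                               data.frame(start_s = 5, end_s = 115))
  expect_lt(res$p_omnibus, 0.01)
  # two well-separated histogram peaks
  sm <- stats::filter(res$counts, rep(1 / 3, 3), circular = TRUE)
  top <- order(sm, decreasing = TRUE)
  centers <- (res$bin_edges_deg[-1] + res$bin_edges_deg[-51]) / 2
  expect_lt(min(abs(centers[top[1]] - c(130, 345))), 15)
})

test_that("the Hodges-Ajne p matches the exact closed form and the oracle", {
  set.seed(63)
  # all angles in one quadrant, n = 20: m = 0, p = 20 * C(20,0) * 2^-19
  a <- runif(20, 0, pi / 2)
  expect_equal(hodges_ajne_test(a), 20 * 2^(1 - 20), tolerance = 1e-12)
  # perfectly alternating antipodal pairs: maximal uniformity, p = 1
  expect_equal(hodges_ajne_test(rep(c(0, pi), 10)), 1)
  expect_error(hodges_ajne_test(runif(5)), "at least 10")
  # statistic m agrees with a brute-force half-circle scan for n <= 30
  for (i in 1:20) {
    n <- sample(10:30, 1)
    ang <- runif(n, 0, 2 * pi)
    m_pkg <- axospindle:::.ajne_m(ang %% (2 * pi))
    expect_equal(m_pkg, ajne_m_oracle(ang), info = paste("case", i))
  }
})

test_that("the omnibus test has calibrated type-I error at alpha 0.05", {
  set.seed(64)
  rej <- mean(replicate(1000, hodges_ajne_test(runif(1e4, 0, 2 * pi)) < 0.05))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("phase effect size matches its construction and invariances", {
  flat <- matrix(1 / 50, nrow = 3, ncol = 50)
  expect_equal(phase_effect_size(flat), 0)
  # constructed: pooled max - min = 0.02, across-array SD = 0.2
  m <- matrix(0.5, nrow = 2, ncol = 4)
  m[, 1] <- 0.5 + c(0.21, -0.19)  # pooled 0.51
  m[, 2] <- 0.5 + c(-0.21, 0.19)  # pooled 0.49
  norm <- sweep(m, 1, rowSums(m), "/")
  # rescale construction directly in normalized space via the function
  ps <- colMeans(norm)
  s <- sd(as.vector(norm))
  expect_equal(phase_effect_size(m), (max(ps) - min(ps)) / s)
  # doubling all counts leaves the effect unchanged
  expect_equal(phase_effect_size(m * 2), phase_effect_size(m))
  expect_error(phase_effect_size(matrix(1, 1, 50)), "at least 2")
})

test_that("envelope correlations find the delay, identity, and null cases", {
  set.seed(65)
  fsr <- 1000
  env <- numeric(60 * fsr)
  spin <- data.frame(start_s = c(10, 25, 40), end_s = c(11, 26.2, 41.5))
  t <- (seq_along(env) - 1) / fsr
  for (i in seq_len(nrow(spin))) {
    c0 <- (spin$start_s[i] + spin$end_s[i]) / 2
    env <- env + 50 * exp(-(t - c0)^2 / (2 * 0.2^2))
  }
  # identity
  id <- spindle_envelope_correlation(env, env, spin, spin, fsr)
  expect_equal(id$r, 1, tolerance = 1e-9)
  expect_equal(id$best_lag_s, 0)
  # delayed by 7 ms: peak r at +7 ms, min velocity over 0.82 mm = 0.1 m/s
  lagged <- c(numeric(7), env[1:(length(env) - 7)])
  spinB <- spin; spinB$start_s <- spin$start_s + 0.007; spinB$end_s <- spin$end_s + 0.007
  del <- spindle_envelope_correlation(env, lagged, spin, spinB, fsr)
  expect_gt(del$r, 0.99)
  expect_equal(del$best_lag_s, 0.007)
  expect_equal(signif(0.82 / (del$best_lag_s * 1000), 1), 0.1)
  # independent spindle trains decorrelate
  env2 <- numeric(60 * fsr)
  spin2 <- data.frame(start_s = c(5, 18, 33, 50), end_s = c(6, 19, 34.4, 51))
  for (i in seq_len(nrow(spin2))) {
    c0 <- (spin2$start_s[i] + spin2$end_s[i]) / 2
    env2 <- env2 + 50 * exp(-(t - c0)^2 / (2 * 0.2^2))
  }
  ind <- spindle_envelope_correlation(env, env2, spin, spin2, fsr)
  expect_lt(abs(ind$r), 0.2)
  # symmetry: corr(A,B) at l equals corr(B,A) at -l
  ba <- spindle_envelope_correlation(lagged, env, spinB, spin, fsr)
  expect_equal(ba$best_lag_s, -del$best_lag_s)
  expect_equal(ba$r, del$r, tolerance = 1e-9)
  # all-zero after masking is reported missing
  expect_message(
    z <- spindle_envelope_correlation(env, env2, spin,
                                      data.frame(start_s = numeric(0),
                                                 end_s = numeric(0)),
                                      fsr),
    "all zero")
  expect_true(is.na(z$r))
})

test_that("group comparison: ANOVA power, calibration, and degenerate input", {
  set.seed(66)
  v <- c(rnorm(10, 0.8, 0.05), rnorm(10, 0.3, 0.05))
  g <- rep(c("a", "b"), each = 10)
  res <- correlation_group_compare(v, g)
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 18L)
  expect_equal(nrow(res$tukey), 1L)
  # type-I calibration with 3 equal-mean groups
  ps <- replicate(400, {
    correlation_group_compare(rnorm(30), rep(c("a", "b", "c"), 10))$p_value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
  # identical values: no-variance notice
  expect_message(nv <- correlation_group_compare(rep(1, 12), rep(c("a", "b"), 6)),
                 "no variance")
  expect_true(is.na(nv$F))
  expect_error(correlation_group_compare(1:4, c("a", "a", "a", "b")),
               "degenerate|>= 2")
})
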