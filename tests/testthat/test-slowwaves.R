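fs <- 25000

test_that("troughs of a clean slow wave are found at the analytic minima", {
  t <- seq(0, 10, by = 1 / fs)[-1]
  x <- -400 * sin(2 * pi * 1.5 * t)   # minima where sin peaks
  tr <- detect_slow_troughs(x, fs)
  expect_equal(nrow(tr), 15L)
  truth <- 1 / 6 + (0:14) / 1.5
  expect_lt(max(abs(tr$trough_s - truth)) * 1000, 2)
  expect_true(all(tr$trough_uv <= -100))
})

test_that("narrow spike deflections are rejected by the 4 ms width rule", {
  t <- seq(0, 10, by = 1 / fs)[-1]
  x <- -400 * sin(2 * pi * 1.5 * t)
  # add -800 uV, ~1 ms wide spikes away from the true troughs
  for (tt in seq(0.4, 9.4, by = 1)) {
    i <- round(tt * fs) + seq_len(25)
    x[i] <- x[i] - 800 * sin(pi * seq_len(25) / 25)
  }
  tr <- detect_slow_troughs(x, fs, lowpass_hz = NA)
  truth <- 1 / 6 + (0:14) / 1.5
  # every reported trough is a slow-wave trough, not a spike
  expect_true(all(vapply(tr$trough_s,
                         function(s) min(abs(s - truth)) < 0.01, logical(1))))
})

test_that("the -100 uV floor and 20%-of-max rules suppress weak minima", {
  t <- seq(0, 10, by = 1 / fs)[-1]
  expect_equal(nrow(detect_slow_troughs(-80 * sin(2 * pi * 1.5 * t), fs)), 0L)
  # one dominant trough makes small (-150 uV) ones fail the 20% rule
  x <- -150 * sin(2 * pi * 1.5 * t)
  i <- round(5 * fs) + seq_len(round(0.2 * fs))
  x[i] <- x[i] - 900 * sin(pi * seq_along(i) / length(i))
  tr <- detect_slow_troughs(x, fs)
  expect_true(all(tr$trough_uv <= 0.2 * min(x)))
})

test_that("slow-oscillation epochs keep the top 40% of peaks and troughs", {
  fs1 <- 1000
  # 10 unit cycles scaled 1..10: ranks 7-10 retained (ceiling(0.4*10) = 4)
  xr <- unlist(lapply(1:10, function(k) k * sin(2 * pi * seq(0, 1, by = 1 / fs1)[-1])))
  ep <- detect_so_epochs(xr, fs1, lowpass_hz = NA)
  expect_equal(attr(ep, "n_candidates"), 10L)
  expect_equal(sort(round(ep$peak_uv)), c(7, 8, 9, 10))
  # peak precedes the crossing which precedes the trough
  expect_true(all(ep$peak_s < ep$zero_cross_s & ep$zero_cross_s < ep$trough_s))

  # identical epochs: ties kept, every cycle qualifies
  xs <- rep(sin(2 * pi * seq(0, 1, by = 1 / fs1)[-1]), 12)
  ep2 <- detect_so_epochs(xs, fs1, lowpass_hz = NA)
  expect_equal(nrow(ep2), 12L)
  # trough floor gate
  ep3 <- detect_so_epochs(xr * 30, fs1, lowpass_hz = NA, min_trough_uv = -100)
  expect_true(all(ep3$trough_uv <= -100))
  # fewer than 3 candidates: warning, all retained
  expect_warning(
    ep4 <- detect_so_epochs(sin(2 * pi * seq(0, 2, by = 1 / fs1)[-1]), fs1,
                            lowpass_hz = NA),
    "fewer than 3")
  expect_equal(nrow(ep4), attr(ep4, "n_candidates"))
})

test_that("trough pairing respects the 5 ms cap and reports unmatched minima", {
  a <- seq(1, 100, by = 1.05)
  p <- pair_troughs(a, a + 0.00132)
  expect_equal(length(p$delays_ms), length(a))
  expect_equal(mean(p$delays_ms), 1.32, tolerance = 1e-9)
  expect_equal(length(p$unmatched_up), 0L)

  p2 <- pair_troughs(a, a + 0.008)
  expect_equal(p2$n_pairs, 0L)

  extra <- sort(c(a + 0.001, a[1:20] + 0.45))
  p3 <- pair_troughs(a, extra)
  expect_equal(p3$n_pairs, length(a))
  expect_equal(length(p3$unmatched_down), 20L)

  # order independence
  set.seed(41)
  shuf <- sample(extra)
  p4 <- pair_troughs(a, shuf)
  expect_equal(sort(p4$delays_ms), sort(p3$delays_ms))
})

test_that("delay summaries reproduce the velocity and percent-slower arithmetic", {
  # feedback worked example: 0.35 ms spikes vs 1.32 ms slow waves
  s <- summarize_delays(list(c(0.30, 0.35, 0.40)), list(c(1.22, 1.32, 1.42)))
  expect_equal(s$v_spike_m_s, 0.57)
  expect_equal(s$v_slow_m_s, 0.15)
  expect_equal(s$percent_slower, 74)
  # feed-forward worked example: 0.40 ms vs 0.86 ms
  s2 <- summarize_delays(list(c(0.35, 0.40, 0.45)), list(c(0.76, 0.86, 0.96)))
  expect_equal(s2$v_spike_m_s, 0.5)
  expect_equal(s2$v_slow_m_s, 0.23)
  expect_equal(s2$percent_slower, 54)
  # identical delay sets: 0% slower, t-test p = 1
  d <- list(c(0.4, 0.5, 0.6), c(0.35, 0.5, 0.65))
  s3 <- summarize_delays(d, d)
  expect_equal(s3$percent_slower, 0)
  expect_equal(s3$t_test$p.value, 1)
})

test_that("the delay t-test is significant under the study conditions", {
  set.seed(42)
  spike <- lapply(1:15, function(i) rnorm(30, 0.35, 0.04))
  slow <- lapply(1:15, function(i) rnorm(30, 1.32, 0.3))
  s <- summarize_delays(spike, slow)
  expect_lt(s$t_test$p.value, 1e-4)
  expect_equal(s$v_spike_m_s, 0.57, tolerance = 0.03)
})

test_that("axons with SE above mean or zero SE are excluded", {
  s <- summarize_delays(
    list(c(0.3, 0.4, 0.5), c(-2, 0.4, 2.8)),   # second axon: SE > |mean|
    list(c(1.2, 1.3, 1.4), rep(1.3, 5)))        # second axon: SE == 0
  expect_equal(s$axons_spike$excluded, c(FALSE, TRUE))
  expect_equal(s$axons_spike$reason[2], "se > mean")
  expect_equal(s$axons_slow$excluded, c(FALSE, TRUE))
  expect_equal(s$axons_slow$reason[2], "se == 0")
  # pooled means use only the surviving axons
  expect_equal(s$mean_spike_ms, 0.4, tolerance = 1e-9)
})

test_that("amplitude attenuation test behaves at the degenerate corners", {
  eq <- amplitude_attenuation_test(rep(-500, 5), rep(-500, 5))
  expect_equal(eq$p_value, 1)
  expect_equal(eq$mean_diff_uv, 0)
  # decline with zero variance: overwhelming evidence
  z <- amplitude_attenuation_test(rep(-1420, 9), rep(-832, 9))
  expect_lt(z$p_value, 0.001)
  # high-variance decline (means as in the feedback axons) not significant:
  # per-axon differences spread wide enough that t is ~1 at n = 9
  set.seed(43)
  near <- -1420 + rnorm(9, 0, 1200)
  far <- -832 + rnorm(9, 0, 1200)
  hv <- amplitude_attenuation_test(near, far)
  expect_gt(hv$p_value, 0.05)
})

test_that("slow-wave delays are recovered end to end on the preset", {
  run <- preset_run()
  errs <- sapply(names(run$truth), function(id) {
    ds <- run$pl$delay_summaries[[id]]
    abs(mean(ds$trough_pairs$delays_ms)) - abs(run$truth[[id]]$sw_delay_ms)
  })
  # pooled across the four tunnels the mean delay is within 0.25 ms of truth
  expect_lt(abs(mean(errs)), 0.25)
  # and the sign of every tunnel's mean delay matches its direction
  for (id in names(run$truth)) {
    d <- run$pl$delay_summaries[[id]]$trough_pairs$delays_ms
    expect_equal(sign(mean(d)), sign(run$truth[[id]]$sw_delay_ms))
  }
})
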