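# Shared fixtures, built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

# Full study-condition run: 300 s, 4 tunnels, fixed seed, complete pipeline.
preset_run <- function() {
  if (is.null(.fixtures$preset)) {
    cfg <- preset_paper_like(seed = 42)
    gen <- generate_recording(cfg)
    pl <- suppressMessages(suppressWarnings(run_pipeline(cfg)))
    .fixtures$preset <- list(cfg = cfg, truth = gen$truth, map = gen$channel_map,
                             pl = pl)
  }
  .fixtures$preset
}

# inverse-CDF power-law draws, independent of the package's sampler
rpow_oracle <- function(n, alpha, lo, hi) {
  u <- runif(n)
  e <- 1 - alpha
  (lo^e + u * (hi^e - lo^e))^(1 / e)
}

# 12 Hz tone burst with a Gaussian envelope added in place
add_burst <- function(x, rate_hz, center_s, peak, fwhm_s, freq_hz = 12) {
  t <- (seq_along(x) - 1) / rate_hz
  s <- fwhm_s / 2.355
  idx <- which(abs(t - center_s) < 4 * s)
  x[idx] <- x[idx] +
    peak * exp(-(t[idx] - center_s)^2 / (2 * s^2)) * cos(2 * pi * freq_hz * (t[idx] - center_s))
  x
}

# rectangular 12 Hz tone burst (sharp envelope edges)
add_rect_burst <- function(x, rate_hz, start_s, end_s, amp, freq_hz = 12) {
  t <- (seq_along(x) - 1) / rate_hz
  idx <- which(t >= start_s & t < end_s)
  x[idx] <- x[idx] + amp * sin(2 * pi * freq_hz * (t[idx] - start_s))
  x
}

# overlap-based recall/precision of detected vs true event windows
interval_recovery <- function(det, tru) {
  if (!nrow(tru)) return(c(recall = NA_real_, precision = NA_real_))
  hit <- vapply(seq_len(nrow(tru)), function(i)
    any(det$start_s < tru$end_s[i] & det$end_s > tru$start_s[i]), logical(1))
  fp <- if (nrow(det)) vapply(seq_len(nrow(det)), function(i)
    any(tru$start_s < det$end_s[i] & tru$end_s > det$start_s[i]), logical(1))
  else logical(0)
  c(recall = mean(hit), precision = if (length(fp)) mean(fp) else NA_real_)
}

# brute-force Hodges-Ajne oracle: scan many half-circle orientations
ajne_m_oracle <- function(a, n_dirs = 7200) {
  a <- a %% (2 * pi)
  dirs <- seq(0, 2 * pi, length.out = n_dirs + 1)[-(n_dirs + 1)]
  min(vapply(dirs, function(th) {
    d <- (a - th) %% (2 * pi)
    sum(d < pi)
  }, numeric(1)))
}
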