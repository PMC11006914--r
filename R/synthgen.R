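#' Specification of one synthetic tunnel
#'
#' Describes the event statistics of a single microfluidic tunnel: one axon
#' whose spikes, slow waves and nested spindle bursts appear on both tunnel
#' electrodes with fixed sub-millisecond conduction delays.
#'
#' @param tunnel_id identifier, e.g. "T1".
#' @param source,target compartments of the tunnel in feed-forward
#'   orientation (adjacent pair of EC -> DG -> CA3 -> CA1 -> EC).
#' @param direction conduction direction of the axon: "feedforward" (source
#'   electrode is upstream) or "feedback".
#' @param spike_rate_hz Poisson rate of background spikes.
#' @param spike_amp_uv negative peak amplitude of the biphasic spike
#'   template (uV, < 0).
#' @param spike_delay_ms conduction delay of spikes between the electrodes.
#' @param sw_rate_hz Poisson rate of slow-oscillation events (their
#'   waveform occupies the 0.5-4 Hz band).
#' @param sw_amp_uv median trough amplitude of the slow-wave event (uV, > 0;
#'   the trough reaches about -sw_amp_uv).
#' @param sw_amp_sigma_log10 log10-SD of the per-event slow-wave amplitude.
#' @param sw_delay_ms conduction delay of slow waves (and their nested
#'   spindles).
#' @param spindle_per_min mean spindle count per minute.
#' @param spindle_freq_hz spindle carrier frequency (10-16 Hz band).
#' @param spindle_amp_uv peak envelope amplitude of a spindle burst.
#' @param spindle_amp_sigma_log10 log10-SD of the per-spindle amplitude.
#' @param spindle_dur_mode_s mode (original units) of the log-normal spindle
#'   duration law.
#' @param spindle_dur_sigma_log10 log10-SD of the duration law.
#' @param nesting_alpha,nesting_tmin_s,nesting_tmax_s truncated power-law
#'   `p(t) ~ t^-alpha` on `[tmin, tmax]` for the SO-peak to spindle-peak lag.
#' @param phase_lock_kappa von Mises concentration of spike phases around
#'   the spindle carrier peak (90 degrees); `NA` (default) for no locking.
#' @return list of class `synth_tunnel`.
#' @export
synth_tunnel <- function(tunnel_id, source, target,
                         direction = c("feedforward", "feedback"),
                         spike_rate_hz = 2, spike_amp_uv = -120,
                         spike_delay_ms = 0.4,
                         sw_rate_hz = 0.5, sw_amp_uv = 800,
                         sw_amp_sigma_log10 = 0.12, sw_delay_ms = 0.86,
                         spindle_per_min = 10, spindle_freq_hz = 12,
                         spindle_amp_uv = 60, spindle_amp_sigma_log10 = 0.05,
                         spindle_dur_mode_s = 0.65,
                         spindle_dur_sigma_log10 = 0.15,
                         nesting_alpha = 1.5, nesting_tmin_s = 0.05,
                         nesting_tmax_s = 1.5,
                         phase_lock_kappa = NA_real_) {
  direction <- match.arg(direction)
  pos <- c(spike_rate_hz = spike_rate_hz, sw_rate_hz = sw_rate_hz,
           sw_amp_uv = sw_amp_uv, spindle_per_min = spindle_per_min,
           spindle_freq_hz = spindle_freq_hz, spindle_amp_uv = spindle_amp_uv,
           spindle_dur_mode_s = spindle_dur_mode_s,
           spike_delay_ms = spike_delay_ms, sw_delay_ms = sw_delay_ms,
           nesting_tmin_s = nesting_tmin_s, nesting_tmax_s = nesting_tmax_s)
  if (any(pos < 0)) stop("rates, amplitudes, durations and delays must be non-negative")
  if (spike_amp_uv >= 0) stop("spike_amp_uv must be negative")
  if (spindle_freq_hz < 8 || spindle_freq_hz > 16)
    warning("spindle_freq_hz outside the detectable 8-16 Hz band")
  structure(as.list(environment()), class = "synth_tunnel")
}

#' Configuration of a synthetic recording
#'
#' @param duration_s recording length in seconds (default 300, matching the
#'   5-minute spontaneous recordings analysed).
#' @param rate_hz sampling rate, default 25000.
#' @param noise_sd_uv Gaussian background noise SD per channel.
#' @param tunnels list of [synth_tunnel()] specifications.
#' @param seed integer RNG seed; the same config and seed reproduce the
#'   recording exactly.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 300, rate_hz = 25000, noise_sd_uv = 10,
                         tunnels = list(), seed = 1L) {
  stopifnot(duration_s > 0, rate_hz > 0, noise_sd_uv >= 0)
  if (!length(tunnels) || !all(vapply(tunnels, inherits, logical(1), "synth_tunnel")))
    stop("tunnels must be a non-empty list of synth_tunnel specs")
  structure(list(duration_s = duration_s, rate_hz = rate_hz,
                 noise_sd_uv = noise_sd_uv, tunnels = tunnels,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Reference synthetic configuration
#'
#' Four tunnels (EC->DG feed-forward, DG->CA3 feedback, CA3->CA1
#' feed-forward, CA1->EC feedback) whose true parameters sit inside the
#' reported physiological ranges: spike conduction delay 0.40 ms (0.5 m/s
#' over 200 um), slow-wave delay 0.86 ms (0.23 m/s), 10 spindles/min at
#' 12 Hz with a log-normal duration law of mode 0.65 s, slow waves of
#' 800 uV trough amplitude, and a heavy-tailed (power-law, alpha = 1.5)
#' SO-to-spindle nesting lag on [0.05, 1.5] s.
#'
#' @param seed RNG seed stored in the config.
#' @param duration_s recording length, default 300 s.
#' @return A `synth_config`.
#' @export
preset_paper_like <- function(seed = 1L, duration_s = 300) {
  mk <- function(id, src, tgt, dir)
    synth_tunnel(id, src, tgt, direction = dir)
  synth_config(
    duration_s = duration_s, rate_hz = 25000, noise_sd_uv = 10,
    tunnels = list(
      mk("T1", "EC", "DG", "feedforward"),
      mk("T2", "DG", "CA3", "feedback"),
      mk("T3", "CA3", "CA1", "feedforward"),
      mk("T4", "CA1", "EC", "feedback")),
    seed = seed)
}

# inverse-CDF draw from a truncated power law p(t) ~ t^-alpha on [a, b]
.rpowerlaw <- function(n, alpha, a, b) {
  u <- runif(n)
  if (abs(alpha - 1) < 1e-12) return(a * (b / a)^u)
  e <- 1 - alpha
  (a^e + u * (b^e - a^e))^(1 / e)
}

# Best-Fisher (1979) von Mises sampler
.rvonmises <- function(n, mu, kappa) {
  if (kappa <= 0) return(runif(n, 0, 2 * pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  rr <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
      z <- cos(pi * u1)
      f <- (1 + rr * z) / (rr + z)
      cc <- kappa * (rr - f)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
        out[i] <- (mu + sign(u3 - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}

# Poisson event times with a refractory minimum gap
.rpoisson_times <- function(rate_hz, duration_s, min_gap_s = 0) {
  if (rate_hz <= 0) return(numeric(0))
  t <- 0; out <- numeric(0)
  repeat {
    t <- t + rexp(1, rate_hz) + min_gap_s
    if (t >= duration_s) break
    out <- c(out, t)
  }
  out
}

#' Generate a synthetic tunnel recording with ground truth
#'
#' For every tunnel two channels are synthesized. The source electrode
#' carries Gaussian noise plus: biphasic spikes (1.2 ms template) at Poisson
#' times; slow-oscillation events at Poisson times (a single Gabor cycle:
#' 2 Hz carrier under a Gaussian envelope, giving a smooth peak ->
#' positive-to-negative crossing -> trough waveform confined to the 0.5-4 Hz
#' band, with log-normally distributed amplitudes); and spindle bursts
#' (carrier at `spindle_freq_hz` under a Gaussian envelope whose FWHM is the
#' log-normally drawn duration), each nested after a slow oscillation whose
#' amplitude ranks in the top 40% (spindles follow strong slow oscillations,
#' mirroring the epoch-selection rule used downstream), at a
#' power-law-distributed lag measured from the SO peak to the spindle
#' envelope peak. The generator guarantees that the nesting SO is the one
#' directly preceding the spindle, so the true lags are exactly
#' recoverable. The second electrode carries the same event streams shifted
#' by the spike and slow-wave conduction delays (rounded to integer 25 kHz
#' samples; the rounded truth is recorded) with independent noise. The
#' spindle carrier peaks at the envelope maximum, so the 90-degrees-at-peak
#' phase convention holds exactly. Optionally, spike times inside spindles
#' are drawn with von Mises phase locking to the carrier.
#'
#' @param cfg a `synth_config`.
#' @return list with `recording` (`axo_recording`), `channel_map`
#'   (`axo_channel_map`) and `truth` (per-tunnel lists of true events,
#'   delays, lags and locking state).
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  fs <- cfg$rate_hz
  n <- round(cfg$duration_s * fs)
  nt <- length(cfg$tunnels)
  data <- matrix(0, nrow = 2L * nt, ncol = n)
  ids <- character(2L * nt)
  truth <- vector("list", nt)
  elec <- NULL; tun <- NULL
  for (k in seq_len(nt)) {
    tk <- cfg$tunnels[[k]]
    g <- .gen_tunnel(tk, cfg, n)
    data[2L * k - 1L, ] <- g$up
    data[2L * k, ] <- g$dn
    ids[2L * k - 1L] <- paste0(tk$tunnel_id, "_up")
    ids[2L * k] <- paste0(tk$tunnel_id, "_dn")
    truth[[k]] <- g$truth
    elec <- rbind(elec, data.frame(
      id = ids[c(2L * k - 1L, 2L * k)],
      x_um = c(1000 * k, 1000 * k + 200), y_um = 0,
      compartment = "tunnel"))
    tun <- rbind(tun, data.frame(
      tunnel_id = tk$tunnel_id, source_compartment = tk$source,
      target_compartment = tk$target,
      upstream_electrode_id = ids[2L * k - 1L],
      downstream_electrode_id = ids[2L * k],
      electrode_spacing_um = 200))
  }
  names(truth) <- vapply(cfg$tunnels, `[[`, character(1), "tunnel_id")
  list(recording = recording(data, fs, ids),
       channel_map = channel_map(elec, tun),
       truth = truth)
}

# Gabor slow-oscillation template on the sample grid: 2 Hz carrier under a
# Gaussian envelope (sigma 0.15 s), scaled so the trough reaches -1.
.so_template <- function(fs) {
  sig <- 0.15
  tt <- seq(-3.5 * sig, 3.5 * sig, by = 1 / fs)
  w <- -sin(2 * pi * 2 * tt) * exp(-tt^2 / (2 * sig^2))
  w <- w / abs(min(w))
  list(w = w, t = tt,
       off_peak = tt[which.max(w)], off_trough = tt[which.min(w)],
       peak_frac = max(w))
}

# one tunnel: returns up/dn sample vectors and the ground truth
.gen_tunnel <- function(tk, cfg, n) {
  fs <- cfg$rate_hz
  dur <- cfg$duration_s
  # --- slow oscillations ---------------------------------------------------
  tpl <- .so_template(fs)
  half_span <- max(abs(tpl$t))
  so_centers <- half_span + 0.1 +
    .rpoisson_times(tk$sw_rate_hz, dur - 2 * (half_span + 0.1),
                    min_gap_s = 2 * half_span + 0.2)
  so_amp <- tk$sw_amp_uv * 10^rnorm(length(so_centers), 0, tk$sw_amp_sigma_log10)
  so <- data.frame(center_s = so_centers,
                   peak_s = so_centers + tpl$off_peak,
                   zero_cross_s = so_centers,
                   trough_s = so_centers + tpl$off_trough,
                   amp_uv = so_amp)
  # spindles nest after slow oscillations whose amplitude is in the top 40%
  so$eligible <- logical(nrow(so))
  if (nrow(so)) {
    k <- ceiling(0.4 * nrow(so))
    so$eligible <- so$amp_uv >= sort(so$amp_uv, decreasing = TRUE)[k]
  }
  # --- spindles nested after SO peaks --------------------------------------
  n_spin <- rpois(1, tk$spindle_per_min * dur / 60)
  mu_dur <- log10(tk$spindle_dur_mode_s) +
    tk$spindle_dur_sigma_log10^2 * log(10)
  spin <- NULL
  elig <- which(so$eligible)
  if (n_spin > 0 && length(elig) > 0) {
    windows <- matrix(numeric(0), ncol = 2L)
    for (i in seq_len(n_spin)) {
      for (try in 1:50) {
        j <- elig[sample.int(length(elig), 1L)]
        lag <- .rpowerlaw(1, tk$nesting_alpha, tk$nesting_tmin_s, tk$nesting_tmax_s)
        pk <- so$peak_s[j] + lag
        d <- 10^rnorm(1, mu_dur, tk$spindle_dur_sigma_log10)
        a <- tk$spindle_amp_uv * 10^rnorm(1, 0, tk$spindle_amp_sigma_log10)
        lo <- pk - d / 2; hi <- pk + d / 2
        if (lo < 0.5 || hi > dur - 0.5) next
        # the chosen SO must directly precede the spindle peak
        if (any(so$peak_s > so$peak_s[j] & so$peak_s <= pk)) next
        # keep spindles well separated (> 1 s edge to edge)
        if (nrow(windows) && any(!(hi + 1 < windows[, 1] | lo - 1 > windows[, 2]))) next
        windows <- rbind(windows, c(lo, hi))
        spin <- rbind(spin, data.frame(
          start_s = lo, end_s = hi, peak_s = pk, duration_s = d,
          amp_uv = a, lag_s = lag, so_peak_s = so$peak_s[j]))
        break
      }
    }
    if (!is.null(spin)) spin <- spin[order(spin$start_s), , drop = FALSE]
  }
  if (is.null(spin))
    spin <- data.frame(start_s = numeric(0), end_s = numeric(0),
                       peak_s = numeric(0), duration_s = numeric(0),
                       amp_uv = numeric(0), lag_s = numeric(0),
                       so_peak_s = numeric(0))
  # --- spikes --------------------------------------------------------------
  spk <- .rpoisson_times(tk$spike_rate_hz, dur - 0.01, min_gap_s = 0.003)
  locked <- logical(length(spk))
  if (is.finite(tk$phase_lock_kappa) && nrow(spin) > 0) {
    # replace in-spindle spikes by von Mises phase-locked times and add one
    # locked spike per spindle cycle with probability 0.5
    extra <- numeric(0)
    f <- tk$spindle_freq_hz
    for (i in seq_len(nrow(spin))) {
      # cycle origins anchored at the envelope peak, where the carrier phase
      # is exactly 90 degrees, so drawn phases map onto true carrier phases
      half_cyc <- floor((spin$duration_s[i] / 2) * f)
      cyc <- spin$peak_s[i] + (-half_cyc:half_cyc) / f
      emit <- runif(length(cyc)) < 0.5
      if (!any(emit)) next
      ph <- .rvonmises(sum(emit), pi / 2, tk$phase_lock_kappa)
      # carrier phase is 90 deg at each envelope-peak-aligned cycle origin
      tt <- cyc[emit] + (ph - pi / 2) / (2 * pi * f)
      extra <- c(extra, tt[tt > 0.01 & tt < dur - 0.01])
    }
    keep <- !vapply(spk, function(t)
      any(t >= spin$start_s & t < spin$end_s), logical(1))
    spk <- spk[keep]
    locked <- c(logical(length(spk)), rep(TRUE, length(extra)))
    spk <- c(spk, extra)
    o <- order(spk); spk <- spk[o]; locked <- locked[o]
  }
  # --- waveform synthesis --------------------------------------------------
  d_spk <- round(tk$spike_delay_ms * fs / 1000)
  d_sw <- round(tk$sw_delay_ms * fs / 1000)
  sgn <- if (tk$direction == "feedforward") 1L else -1L
  base <- numeric(n)
  # slow oscillations
  for (i in seq_len(nrow(so))) {
    i0 <- round((so$center_s[i] + tpl$t[1L]) * fs)
    idx <- i0 + seq_along(tpl$w)
    ok <- idx >= 1L & idx <= n
    base[idx[ok]] <- base[idx[ok]] + so$amp_uv[i] * tpl$w[ok]
  }
  # spindles
  for (i in seq_len(nrow(spin))) {
    s <- spin$duration_s[i] / 2.355   # FWHM = duration
    half <- min(round(3.5 * s * fs), n)
    pk_i <- round(spin$peak_s[i] * fs)
    idx <- max(1L, pk_i - half):min(n, pk_i + half)
    trel <- (idx - 1L) / fs - spin$peak_s[i]
    base[idx] <- base[idx] + spin$amp_uv[i] *
      exp(-trel^2 / (2 * s^2)) * cos(2 * pi * tk$spindle_freq_hz * trel)
  }
  # spikes (kept separate so the two channels can shift them independently)
  spikes_tr <- numeric(n)
  tmpl <- c(-sin(pi * (0:14) / 14), 0.45 * sin(pi * (0:14) / 14)) * abs(tk$spike_amp_uv)
  half_pre <- 7L
  for (t in spk) {
    i0 <- round(t * fs) - half_pre
    idx <- i0 + seq_along(tmpl)
    ok <- idx >= 1L & idx <= n
    spikes_tr[idx[ok]] <- spikes_tr[idx[ok]] + tmpl[ok]
  }
  shift <- function(x, by) {
    if (by == 0L) return(x)
    if (by > 0L) c(numeric(by), x[1:(length(x) - by)])
    else c(x[(1 - by):length(x)], numeric(-by))
  }
  src <- base + spikes_tr
  dst <- shift(base, sgn * d_sw) + shift(spikes_tr, sgn * d_spk)
  up <- src + rnorm(n, 0, cfg$noise_sd_uv)
  dn <- dst + rnorm(n, 0, cfg$noise_sd_uv)
  list(up = up, dn = dn,
       truth = list(
         spikes_s = spk, spikes_locked = locked,
         so = so, spindles = spin,
         spike_delay_ms = sgn * d_spk / fs * 1000,
         sw_delay_ms = sgn * d_sw / fs * 1000,
         direction = tk$direction,
         phase_locked = is.finite(tk$phase_lock_kappa)))
}
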