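#' Detect slow-wave troughs on a raw channel
#'
#' Finds local minima of the slow-wave component satisfying all four
#' constraints: inter-trough spacing >= `min_sep_s` (100 ms), depth at least
#' `frac_of_max` (20%) of the channel's maximum negative amplitude, depth at
#' most `min_amp_uv` (-100 uV), and width at half-prominence >= `min_width_s`
#' (4 ms, which excludes spikes). Because the cross-electrode slow-wave
#' delays of interest are sub-millisecond, detection runs at the raw 25 kHz
#' rate on a 50 Hz zero-phase low-passed copy of the trace rather than on
#' the 1 kHz LFP.
#'
#' @param x raw channel in microvolts.
#' @param rate_hz sampling rate, default 25000.
#' @param min_sep_s minimum spacing between retained troughs.
#' @param frac_of_max fraction of the global minimum a trough must reach.
#' @param min_amp_uv amplitude ceiling (troughs must be below this, in uV).
#' @param min_width_s minimum width at half-prominence.
#' @param lowpass_hz smoothing cutoff before minima detection (4th-order
#'   Butterworth, zero-phase); set `NA` to skip.
#' @return data.frame with `trough_s`, `trough_uv`, `width_s`.
#' @export
detect_slow_troughs <- function(x, rate_hz = 25000, min_sep_s = 0.1,
                                frac_of_max = 0.2, min_amp_uv = -100,
                                min_width_s = 0.004, lowpass_hz = 50) {
  xs <- if (is.na(lowpass_hz)) x else
    .apply_iir(x, signal::butter(4, lowpass_hz / (rate_hz / 2), type = "low"), TRUE)
  n <- length(xs)
  # local minima (strict on the left, non-strict right to break flat ties)
  cand <- which(xs[2:(n - 1L)] < xs[1:(n - 2L)] & xs[2:(n - 1L)] <= xs[3:n]) + 1L
  if (!length(cand)) return(.empty_troughs())
  depth_floor <- frac_of_max * min(xs)  # negative number
  cand <- cand[xs[cand] <= depth_floor & xs[cand] <= min_amp_uv]
  if (!length(cand)) return(.empty_troughs())
  # width at half prominence; prominence measured against the higher of the
  # two flanking maxima between neighbouring candidate minima
  width_ok <- vapply(seq_along(cand), function(k) {
    i <- cand[k]
    lb <- if (k > 1L) cand[k - 1L] else 1L
    rb <- if (k < length(cand)) cand[k + 1L] else n
    base <- min(max(xs[lb:i]), max(xs[i:rb]))
    half <- xs[i] + (base - xs[i]) / 2
    l <- i; while (l > 1L && xs[l] <= half) l <- l - 1L
    r <- i; while (r < n && xs[r] <= half) r <- r + 1L
    (r - l) / rate_hz >= min_width_s
  }, logical(1))
  cand <- cand[width_ok]
  if (!length(cand)) return(.empty_troughs())
  # enforce minimum separation, deepest first
  o <- cand[order(xs[cand])]
  sep <- min_sep_s * rate_hz
  kept <- integer(0)
  for (i in o) if (!length(kept) || all(abs(i - kept) >= sep)) kept <- c(kept, i)
  kept <- sort(kept)
  out <- data.frame(trough_s = (kept - 1L) / rate_hz, trough_uv = xs[kept])
  # recompute width for reporting
  out$width_s <- vapply(kept, function(i) {
    half <- xs[i] / 2
    l <- i; while (l > 1L && xs[l] <= half) l <- l - 1L
    r <- i; while (r < n && xs[r] <= half) r <- r + 1L
    (r - l) / rate_hz
  }, numeric(1))
  out
}

.empty_troughs <- function() {
  data.frame(trough_s = numeric(0), trough_uv = numeric(0), width_s = numeric(0))
}

#' Detect slow-oscillation epochs
#'
#' A slow-oscillation epoch is a positive-to-negative zero crossing of the
#' slow-band signal with a peak to the left of the crossing and a trough to
#' the right. The trace is mean-subtracted and zero-phase low-passed at
#' `lowpass_hz` (4 Hz, 4th-order Butterworth; a high-pass is avoided because
#' its multi-second transient distorts epoch amplitudes at the record
#' edges). All peak / crossing / trough triplets are located; retained
#' epochs are those whose peak is in the top `top_frac` (40%) of peak
#' amplitudes and whose trough is in the top 40% most negative troughs.
#' Ties at the selection threshold are kept.
#'
#' @param x single channel in microvolts.
#' @param rate_hz sampling rate.
#' @param lowpass_hz slow-band upper edge in Hz; `NA` skips filtering (the
#'   mean is still subtracted), for signals that are already slow-band.
#' @param top_frac fraction of epochs retained on each criterion.
#' @param min_trough_uv optional amplitude floor (uV): candidate epochs whose
#'   trough is above this value are discarded before the top-40% selection.
#'   `NA` (default) disables the gate; the pipeline uses -100 uV, the
#'   slow-wave floor, so that micro-noise zero crossings in continuous
#'   recordings do not enter the epoch ranking.
#' @return data.frame with `peak_s`, `peak_uv`, `zero_cross_s`, `trough_s`,
#'   `trough_uv`; attribute `n_candidates` gives the pre-selection count.
#' @export
detect_so_epochs <- function(x, rate_hz, lowpass_hz = 4, top_frac = 0.4,
                             min_trough_uv = NA) {
  xs <- x - mean(x)
  if (!is.na(lowpass_hz)) {
    flt <- signal::butter(4, lowpass_hz / (rate_hz / 2), type = "low")
    xs <- .apply_iir(xs, flt, TRUE)
  }
  n <- length(xs)
  sgn <- sign(xs)
  # positive-to-negative crossings
  dn <- which(sgn[-n] > 0 & sgn[-1L] <= 0)
  up <- which(sgn[-n] <= 0 & sgn[-1L] > 0)
  if (length(dn) < 1L) return(.empty_epochs())
  rows <- lapply(dn, function(c0) {
    prev_up <- up[up < c0]
    next_up <- up[up > c0]
    a <- if (length(prev_up)) max(prev_up) else 1L
    b <- if (length(next_up)) min(next_up) else n
    pk <- a - 1L + which.max(xs[a:c0])
    tr <- c0 - 1L + which.min(xs[c0:b])
    data.frame(peak_s = (pk - 1L) / rate_hz, peak_uv = xs[pk],
               zero_cross_s = (c0 - 1L) / rate_hz,
               trough_s = (tr - 1L) / rate_hz, trough_uv = xs[tr])
  })
  ep <- do.call(rbind, rows)
  if (!is.na(min_trough_uv))
    ep <- ep[ep$trough_uv <= min_trough_uv, , drop = FALSE]
  if (!nrow(ep)) return(.empty_epochs())
  ncand <- nrow(ep)
  if (ncand < 3L) {
    warning("fewer than 3 candidate epochs; all retained")
  } else {
    k <- ceiling(top_frac * ncand)
    pk_thr <- sort(ep$peak_uv, decreasing = TRUE)[k]
    tr_thr <- sort(ep$trough_uv)[k]
    ep <- ep[ep$peak_uv >= pk_thr & ep$trough_uv <= tr_thr, , drop = FALSE]
  }
  rownames(ep) <- NULL
  attr(ep, "n_candidates") <- ncand
  ep
}

.empty_epochs <- function() {
  e <- data.frame(peak_s = numeric(0), peak_uv = numeric(0),
                  zero_cross_s = numeric(0), trough_s = numeric(0),
                  trough_uv = numeric(0))
  attr(e, "n_candidates") <- 0L
  e
}

#' Pair slow-wave troughs across a tunnel's electrodes
#'
#' Greedy minimum-|dt| pairing, each trough used at most once, capped at
#' `max_delay_s` (5 ms). Unmatched minima on either side are reported.
#' Pairing is order-independent: shuffling the inputs yields the same pairs.
#'
#' @param up,down trough times in seconds (vectors or data.frames from
#'   [detect_slow_troughs()]).
#' @param max_delay_s maximum |delay| accepted, default 5 ms.
#' @return list with `delays_ms` (signed, down - up), `n_pairs`,
#'   `unmatched_up`, `unmatched_down` (times in seconds).
#' @export
pair_troughs <- function(up, down, max_delay_s = 0.005) {
  if (is.data.frame(up)) up <- up$trough_s
  if (is.data.frame(down)) down <- down$trough_s
  up <- sort(up); down <- sort(down)
  m <- .greedy_match(up, down, max_delay_s)
  list(delays_ms = m$delay_s * 1000,
       n_pairs = length(m$delay_s),
       unmatched_up = up[setdiff(seq_along(up), m$up_idx)],
       unmatched_down = down[setdiff(seq_along(down), m$down_idx)])
}

#' Summarize spike and slow-wave conduction delays per direction
#'
#' Takes per-axon spike delays and per-axon slow-wave delays (lists of
#' numeric vectors, milliseconds, one element per axon), applies the
#' exclusion rule (an axon with delay SE greater than its mean |delay| or SE
#' equal to 0 is excluded), pools the surviving per-axon delay samples into
#' a grand mean and SE per modality, converts the group means to velocities
#' (2 significant figures), and tests slow-wave delays against spike delays
#' by two-sample t-test. The percent-slower figure is computed from the
#' rounded group velocities: `(1 - v_slow / v_spike) * 100`, rounded to the
#' nearest percent.
#'
#' @param spike_delays_ms list of numeric vectors (one per axon) or a single
#'   numeric vector treated as one axon.
#' @param slow_delays_ms same structure for slow-wave delays.
#' @param spacing_mm electrode spacing in mm, default 0.2.
#' @return list of class `axo_delay_summary` with per-axon tables
#'   (`axons_spike`, `axons_slow` including `excluded` flags), group
#'   statistics (`mean_spike_ms`, `se_spike_ms`, `mean_slow_ms`,
#'   `se_slow_ms`), `v_spike_m_s`, `v_slow_m_s`, `percent_slower`, and
#'   `t_test` (htest or NULL with a notice when < 2 axons per group).
#' @export
summarize_delays <- function(spike_delays_ms, slow_delays_ms, spacing_mm = 0.2) {
  as_list <- function(v) if (is.list(v)) v else list(v)
  per_axon <- function(lst) {
    do.call(rbind, lapply(seq_along(lst), function(i) {
      d <- lst[[i]]
      mu <- mean(d)
      se <- if (length(d) > 1L) sd(d) / sqrt(length(d)) else 0
      excl <- se > abs(mu) || se == 0
      data.frame(axon = i, n = length(d), mean_ms = mu, se_ms = se,
                 excluded = excl,
                 reason = if (!excl) "" else if (se == 0) "se == 0" else "se > mean")
    }))
  }
  sp <- per_axon(as_list(spike_delays_ms))
  sl <- per_axon(as_list(slow_delays_ms))
  pool <- function(lst, tab) unlist(lst[!tab$excluded], use.names = FALSE)
  sp_all <- pool(as_list(spike_delays_ms), sp)
  sl_all <- pool(as_list(slow_delays_ms), sl)
  if (!length(sp_all) || !length(sl_all))
    stop("all axons excluded in at least one modality")
  # delay magnitude = |signed mean|: taking |.| per pair first would fold the
  # jitter distribution and bias sub-millisecond delays upward
  gm <- function(v) abs(mean(v))
  gse <- function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0
  v_spike <- conduction_velocity(gm(sp_all), spacing_mm)
  v_slow <- conduction_velocity(gm(sl_all), spacing_mm)
  pct <- round((1 - round(v_slow, 2) / round(v_spike, 2)) * 100)
  # align signs (per-direction data share one conduction sign) for the test
  sp_mag <- sp_all * sign(mean(sp_all))
  sl_mag <- sl_all * sign(mean(sl_all))
  tt <- NULL
  if (sum(!sp$excluded) >= 2L && sum(!sl$excluded) >= 2L &&
      (var(sp_mag) > 0 || var(sl_mag) > 0)) {
    tt <- t.test(sl_mag, sp_mag)
  } else message("t-test skipped: fewer than 2 usable axons per group or no variance")
  structure(list(axons_spike = sp, axons_slow = sl,
                 mean_spike_ms = gm(sp_all), se_spike_ms = gse(sp_all),
                 mean_slow_ms = gm(sl_all), se_slow_ms = gse(sl_all),
                 v_spike_m_s = v_spike, v_slow_m_s = v_slow,
                 percent_slower = pct, t_test = tt, spacing_mm = spacing_mm),
            class = "axo_delay_summary")
}

#' @export
print.axo_delay_summary <- function(x, ...) {
  cat(sprintf("<axo_delay_summary> spike %.2f ms (%.2f m/s), slow wave %.2f ms (%.2f m/s): %d%% slower\n",
              x$mean_spike_ms, x$v_spike_m_s, x$mean_slow_ms, x$v_slow_m_s,
              x$percent_slower))
  if (!is.null(x$t_test))
    cat(sprintf("  t-test slow vs spike: t = %.2f, p = %.3g\n",
                unname(x$t_test$statistic), x$t_test$p.value))
  invisible(x)
}

#' Paired t-test of slow-wave amplitude attenuation along the tunnel
#'
#' Tests whether the per-axon mean trough amplitude declines in magnitude
#' from the electrode nearer the source subregion to the farther one
#' (paired, one-sided |near| > |far|).
#'
#' @param near,far per-axon mean trough amplitudes in uV (negative),
#'   aligned by axon.
#' @return list with `mean_near_uv`, `mean_far_uv`, `mean_diff_uv`
#'   (|near| - |far|), `p_value`, `n`, `t_test` (htest or NULL when n < 2 or
#'   no variance).
#' @export
amplitude_attenuation_test <- function(near, far) {
  if (length(near) != length(far)) stop("near and far must align by axon")
  n <- length(near)
  d <- abs(near) - abs(far)
  if (n < 2L) {
    message("attenuation test skipped: fewer than 2 axons")
    return(list(mean_near_uv = mean(near), mean_far_uv = mean(far),
                mean_diff_uv = mean(d), p_value = NA_real_, n = n,
                t_test = NULL))
  }
  if (var(d) == 0) {
    p <- if (all(d == 0)) 1 else if (mean(d) > 0) 0 else 1
    return(list(mean_near_uv = mean(near), mean_far_uv = mean(far),
                mean_diff_uv = mean(d), p_value = p, n = n, t_test = NULL))
  }
  tt <- t.test(abs(near), abs(far), paired = TRUE, alternative = "greater")
  list(mean_near_uv = mean(near), mean_far_uv = mean(far),
       mean_diff_uv = mean(d), p_value = tt$p.value, n = n, t_test = tt)
}
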