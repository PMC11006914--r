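#' Detect spindle events on a 1 kHz LFP channel
#'
#' Pipeline: [bandpass_spindle()] (8-16 Hz) -> [hilbert_envelope()] ->
#' threshold crossing. A candidate window is classified as a spindle when the
#' envelope stays above `mean + 1.5 SD` continuously for more than
#' `min_dur_s` (300 ms) and exceeds `mean + 2.5 SD` at least once within the
#' window. Event boundaries are the 1.5 SD crossings. Multiple detections of
#' the same spindle are eliminated by merging events separated by less than
#' `merge_gap_s` (500 ms); merged-event metrics are recomputed over the
#' merged span. The envelope mean and SD are taken over the whole channel.
#'
#' Detection is scale-equivariant: multiplying the channel by any c > 0
#' leaves event times unchanged, because both thresholds are in units of the
#' channel's own envelope statistics.
#'
#' @param x single LFP channel (microvolts) at `rate_hz`.
#' @param rate_hz sampling rate, default 1000.
#' @param band detection band in Hz passed to [bandpass_spindle()].
#' @param thr_event upper threshold in envelope SD units (event criterion).
#' @param thr_bound lower threshold in envelope SD units (boundary/duration
#'   criterion).
#' @param min_dur_s minimum continuous supra-boundary duration in seconds.
#' @param merge_gap_s events closer than this are combined.
#' @return list of class `axo_spindles`: `events` (data.frame with `start_s`,
#'   `end_s`, `duration_s`, `peak_env_uv`, `peak_s`, `merged_from_n`),
#'   `envelope`, `rate_hz`, `env_mean`, `env_sd`.
#' @export
detect_spindles <- function(x, rate_hz = 1000, band = c(8, 16),
                            thr_event = 2.5, thr_bound = 1.5,
                            min_dur_s = 0.3, merge_gap_s = 0.5) {
  if (length(x) < 10 * rate_hz)
    warning("recording shorter than 10 s: envelope SD baseline may be unstable")
  xf <- bandpass_spindle(x, rate_hz = rate_hz, band = band)
  env <- hilbert_envelope(xf)$envelope
  mu <- mean(env); sigma <- sd(env)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), peak_env_uv = numeric(0),
                      peak_s = numeric(0), merged_from_n = integer(0))
  if (!is.finite(sigma) || sigma == 0)
    return(structure(list(events = empty, envelope = env, rate_hz = rate_hz,
                          env_mean = mu, env_sd = sigma),
                     class = "axo_spindles"))
  lo <- mu + thr_bound * sigma
  hi <- mu + thr_event * sigma
  above <- env > lo
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  keep <- (ends - starts + 1L) / rate_hz > min_dur_s
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts)) {
    has_peak <- mapply(function(a, b) max(env[a:b]) >= hi, starts, ends)
    starts <- starts[has_peak]; ends <- ends[has_peak]
  }
  merged_n <- rep(1L, length(starts))
  # merge events with gaps < merge_gap_s
  if (length(starts) > 1L) {
    i <- 1L
    while (i < length(starts)) {
      gap <- (starts[i + 1L] - ends[i] - 1L) / rate_hz
      if (gap < merge_gap_s) {
        ends[i] <- ends[i + 1L]
        merged_n[i] <- merged_n[i] + merged_n[i + 1L]
        starts <- starts[-(i + 1L)]; ends <- ends[-(i + 1L)]
        merged_n <- merged_n[-(i + 1L)]
      } else i <- i + 1L
    }
  }
  if (length(starts)) {
    peak_i <- mapply(function(a, b) a - 1L + which.max(env[a:b]), starts, ends)
    events <- data.frame(
      start_s = (starts - 1L) / rate_hz,
      end_s = ends / rate_hz,  # half-open [start, end)
      duration_s = (ends - starts + 1L) / rate_hz,
      peak_env_uv = env[peak_i],
      peak_s = (peak_i - 1L) / rate_hz,
      merged_from_n = merged_n)
  } else events <- empty
  structure(list(events = events, envelope = env, rate_hz = rate_hz,
                 env_mean = mu, env_sd = sigma),
            class = "axo_spindles")
}

#' @export
print.axo_spindles <- function(x, ...) {
  cat(sprintf("<axo_spindles> %d event(s); envelope mean %.2f uV, SD %.2f uV\n",
              nrow(x$events), x$env_mean, x$env_sd))
  invisible(x)
}

#' Per-spindle metrics and inter-spindle intervals
#'
#' Adds to each event the area under the envelope (trapezoidal integral over
#' the half-open event span, in uV*s), the amplitude (area / duration, uV),
#' and the inter-spindle interval (start of the next event minus end of this
#' one, NA for the last event of a channel). Events shorter than
#' `min_keep_s` (0.4 s) are flagged `short = TRUE`; they remain in the table
#' but are excluded from distribution statistics.
#'
#' @param sp an `axo_spindles` object, or an event data.frame (then
#'   `envelope` and `rate_hz` must be given).
#' @param envelope envelope samples when `sp` is a plain data.frame.
#' @param rate_hz envelope sampling rate when `sp` is a plain data.frame.
#' @param min_keep_s length below which an event is flagged short.
#' @return Event data.frame with `area_uv_s`, `amplitude_uv`, `isi_s`,
#'   `short` columns added.
#' @export
spindle_metrics <- function(sp, envelope = NULL, rate_hz = NULL,
                            min_keep_s = 0.4) {
  if (inherits(sp, "axo_spindles")) {
    events <- sp$events; envelope <- sp$envelope; rate_hz <- sp$rate_hz
  } else {
    events <- as.data.frame(sp)
    if (is.null(envelope) || is.null(rate_hz))
      stop("envelope and rate_hz are required with a plain event table")
  }
  if (!nrow(events)) {
    events$area_uv_s <- numeric(0); events$amplitude_uv <- numeric(0)
    events$isi_s <- numeric(0); events$short <- logical(0)
    return(events)
  }
  if (is.unsorted(events$start_s, strictly = FALSE))
    stop("events out of order")
  i0 <- round(events$start_s * rate_hz) + 1L
  i1 <- round(events$end_s * rate_hz)  # [start, end): last sample index
  i1 <- pmin(i1, length(envelope))
  area <- mapply(function(a, b) {
    seg <- envelope[a:b]
    sum((seg[-1] + seg[-length(seg)]) / 2) / rate_hz
  }, i0, i1)
  events$area_uv_s <- area
  events$amplitude_uv <- area / events$duration_s
  events$isi_s <- c(events$start_s[-1L] - events$end_s[-nrow(events)], NA_real_)
  events$short <- events$duration_s < min_keep_s
  events
}
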