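#' Spike-phase histogram within spindles
#'
#' Assigns to every spike that falls inside a spindle window the
#' instantaneous phase of the spindle-band signal at its peak time, and
#' accumulates a 50-bin histogram over [0, 360) degrees (0 at the
#' positive-going zero crossing, 90 at the oscillation peak, 270 at the
#' trough). Reports the resultant vector length and the Hodges-Ajne omnibus
#' p-value for non-uniformity.
#'
#' @param spikes spike times in seconds (vector or [detect_spikes()] output).
#'   Spike times are on the raw 25 kHz clock; phases are looked up at the
#'   nearest sample of the phase signal.
#' @param phase instantaneous phase in radians from [hilbert_envelope()] of
#'   the 10-16 Hz filtered channel.
#' @param rate_hz sampling rate of `phase`, default 1000.
#' @param spindles spindle events (data.frame with `start_s`, `end_s`).
#' @param n_bins histogram bins, default 50.
#' @param t0_s start time of the phase signal.
#' @return Object of class `phaselock`: `bin_edges_deg`, `counts`,
#'   `phases_deg`, `n_spikes`, `resultant_length`, `p_omnibus`,
#'   `effect_size` (NA at single-recording level; see
#'   [phase_effect_size()]).
#' @export
spike_phase_histogram <- function(spikes, phase, rate_hz = 1000, spindles,
                                  n_bins = 50, t0_s = 0) {
  if (is.data.frame(spikes)) spikes <- spikes$t_s
  ev <- if (is.data.frame(spindles)) spindles else as.data.frame(spindles)
  edges <- seq(0, 360, length.out = n_bins + 1L)
  inside <- rep(FALSE, length(spikes))
  if (nrow(ev)) {
    for (k in seq_len(nrow(ev)))
      inside <- inside | (spikes >= ev$start_s[k] & spikes < ev$end_s[k])
  }
  st <- spikes[inside]
  if (!length(st)) {
    message("no in-spindle spikes")
    return(structure(list(bin_edges_deg = edges, counts = integer(n_bins),
                          phases_deg = numeric(0), n_spikes = 0L,
                          resultant_length = NA_real_, p_omnibus = NA_real_,
                          effect_size = NA_real_),
                     class = "phaselock"))
  }
  idx <- pmin(pmax(round((st - t0_s) * rate_hz) + 1L, 1L), length(phase))
  ph <- phase[idx]
  deg <- (ph * 180 / pi) %% 360
  counts <- hist(deg, breaks = edges, plot = FALSE, right = FALSE)$counts
  r <- Mod(mean(exp(1i * ph)))
  p <- if (length(ph) >= 10L) hodges_ajne_test(ph) else {
    message("fewer than 10 in-spindle spikes: omnibus test skipped")
    NA_real_
  }
  structure(list(bin_edges_deg = edges, counts = counts, phases_deg = deg,
                 n_spikes = length(st), resultant_length = r, p_omnibus = p,
                 effect_size = NA_real_),
            class = "phaselock")
}

#' @export
print.phaselock <- function(x, ...) {
  cat(sprintf("<phaselock> %d in-spindle spikes, resultant length %.3f, omnibus p = %.3g\n",
              x$n_spikes, x$resultant_length, x$p_omnibus))
  invisible(x)
}

#' Hodges-Ajne omnibus test for circular uniformity
#'
#' The statistic m is the minimum, over all half-circles, of the number of
#' angles falling in the half-circle. For n <= 50 the exact tail probability
#' `p = (n - 2m) * choose(n, m) * 2^(1 - n)` is used (capped at 1); for
#' larger n the Ajne normal-form approximation
#' `p = sqrt(2*pi)/A * exp(-pi^2 / (8 A^2))` with
#' `A = pi * sqrt(n) / (2 * (n - 2m))`.
#'
#' @param angles angles in radians (any range; taken mod 2*pi). n >= 10.
#' @return p-value in [0, 1].
#' @export
hodges_ajne_test <- function(angles) {
  a <- angles[is.finite(angles)] %% (2 * pi)
  n <- length(a)
  if (n < 10L) stop("need at least 10 angles")
  m <- .ajne_m(a)
  if (n - 2 * m <= 0) return(1)  # perfectly balanced half-circles
  if (n <= 50L) {
    p <- (n - 2 * m) * choose(n, m) * 2^(1 - n)
    return(min(max(p, 0), 1))
  }
  A <- pi * sqrt(n) / (2 * (n - 2 * m))
  min(max(sqrt(2 * pi) / A * exp(-pi^2 / (8 * A^2)), 0), 1)
}

# minimum half-circle count: evaluate the (right-continuous) count of points
# in [theta, theta + pi) just after each of its breakpoints
.ajne_m <- function(a) {
  n <- length(a)
  s <- sort(a)
  eps <- 1e-10
  cand <- sort(unique(c(s, (s - pi)))) %% (2 * pi) + eps
  hi <- (cand + pi) %% (2 * pi)
  wrap <- cand + pi > 2 * pi
  cnt <- integer(length(cand))
  f <- findInterval(cand, s)
  fh <- findInterval(hi, s)
  cnt[!wrap] <- fh[!wrap] - f[!wrap]
  cnt[wrap] <- (n - f[wrap]) + fh[wrap]
  min(pmin(cnt, n - cnt))
}

#' Effect size of phase-histogram modulation across recordings
#'
#' The pooled (across-array mean) normalized histogram's largest bin count
#' minus its smallest, divided by the standard deviation of the per-array
#' normalized bin counts. Dimensionless; 0 for identical flat histograms and
#' invariant to rescaling all counts of an array.
#'
#' @param counts matrix of bin counts, arrays x bins (>= 2 rows). Rows are
#'   normalized to unit sum before use.
#' @return Effect size (scalar).
#' @export
phase_effect_size <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L)
    stop("need at least 2 arrays: across-array SD undefined")
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("an array has zero total count")
  norm <- sweep(counts, 1L, tot, "/")
  pooled <- colMeans(norm)
  s <- sd(as.vector(norm))
  if (s == 0) return(0)
  (max(pooled) - min(pooled)) / s
}

#' Cross-correlation of spindle envelopes between two channels
#'
#' Each envelope is set to zero outside its own spindle windows, then the
#' coefficient-normalized cross-correlation
#' `r(l) = sum(A_t * B_{t+l}) / sqrt(sum(A^2) * sum(B^2))`
#' is evaluated over lags |l| <= `max_lag_s` and the peak coefficient and its
#' lag returned. A positive best lag means channel B lags channel A. When
#' the channels sit `distance_mm` apart, `distance / |best_lag|` bounds the
#' propagation velocity from below.
#'
#' @param envA,envB equal-length 1 kHz envelopes (uV).
#' @param spindlesA,spindlesB spindle event tables for the two channels
#'   (data.frames with `start_s`, `end_s`).
#' @param rate_hz envelope sampling rate, default 1000.
#' @param max_lag_s maximum |lag| scanned, default 0.1 s.
#' @return list of class `axo_envcorr`: `r`, `best_lag_s`, `lags_s`,
#'   `r_by_lag`. `r` is NA (with a message) when either masked envelope is
#'   all zero.
#' @export
spindle_envelope_correlation <- function(envA, envB, spindlesA, spindlesB,
                                         rate_hz = 1000, max_lag_s = 0.1) {
  if (length(envA) != length(envB)) stop("envelopes must have equal length")
  mask <- function(env, ev) {
    keep <- rep(FALSE, length(env))
    if (nrow(ev)) for (k in seq_len(nrow(ev))) {
      i0 <- max(1L, round(ev$start_s[k] * rate_hz) + 1L)
      i1 <- min(length(env), round(ev$end_s[k] * rate_hz))
      if (i1 >= i0) keep[i0:i1] <- TRUE
    }
    env * keep
  }
  A <- mask(envA, as.data.frame(spindlesA))
  B <- mask(envB, as.data.frame(spindlesB))
  ea <- sum(A^2); eb <- sum(B^2)
  if (ea == 0 || eb == 0) {
    message("a channel is all zero after spindle masking: r undefined")
    return(structure(list(r = NA_real_, best_lag_s = NA_real_,
                          lags_s = numeric(0), r_by_lag = numeric(0)),
                     class = "axo_envcorr"))
  }
  L <- round(max_lag_s * rate_hz)
  n <- length(A)
  lags <- (-L):L
  r_by_lag <- vapply(lags, function(l) {
    if (l >= 0) sum(A[1:(n - l)] * B[(1 + l):n]) else
      sum(A[(1 - l):n] * B[1:(n + l)])
  }, numeric(1)) / sqrt(ea * eb)
  best <- which.max(r_by_lag)
  structure(list(r = r_by_lag[best], best_lag_s = lags[best] / rate_hz,
                 lags_s = lags / rate_hz, r_by_lag = r_by_lag),
            class = "axo_envcorr")
}

#' @export
print.axo_envcorr <- function(x, ...) {
  cat(sprintf("<axo_envcorr> r = %.3f at lag %.3f s\n", x$r, x$best_lag_s))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD over grouped correlation values
#'
#' Shared group-comparison engine: one-way analysis of variance followed by
#' Tukey's honestly-significant-difference pairwise comparisons.
#'
#' @param values numeric vector.
#' @param groups grouping factor (>= 2 levels, each with >= 2 values).
#' @return list of class `axo_group_compare`: `F`, `df_between`, `df_within`,
#'   `p_value`, `tukey` (data.frame of pairwise results), `group_means`.
#'   With zero variance everywhere, `F` is NA and a notice is emitted.
#' @export
correlation_group_compare <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  tab <- table(g)
  if (any(tab < 2L)) stop("degenerate groups: every group needs >= 2 values")
  if (var(values) == 0) {
    message("no variance in the data: ANOVA undefined")
    return(structure(list(F = NA_real_, df_between = nlevels(g) - 1L,
                          df_within = length(values) - nlevels(g),
                          p_value = NA_real_, tukey = NULL,
                          group_means = tapply(values, g, mean)),
                     class = "axo_group_compare"))
  }
  fit <- aov(values ~ g)
  an <- anova(fit)
  tk <- TukeyHSD(fit)$g
  structure(list(F = an$`F value`[1L], df_between = an$Df[1L],
                 df_within = an$Df[2L], p_value = an$`Pr(>F)`[1L],
                 tukey = data.frame(comparison = rownames(tk),
                                    diff = tk[, "diff"], p_adj = tk[, "p adj"],
                                    row.names = NULL),
                 group_means = tapply(values, g, mean)),
            class = "axo_group_compare")
}

#' @export
print.axo_group_compare <- function(x, ...) {
  cat(sprintf("<axo_group_compare> F(%d,%d) = %.3g, p = %.3g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  invisible(x)
}
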