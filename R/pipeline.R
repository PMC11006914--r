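#' Run the full spindle analysis pipeline
#'
#' Orchestrates conditioning -> spikes -> spindles -> slow waves -> nesting
#' -> coupling -> distributions over every tunnel of a recording, and
#' (optionally) writes every event table and fit summary plus a run log to
#' `out_dir`. Re-running with the same inputs reproduces identical outputs.
#'
#' @param input either a `synth_config` (the recording is generated) or a
#'   list with elements `recording` (`axo_recording` at 25 kHz) and
#'   `channel_map` (`axo_channel_map`).
#' @param out_dir output directory; `NULL` (default) skips writing.
#' @param phase_band band used for the spike-phase analysis, default
#'   10-16 Hz.
#' @return list of class `axo_pipeline` with per-stage results: `lfp`,
#'   `spikes` (per channel), `axons` (per tunnel), `spindles` (per channel),
#'   `troughs`, `delay_summaries`, `so_epochs`, `nesting`, `coupling`,
#'   `distributions`, `truth` (when synthetic), `log`.
#' @export
run_pipeline <- function(input, out_dir = NULL, phase_band = c(10, 16)) {
  if (inherits(input, "synth_config")) {
    gen <- generate_recording(input)
    rec <- gen$recording; map <- gen$channel_map; truth <- gen$truth
    cfg_for_log <- input
  } else {
    rec <- input$recording; map <- input$channel_map; truth <- NULL
    cfg_for_log <- list(channels = rec$channel_ids, rate_hz = rec$rate_hz)
    if (is.null(rec) || is.null(map))
      stop("missing prerequisite: input needs recording and channel_map")
  }
  if (rec$rate_hz != 25000)
    stop("missing prerequisite: pipeline expects a 25 kHz raw recording")
  chans <- rec$channel_ids
  # --- condition -----------------------------------------------------------
  lfp <- downsample_lfp(rec)
  # --- per-channel detections ---------------------------------------------
  spikes <- list(); spindles <- list(); troughs <- list(); so_epochs <- list()
  for (ch in chans) {
    raw <- recording_channel(rec, ch)
    spikes[[ch]] <- detect_spikes(bandpass_spike(raw, rec$rate_hz), rec$rate_hz)
    x1k <- recording_channel(lfp, ch)
    det <- detect_spindles(x1k, lfp$rate_hz)
    spindles[[ch]] <- list(events = spindle_metrics(det), det = det)
    troughs[[ch]] <- detect_slow_troughs(raw, rec$rate_hz)
    # the -100 uV slow-wave floor gates out micro-noise zero crossings before
    # the top-40% epoch selection
    so_epochs[[ch]] <- detect_so_epochs(x1k, lfp$rate_hz, min_trough_uv = -100)
  }
  # --- per-tunnel matching, delays, coupling -------------------------------
  tun <- map$tunnels
  axons <- list(); delay_summaries <- list(); coupling <- list()
  for (i in seq_len(nrow(tun))) {
    id <- tun$tunnel_id[i]
    up <- tun$upstream_electrode_id[i]; dn <- tun$downstream_electrode_id[i]
    m <- match_tunnel_spikes(spikes[[up]], spikes[[dn]])
    ax <- identify_axons(m, spacing_um = tun$electrode_spacing_um[i])
    axons[[id]] <- ax
    pt <- pair_troughs(troughs[[up]], troughs[[dn]])
    ds <- NULL
    if (nrow(ax) && length(pt$delays_ms) >= 2L) {
      mode_ms <- ax$mode_delay_ms[which.max(ax$n_matched_spikes)]
      spike_d <- m$delays_ms[abs(m$delays_ms - mode_ms) <= 0.2]
      ds <- tryCatch(
        summarize_delays(list(spike_d), list(pt$delays_ms),
                         spacing_mm = tun$electrode_spacing_um[i] / 1000),
        error = function(e) NULL)
    }
    delay_summaries[[id]] <- list(trough_pairs = pt, summary = ds)
    # spike-phase coupling and envelope correlation on the tunnel pair
    x_up <- recording_channel(lfp, up)
    ph <- hilbert_envelope(bandpass_spindle(x_up, lfp$rate_hz, band = phase_band))
    plk <- spike_phase_histogram(spikes[[up]], ph$phase, lfp$rate_hz,
                                 spindles[[up]]$events)
    env_up <- spindles[[up]]$det$envelope
    env_dn <- spindles[[dn]]$det$envelope
    ec <- spindle_envelope_correlation(env_up, env_dn,
                                       spindles[[up]]$events,
                                       spindles[[dn]]$events,
                                       rate_hz = lfp$rate_hz)
    coupling[[id]] <- list(phase = plk, envcorr = ec)
  }
  # --- nesting -------------------------------------------------------------
  lags <- unlist(lapply(chans, function(ch) {
    nesting_lags(so_epochs[[ch]], spindles[[ch]]$events)$lags_s
  }), use.names = FALSE)
  nest <- if (length(lags) >= 20L)
    tryCatch(fit_loglog(lags), error = function(e) NULL) else NULL
  # --- distributions -------------------------------------------------------
  dist_tbl <- do.call(rbind, lapply(seq_len(nrow(tun)), function(i) {
    ch <- tun$upstream_electrode_id[i]
    ev <- spindles[[ch]]$events
    if (nrow(ev) <= 1L) return(NULL)  # single-spindle channels dropped
    ev <- ev[!ev$short, , drop = FALSE]
    if (!nrow(ev)) return(NULL)
    dir <- if (!is.null(truth)) truth[[tun$tunnel_id[i]]]$direction else "unknown"
    data.frame(tunnel_id = tun$tunnel_id[i], direction = dir,
               duration_s = ev$duration_s, amplitude_uv = ev$amplitude_uv,
               isi_s = ev$isi_s)
  }))
  dists <- list()
  if (!is.null(dist_tbl) && nrow(dist_tbl) >= 10L) {
    dists$duration <- fit_log_histogram(dist_tbl$duration_s, n_bins = 50)
    dists$amplitude <- fit_log_histogram(dist_tbl$amplitude_uv, n_bins = 100)
    isi <- dist_tbl$isi_s[is.finite(dist_tbl$isi_s) & dist_tbl$isi_s > 0]
    if (length(isi) >= 10L) dists$isi <- fit_log_histogram(isi, n_bins = 50)
  }
  log <- list(config_hash = .cfg_hash(cfg_for_log),
              seed = if (inherits(input, "synth_config")) input$seed else NA,
              version = as.character(utils::packageVersion("axospindle")),
              n_channels = length(chans), n_tunnels = nrow(tun))
  out <- structure(list(lfp = lfp, spikes = spikes, axons = axons,
                        spindles = spindles, troughs = troughs,
                        delay_summaries = delay_summaries,
                        so_epochs = so_epochs, nesting = nest,
                        coupling = coupling, distributions = dists,
                        truth = truth, log = log),
                   class = "axo_pipeline")
  if (!is.null(out_dir)) .write_bundle(out, map, out_dir)
  out
}

#' @export
print.axo_pipeline <- function(x, ...) {
  nsp <- sum(vapply(x$spindles, function(s) nrow(s$events), numeric(1)))
  cat(sprintf("<axo_pipeline> %d channels, %d tunnels, %d spindles, %s nesting lags\n",
              x$log$n_channels, x$log$n_tunnels, nsp,
              if (is.null(x$nesting)) "no" else x$nesting$n))
  invisible(x)
}

# small deterministic polynomial hash of the serialized config
.cfg_hash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2)[-(1:14)])  # skip header
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.write_bundle <- function(x, map, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  ev <- function(lst, type, cols) {
    do.call(rbind, lapply(names(lst), function(ch) {
      d <- lst[[ch]]
      if (!nrow(d)) return(NULL)
      cbind(data.frame(channel_id = ch, event_type = type), d)
    }))
  }
  spikes_tbl <- do.call(rbind, lapply(names(x$spikes), function(ch) {
    d <- x$spikes[[ch]]
    if (!nrow(d)) return(NULL)
    data.frame(channel_id = ch, event_type = "spike", start_s = d$t_s,
               end_s = d$t_s, amplitude_uv = d$amplitude_uv, band = d$band)
  }))
  if (!is.null(spikes_tbl)) write_events(spikes_tbl, p("spikes.csv"))
  spin_tbl <- do.call(rbind, lapply(names(x$spindles), function(ch) {
    d <- x$spindles[[ch]]$events
    if (!nrow(d)) return(NULL)
    cbind(data.frame(channel_id = ch, event_type = "spindle"), d)
  }))
  if (!is.null(spin_tbl)) write_events(spin_tbl, p("spindles.csv"))
  tr_tbl <- do.call(rbind, lapply(names(x$troughs), function(ch) {
    d <- x$troughs[[ch]]
    if (!nrow(d)) return(NULL)
    data.frame(channel_id = ch, event_type = "slow_wave_trough",
               start_s = d$trough_s, end_s = d$trough_s,
               trough_uv = d$trough_uv, width_s = d$width_s)
  }))
  if (!is.null(tr_tbl)) write_events(tr_tbl, p("slow_waves.csv"))
  ax_tbl <- do.call(rbind, lapply(names(x$axons), function(id) {
    d <- x$axons[[id]]
    if (!nrow(d)) return(NULL)
    cbind(data.frame(tunnel_id = id), d)
  }))
  if (!is.null(ax_tbl)) write.csv(ax_tbl, p("axons.csv"), row.names = FALSE)
  if (!is.null(x$nesting))
    jsonlite::write_json(
      list(boundary_s = x$nesting$boundary_s, slope = x$nesting$slope,
           intercept = x$nesting$intercept, r2 = x$nesting$r2,
           median_lag_s = x$nesting$median_lag_s, n = x$nesting$n),
      p("nesting.json"), auto_unbox = TRUE, digits = NA)
  cp_tbl <- do.call(rbind, lapply(names(x$coupling), function(id) {
    cp <- x$coupling[[id]]
    data.frame(tunnel_id = id, n_spikes = cp$phase$n_spikes,
               resultant_length = cp$phase$resultant_length,
               p_omnibus = cp$phase$p_omnibus,
               envcorr_r = cp$envcorr$r, envcorr_lag_s = cp$envcorr$best_lag_s)
  }))
  if (!is.null(cp_tbl)) write.csv(cp_tbl, p("coupling.csv"), row.names = FALSE)
  if (length(x$distributions)) {
    jsonlite::write_json(lapply(x$distributions, function(f)
      list(n_components = f$n_components, r2_fit = f$r2_fit,
           components = f$components, n = f$n)),
      p("distributions.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(x$log, p("run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(x)
}
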