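#' Construct a recording object
#'
#' A recording is a channels x samples matrix of extracellular voltages in
#' microvolts, together with its sampling rate, start time and channel
#' identifiers. Raw acquisitions are sampled at 25 kHz; the decimated LFP
#' produced by [downsample_lfp()] is at 1 kHz. All downstream operations
#' report times in seconds as `t = t0_s + index / rate_hz` (0-based indices);
#' intervals are half-open `[start, end)`.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param rate_hz sampling rate in Hz (> 0).
#' @param channel_ids character vector of unique electrode identifiers, one
#'   per row of `data`.
#' @param t0_s start time of the first sample in seconds.
#' @return An object of class `axo_recording`.
#' @export
recording <- function(data, rate_hz, channel_ids, t0_s = 0) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  storage.mode(data) <- "double"
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a single positive number")
  channel_ids <- as.character(channel_ids)
  if (anyDuplicated(channel_ids))
    stop("channel_ids must be unique")
  if (nrow(data) != length(channel_ids))
    stop("data has ", nrow(data), " rows but ", length(channel_ids),
         " channel_ids were given")
  structure(list(data = data, rate_hz = rate_hz, t0_s = t0_s,
                 channel_ids = channel_ids),
            class = "axo_recording")
}

#' @export
print.axo_recording <- function(x, ...) {
  cat(sprintf("<axo_recording> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$data), ncol(x$data), x$rate_hz,
              ncol(x$data) / x$rate_hz))
  cat("  channels:", paste(head(x$channel_ids, 8), collapse = ", "),
      if (length(x$channel_ids) > 8) "..." else "", "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `axo_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$rate_hz

#' Extract one channel as a numeric vector
#' @param rec an `axo_recording`.
#' @param channel_id electrode identifier.
#' @return Numeric vector of samples in microvolts.
#' @export
recording_channel <- function(rec, channel_id) {
  i <- match(channel_id, rec$channel_ids)
  if (is.na(i)) stop("unknown channel: ", channel_id)
  rec$data[i, ]
}

#' Read a raw recording from disk
#'
#' The on-disk format is a little-endian 32-bit float matrix, channel-major
#' (all samples of channel 1, then channel 2, ...), with a JSON sidecar giving
#' `rate_hz`, `channel_ids` and optionally `t0_s` (default 0) and `scale_uv`
#' (microvolts per stored count, default 1; applied on load).
#'
#' @param signal_path path to the raw float32 file.
#' @param meta_path path to the JSON metadata sidecar.
#' @return An `axo_recording` with data in microvolts.
#' @export
load_recording <- function(signal_path, meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$rate_hz) || is.null(meta$channel_ids))
    stop("metadata must contain rate_hz and channel_ids")
  nch <- length(meta$channel_ids)
  nbytes <- file.size(signal_path)
  if (nbytes %% 4L != 0L)
    stop(sprintf("format error: file size %d bytes is not a whole number of float32 samples (truncated at byte offset %d)",
                 nbytes, 4L * (nbytes %/% 4L)))
  n <- nbytes %/% 4L
  if (n %% nch != 0L)
    stop(sprintf("format error: %d samples do not divide into %d channels (truncated at byte offset %d)",
                 n, nch, 4L * nch * (n %/% nch)))
  con <- file(signal_path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
  scale <- if (is.null(meta$scale_uv)) 1 else meta$scale_uv
  m <- matrix(v * scale, nrow = nch, byrow = TRUE)
  bad <- which(!apply(is.finite(m), 1L, all))
  if (length(bad))
    stop("validation error: non-finite samples on channel(s) ",
         paste(meta$channel_ids[bad], collapse = ", "))
  recording(m, meta$rate_hz, meta$channel_ids,
            t0_s = if (is.null(meta$t0_s)) 0 else meta$t0_s)
}

#' Write a recording to disk (float32 + JSON sidecar)
#'
#' @param rec an `axo_recording`.
#' @param signal_path output path for the raw float32 file.
#' @param meta_path output path for the JSON sidecar.
#' @return Invisibly, `rec`. Round-trips with [load_recording()] to float32
#'   precision.
#' @export
write_recording <- function(rec, signal_path, meta_path) {
  stopifnot(inherits(rec, "axo_recording"))
  con <- file(signal_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$data)), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(rate_hz = rec$rate_hz, channel_ids = rec$channel_ids,
         t0_s = rec$t0_s, scale_uv = 1),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(rec)
}

.compartments <- c("EC", "DG", "CA3", "CA1")
.loop_next <- c(EC = "DG", DG = "CA3", CA3 = "CA1", CA1 = "EC")

#' Construct a channel map
#'
#' Describes electrode geometry and tunnel topology. Tunnels are recorded in
#' feed-forward orientation along the closed hippocampal loop
#' EC -> DG -> CA3 -> CA1 -> EC, each with an upstream and a downstream
#' electrode 200 um apart (default).
#'
#' @param electrodes data.frame with columns `id`, `x_um`, `y_um`,
#'   `compartment` (one of EC, DG, CA3, CA1, tunnel).
#' @param tunnels data.frame with columns `tunnel_id`, `source_compartment`,
#'   `target_compartment`, `upstream_electrode_id`, `downstream_electrode_id`
#'   and optionally `electrode_spacing_um` (default 200).
#' @return An object of class `axo_channel_map`.
#' @export
channel_map <- function(electrodes, tunnels) {
  electrodes <- as.data.frame(electrodes)
  tunnels <- as.data.frame(tunnels)
  if (anyDuplicated(electrodes$id))
    stop("validation error: duplicate electrode ids")
  ok <- electrodes$compartment %in% c(.compartments, "tunnel")
  if (!all(ok))
    stop("validation error: unknown compartment(s): ",
         paste(unique(electrodes$compartment[!ok]), collapse = ", "))
  if (is.null(tunnels$electrode_spacing_um)) {
    message("electrode_spacing_um not given; defaulting to 200 um")
    tunnels$electrode_spacing_um <- 200
  }
  tunnels$electrode_spacing_um[is.na(tunnels$electrode_spacing_um)] <- 200
  if (any(tunnels$electrode_spacing_um <= 0))
    stop("validation error: electrode_spacing_um must be positive")
  for (col in c("upstream_electrode_id", "downstream_electrode_id")) {
    miss <- !(tunnels[[col]] %in% electrodes$id)
    if (any(miss))
      stop("validation error: tunnel references unknown electrode(s): ",
           paste(tunnels[[col]][miss], collapse = ", "))
  }
  if (any(tunnels$upstream_electrode_id == tunnels$downstream_electrode_id))
    stop("validation error: tunnel electrodes must be distinct")
  badpair <- .loop_next[tunnels$source_compartment] != tunnels$target_compartment
  if (any(is.na(badpair)) || any(badpair))
    stop("validation error: tunnel source->target must be an adjacent pair of the loop EC->DG->CA3->CA1->EC")
  structure(list(electrodes = electrodes, tunnels = tunnels),
            class = "axo_channel_map")
}

#' @export
print.axo_channel_map <- function(x, ...) {
  cat(sprintf("<axo_channel_map> %d electrodes, %d tunnels\n",
              nrow(x$electrodes), nrow(x$tunnels)))
  invisible(x)
}

#' Read a channel map from JSON
#' @param path path to a JSON file with `electrodes` and `tunnels` records.
#' @return An `axo_channel_map`.
#' @export
load_channel_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  channel_map(obj$electrodes, obj$tunnels)
}

#' Write a channel map to JSON
#' @param map an `axo_channel_map`.
#' @param path output path.
#' @return Invisibly, `map`.
#' @export
write_channel_map <- function(map, path) {
  stopifnot(inherits(map, "axo_channel_map"))
  jsonlite::write_json(list(electrodes = map$electrodes, tunnels = map$tunnels),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(map)
}

#' Look up the electrode pair of a tunnel
#'
#' @param map an `axo_channel_map`.
#' @param source,target compartments of the tunnel in feed-forward
#'   orientation (e.g. "DG", "CA3").
#' @param direction "feedforward" returns (upstream, downstream) along the
#'   loop; "feedback" returns the reversed pair. Flipping direction twice is
#'   the identity.
#' @return list with `upstream`, `downstream`, `spacing_um`, `tunnel_id`.
#' @export
tunnel_electrodes <- function(map, source, target,
                              direction = c("feedforward", "feedback")) {
  direction <- match.arg(direction)
  tun <- map$tunnels
  i <- which(tun$source_compartment == source & tun$target_compartment == target)
  if (!length(i)) stop("no tunnel ", source, "->", target, " in map")
  tun <- tun[i[1L], ]
  pair <- c(tun$upstream_electrode_id, tun$downstream_electrode_id)
  if (direction == "feedback") pair <- rev(pair)
  list(upstream = pair[1L], downstream = pair[2L],
       spacing_um = tun$electrode_spacing_um, tunnel_id = tun$tunnel_id)
}

#' Write an event table to CSV
#'
#' Event tables are data.frames with at least `channel_id`, `event_type`,
#' `start_s`, `end_s` plus any per-event payload columns. Times are written
#' in seconds with sub-millisecond precision and round-trip losslessly at
#' 1 ms resolution via [read_events()].
#'
#' @param table event data.frame.
#' @param path output CSV path.
#' @return Invisibly, the table as written (sorted by start time within
#'   channel).
#' @export
write_events <- function(table, path) {
  table <- as.data.frame(table)
  need <- c("channel_id", "event_type", "start_s", "end_s")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("event table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(table$start_s > table$end_s))
    stop("validation error: start_s > end_s")
  table <- table[order(table$channel_id, table$start_s), , drop = FALSE]
  ok <- tryCatch({ write.csv(table, path, row.names = FALSE); TRUE },
                 error = function(e) stop("I/O error writing ", path, ": ",
                                          conditionMessage(e)))
  invisible(table)
}

#' Read an event table written by [write_events()]
#' @param path CSV path.
#' @return Event data.frame.
#' @export
read_events <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
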