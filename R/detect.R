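#' Band-pass filter an extracellular trace
#'
#' Applies a 2nd-order Butterworth band-pass (default 100-3500 Hz) in the
#' forward direction only (causal), removing slow field potentials and
#' high-frequency noise ahead of spike detection.
#'
#' @param trace Numeric vector of voltage samples (uV).
#' @param fs_khz Sampling rate in kHz; must exceed 7 kHz so the upper band
#'   edge stays below the Nyquist frequency.
#' @param band Passband edges in Hz.
#' @return Filtered trace, same length.
#' @export
bandpass <- function(trace, fs_khz, band = c(100, 3500)) {
  if (fs_khz * 1000 / 2 <= band[2])
    stop("sampling rate too low: Nyquist must exceed ", band[2], " Hz")
  bf <- signal::butter(2, band / (fs_khz * 1000 / 2), type = "pass")
  as.numeric(signal::filter(bf, trace))
}

#' Robust noise estimate of a trace
#'
#' Estimates the background-noise standard deviation as
#' `s_V = 1.4826 * MAD`, the consistent robust estimator of a Gaussian SD
#' that is insensitive to the spikes riding on the trace.
#'
#' @param trace Numeric vector (length >= 2).
#' @return `s_V` in the units of `trace` (uV).
#' @export
noise_sd <- function(trace) {
  if (length(trace) < 2) stop("'trace' must have at least 2 samples")
  stats::mad(trace)  # constant 1.4826 is mad()'s default
}

#' Threshold spike detection
#'
#' Detects negative signal peaks below `-k * s_V` on a band-pass-filtered
#' trace: every local minimum under the threshold is an event; among events
#' closer together than the dead time only the first is kept, avoiding
#' multiple detection of the same spike. The first `transient_ms` of the
#' trace are excluded from the noise estimate (causal filter transient).
#'
#' @param trace Filtered numeric vector (uV).
#' @param fs_khz Sampling rate (kHz).
#' @param k Threshold multiplier on `s_V` (default 5).
#' @param dead_time_ms Minimum separation of events (ms, default 0.5).
#' @param s_v Optional externally supplied noise SD; estimated from the
#'   trace by [noise_sd()] when `NULL`.
#' @param transient_ms Initial stretch excluded from noise estimation.
#' @return Data frame with columns `sample` (1-based index), `time_ms`, and
#'   `amplitude_uV` (the negative peak value), plus attribute `s_v`.
#' @export
detect_spikes <- function(trace, fs_khz, k = 5, dead_time_ms = 0.5,
                          s_v = NULL, transient_ms = 10) {
  n <- length(trace)
  if (is.null(s_v)) {
    skip <- min(n - 2L, round(transient_ms * fs_khz))
    s_v <- noise_sd(trace[(skip + 1L):n])
  }
  thr <- -k * s_v
  empty <- data.frame(sample = integer(), time_ms = numeric(),
                      amplitude_uV = numeric())
  if (n < 3 || !any(trace < thr))
    return(structure(empty, s_v = s_v))
  mid <- 2:(n - 1L)
  is_min <- trace[mid] < trace[mid - 1L] & trace[mid] <= trace[mid + 1L] &
    trace[mid] < thr
  idx <- mid[is_min]
  if (!length(idx)) return(structure(empty, s_v = s_v))
  # dead time: keep the first event of any run closer than dead_time_ms
  keep <- idx[1]
  last <- idx[1]
  for (i in idx[-1]) {
    if ((i - last) / fs_khz >= dead_time_ms) {
      keep <- c(keep, i)
      last <- i
    }
  }
  structure(data.frame(sample = keep, time_ms = (keep - 1L) / fs_khz,
                       amplitude_uV = trace[keep]),
            s_v = s_v)
}

#' Detect spikes on every electrode of a recording block
#'
#' Band-pass filters each trace and runs [detect_spikes()], returning the
#' pooled event table used for activity mapping.
#'
#' @param block A `recording_block` (see [simulate_recording()]).
#' @param k,dead_time_ms As in [detect_spikes()].
#' @param band Passband (Hz); set `NULL` to skip filtering (already
#'   filtered or synthetic band-limited data).
#' @return Data frame `electrode_id`, `time_ms`, `amplitude_uV`.
#' @export
detect_block <- function(block, k = 5, dead_time_ms = 0.5,
                         band = c(100, 3500)) {
  out <- lapply(seq_len(nrow(block$traces)), function(i) {
    tr <- block$traces[i, ]
    if (!is.null(band)) tr <- bandpass(tr, block$fs_khz, band)
    ev <- detect_spikes(tr, block$fs_khz, k, dead_time_ms)
    if (!nrow(ev)) return(NULL)
    data.frame(electrode_id = block$electrode_id[i], time_ms = ev$time_ms,
               amplitude_uV = ev$amplitude_uV)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(electrode_id = integer(), time_ms = numeric(),
                      amplitude_uV = numeric())
  out
}

#' Whole-array activity map
#'
#' Summarises a block-scan event table per electrode: spike count and the
#' median negative-peak amplitude. Local minima of the median amplitude map
#' mark putative axon-initial-segment (AIS) locations.
#'
#' @param events Data frame `electrode_id`, `time_ms`, `amplitude_uV` (e.g.
#'   from [detect_block()]).
#' @param electrode_ids All electrode ids of the scan; electrodes without
#'   events get count 0 and `NA` amplitude.
#' @return Data frame of class `activity_map`: `electrode_id`, `count`,
#'   `median_amp_uV`.
#' @export
activity_map <- function(events, electrode_ids) {
  cnt <- table(factor(events$electrode_id, levels = electrode_ids))
  med <- tapply(events$amplitude_uV,
                factor(events$electrode_id, levels = electrode_ids),
                stats::median)
  structure(data.frame(electrode_id = electrode_ids,
                       count = as.integer(cnt),
                       median_amp_uV = as.numeric(med)),
            class = c("activity_map", "data.frame"))
}

#' Select fixed (trigger) electrodes
#'
#' Greedy spatial selection of trigger electrodes at putative AIS sites:
#' electrodes are ranked by most-negative median peak amplitude; after each
#' pick, every electrode within `min_dist_um` is discarded, so the same
#' neuron is not recorded twice.
#'
#' Ties in the ranking are broken by lower electrode id.
#'
#' @param map An [activity_map()].
#' @param layout A [hex_layout()] sharing the map's electrode ids.
#' @param min_dist_um Exclusion radius (um, default 100).
#' @param max_n Maximum number of fixed electrodes.
#' @return Integer vector of selected electrode ids, in rank order.
#' @export
select_fixed_electrodes <- function(map, layout, min_dist_um = 100,
                                    max_n = Inf) {
  stopifnot(inherits(layout, "hex_layout"))
  cand <- map[map$count > 0 & !is.na(map$median_amp_uV), , drop = FALSE]
  if (!nrow(cand)) return(integer())
  cand <- cand[order(cand$median_amp_uV, cand$electrode_id), , drop = FALSE]
  pos <- layout[match(cand$electrode_id, layout$id), c("x_um", "y_um")]
  sel <- integer()
  alive <- rep(TRUE, nrow(cand))
  while (any(alive) && length(sel) < max_n) {
    i <- which(alive)[1L]
    sel <- c(sel, cand$electrode_id[i])
    d <- sqrt((pos$x_um - pos$x_um[i])^2 + (pos$y_um - pos$y_um[i])^2)
    alive <- alive & d > min_dist_um
  }
  sel
}
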