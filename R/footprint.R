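#' Construct an electrical footprint
#'
#' A footprint is the spatial map of spike-triggered-average (STA)
#' extracellular waveforms of one neuron across the array. From the averaged
#' waveforms three per-electrode statistics are derived:
#'
#' * `v_n` — negative-peak amplitude, reported as a positive magnitude in
#'   microvolts (`-min` of the averaged trace);
#' * `tau_ms` — delay of that negative peak relative to the trigger, in ms;
#' * `s_n` — residual noise of the averaged trace, estimated robustly as
#'   `1.4826 * MAD` of the samples excluding +/- 1 ms around the peak.
#'
#' The putative axon initial segment (AIS) is the electrode with the largest
#' `v_n` among `fixed_ids` (or among all electrodes when `fixed_ids` is
#' `NULL`); its delay `tau_ais` anchors the causality gate used by the
#' delay-based segmentation.
#'
#' @param waveforms Numeric matrix, electrodes x samples, in microvolts.
#' @param t_ms Numeric vector of sample times relative to the trigger (ms);
#'   length must equal `ncol(waveforms)` and span the STA window
#'   `[t_pre, t_post]` with total length `T = t_post - t_pre`.
#' @param electrode_id Integer electrode ids, one per row.
#' @param n_spikes Number of spikes averaged (scalar or per electrode).
#' @param fixed_ids Optional ids of fixed (trigger) electrodes used to
#'   locate the AIS.
#' @param neuron Optional neuron identifier.
#' @return An object of class `axon_footprint`: a list with elements
#'   `waveforms`, `t_ms`, `electrode_id`, `n_spikes`, `v_n`, `tau_ms`,
#'   `s_n`, `ais_electrode`, `tau_ais`, `window_ms`, `neuron`.
#' @export
footprint <- function(waveforms, t_ms, electrode_id, n_spikes,
                      fixed_ids = NULL, neuron = NA) {
  waveforms <- as.matrix(waveforms)
  dimnames(waveforms) <- NULL
  if (ncol(waveforms) != length(t_ms))
    stop("ncol(waveforms) must equal length(t_ms)")
  if (nrow(waveforms) != length(electrode_id))
    stop("nrow(waveforms) must equal length(electrode_id)")
  peak <- apply(waveforms, 1L, which.min)
  v_n <- -waveforms[cbind(seq_len(nrow(waveforms)), peak)]
  tau <- t_ms[peak]
  s_n <- vapply(seq_len(nrow(waveforms)), function(i) {
    keep <- abs(t_ms - tau[i]) > 1
    stats::mad(waveforms[i, keep])
  }, numeric(1))
  s_n[s_n <= 0] <- .Machine$double.eps  # flat traces: keep s_n positive
  cand <- if (is.null(fixed_ids)) seq_along(electrode_id)
          else which(electrode_id %in% fixed_ids)
  if (!length(cand)) cand <- seq_along(electrode_id)
  ais <- cand[which.max(v_n[cand])]
  structure(list(
    waveforms = waveforms, t_ms = t_ms,
    electrode_id = as.integer(electrode_id),
    n_spikes = if (length(n_spikes) == 1L)
      rep(as.integer(n_spikes), nrow(waveforms)) else as.integer(n_spikes),
    v_n = v_n, tau_ms = tau, s_n = s_n,
    ais_electrode = electrode_id[ais], tau_ais = tau[ais],
    window_ms = c(min(t_ms), max(t_ms)),
    neuron = neuron
  ), class = "axon_footprint")
}

#' STA window length of a footprint
#'
#' @param fp An `axon_footprint`.
#' @return Total STA window length `T = t_post - t_pre` in ms.
#' @export
footprint_window <- function(fp) {
  stopifnot(inherits(fp, "axon_footprint"))
  diff(fp$window_ms)
}

#' @export
print.axon_footprint <- function(x, ...) {
  cat(sprintf("Electrical footprint%s: %d electrodes, STA window [%g, %g] ms\n",
              if (is.na(x$neuron)) "" else paste0(" (neuron ", x$neuron, ")"),
              nrow(x$waveforms), x$window_ms[1], x$window_ms[2]))
  cat(sprintf("  AIS electrode %d (V = %.1f uV at tau = %.2f ms); median n_spikes %d\n",
              x$ais_electrode, max(x$v_n), x$tau_ais,
              as.integer(stats::median(x$n_spikes))))
  cat(sprintf("  amplitude range %.2f..%.1f uV, median residual noise %.2f uV\n",
              min(x$v_n), max(x$v_n), stats::median(x$s_n)))
  invisible(x)
}

#' Plot an electrical footprint
#'
#' Draws the amplitude map (circle area proportional to `sqrt(v_n)`) with
#' the negative-peak delay colour-coded, the standard display for
#' HD-MEA axonal footprints.
#'
#' @param x An `axon_footprint`.
#' @param layout A [hex_layout()] supplying electrode positions.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.axon_footprint <- function(x, layout, ...) {
  stopifnot(inherits(layout, "hex_layout"))
  i <- match(x$electrode_id, layout$id)
  pal <- grDevices::hcl.colors(64, "viridis")
  tr <- range(x$tau_ms)
  col <- pal[pmax(1L, ceiling(64 * (x$tau_ms - tr[1]) / max(diff(tr), 1e-9)))]
  graphics::plot(layout$x_um[i], layout$y_um[i], asp = 1,
                 cex = 2.5 * sqrt(x$v_n / max(x$v_n)), pch = 16, col = col,
                 xlab = "x (um)", ylab = "y (um)", ...)
  j <- which(x$electrode_id == x$ais_electrode)
  graphics::points(layout$x_um[i[j]], layout$y_um[i[j]], pch = 3, cex = 2)
  invisible(x)
}
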