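# Shared fixtures, built in code.

# a bounded simulation on a mid-sized array at the standard operating point:
# 5 uV RMS noise, 14 averaged spikes, c = 0.35 m/s, 18 um pitch, T = 8 ms
paper_like_neuron <- function(seed, n_rows = 40, n_cols = 40, pitch = 18,
                              n_spikes = 14, ...) {
  lay <- hex_layout(n_rows, n_cols, pitch)
  margin <- 2 * pitch
  bounds <- c(margin, max(lay$x_um) - margin, margin, max(lay$y_um) - margin)
  cfg <- sim_config(soma = c(mean(lay$x_um), mean(lay$y_um)),
                    bounds = bounds, seed = seed, ...)
  arb <- grow_arbor(cfg)
  list(layout = lay, cfg = cfg, arbor = arb,
       fp = render_footprint(arb, lay, cfg, n_spikes = n_spikes))
}

# hand-built footprint whose per-electrode delays are prescribed exactly:
# one unit negative pulse at tau per electrode, no noise
delay_footprint <- function(layout, tau_ms, t_pre = -2, t_post = 6,
                            fs_khz = 20, amp = 50) {
  t_ms <- seq(t_pre, t_post, by = 1 / fs_khz)
  wav <- t(vapply(tau_ms, function(tau) {
    w <- numeric(length(t_ms))
    w[which.min(abs(t_ms - tau))] <- -amp
    w
  }, numeric(length(t_ms))))
  footprint(wav, t_ms, layout$id, n_spikes = 1)
}

# directed-sup-inf brute-force Hausdorff oracle
hausdorff_oracle <- function(A, E) {
  d <- function(P, Q) {
    max(apply(P, 1, function(p)
      min(sqrt((Q[, 1] - p[1])^2 + (Q[, 2] - p[2])^2))))
  }
  max(d(A, E), d(E, A))
}

# distance of each layout electrode to the closest arbor point
dist_to_arbor <- function(layout, arbor, spacing = 2) {
  gt <- ground_truth_points(arbor, spacing)
  vapply(seq_len(nrow(layout)), function(i)
    min(sqrt((gt[, 1] - layout$x_um[i])^2 + (gt[, 2] - layout$y_um[i])^2)),
    numeric(1))
}
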