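test_that("arbor growth is seeded, bounded and branches at the set rate", {
  cfg0 <- sim_config(branch_prob = 0, angle_sd_rad = 0, max_length_um = 300,
                     seed = 4)
  straight <- grow_arbor(cfg0)
  expect_length(straight$branches, 1)
  expect_equal(max(straight$branches[[1]]$pathlen), 300)

  cfg <- sim_config(seed = 11)
  expect_identical(grow_arbor(cfg), grow_arbor(cfg))
  expect_false(identical(grow_arbor(cfg), grow_arbor(cfg, seed = 12)))

  # Monte-Carlo branch count vs the binomial expectation: 30 growth steps
  # with branching probability p each give 1 + Binomial(30, p) branches
  p <- 0.05
  cfgb <- sim_config(branch_prob = p, max_length_um = 300, step_um = 10)
  counts <- vapply(1:400, function(s)
    length(grow_arbor(cfgb, seed = s)$branches), numeric(1))
  expected <- 1 + 30 * p
  se <- sqrt(30 * p * (1 - p) / 400)
  expect_lt(abs(mean(counts) - expected), 3 * se)

  # bounded growth stays inside the box
  cfgbox <- sim_config(bounds = c(0, 100, 0, 80), soma = c(50, 40),
                       max_length_um = 2000, seed = 2)
  pts <- do.call(rbind, lapply(grow_arbor(cfgbox)$branches, `[[`, "points"))
  expect_true(all(pts[, 1] >= 0 & pts[, 1] <= 100))
  expect_true(all(pts[, 2] >= 0 & pts[, 2] <= 80))
})

test_that("conduction delays are path length over velocity", {
  cfg <- sim_config(branch_prob = 0, angle_sd_rad = 0, max_length_um = 300)
  arb <- grow_arbor(cfg, seed = 1)
  d <- arbor_delays(arb, 0.3)
  expect_equal(d[[1]][1], 0)                    # soma
  expect_equal(max(d[[1]]), 1.0)                # 300 um / 0.3 m/s = 1 ms

  # delays non-decreasing along every branch of random arbors
  for (s in 1:5) {
    arb <- grow_arbor(sim_config(branch_prob = 0.05, seed = s))
    for (del in arbor_delays(arb, 0.35)) expect_true(all(diff(del) >= 0))
  }
  expect_error(arbor_delays(arb, 0), "velocity")
})

test_that("ground-truth resampling stays on the polyline at the set spacing", {
  cfg <- sim_config(branch_prob = 0, angle_sd_rad = 0, max_length_um = 100)
  arb <- grow_arbor(cfg, seed = 3)
  pts <- ground_truth_points(arb, 10)
  expect_equal(nrow(pts), 11)                   # 100 um at 10 um spacing

  # resampled points lie on the original (straight) polyline
  p0 <- arb$branches[[1]]$points[1, ]
  p1 <- arb$branches[[1]]$points[nrow(arb$branches[[1]]$points), ]
  v <- p1 - p0
  cross <- (pts[, 1] - p0[1]) * v[2] - (pts[, 2] - p0[2]) * v[1]
  expect_equal(max(abs(cross)), 0, tolerance = 1e-9)

  # spacing -> 0: the resampled set converges (in Hausdorff distance) to
  # the densely resampled polyline
  arb2 <- grow_arbor(sim_config(branch_prob = 0.05, seed = 9))
  dense <- ground_truth_points(arb2, 0.5)
  for (sp in c(20, 5, 1)) {
    h <- hausdorff_distance(ground_truth_points(arb2, sp), dense)
    expect_lte(h, sp / 2 + 0.5)
  }
})

test_that("rendered footprints follow the delay and decay forward model", {
  lay <- hex_layout(14, 14, 18)
  cfg <- sim_config(soma = c(110, 100), bounds = c(30, 200, 30, 170),
                    noise_uV = 0, max_length_um = 600, seed = 5)
  arb <- grow_arbor(cfg)
  fp <- render_footprint(arb, lay, cfg, n_spikes = 1)

  # with no noise, negative-peak delays of near-arbor electrodes equal the
  # nearest arbor point's delay to within the sample period
  darb <- dist_to_arbor(lay, arb)
  near <- which(darb < 10 & fp$tau_ms > 0.2)
  expect_gt(length(near), 5)
  pts <- do.call(rbind, lapply(seq_along(arb$branches), function(i)
    cbind(arb$branches[[i]]$points,
          arbor_delays(arb, cfg$velocity_mps)[[i]])))
  for (i in near) {
    d2 <- (pts[, 1] - lay$x_um[i])^2 + (pts[, 2] - lay$y_um[i])^2
    expect_lt(abs(fp$tau_ms[i] - pts[which.min(d2), 3]), 0.04)
  }

  # amplitude decay: an electrode > 10 decay lengths from the arbor sees
  # < 1% of the template amplitude (AIS source switched off)
  cfgd <- sim_config(soma = c(50, 50), bounds = c(30, 110, 30, 110),
                     noise_uV = 0, ais_amp_uV = 0, amp_range_uV = c(15, 15),
                     max_length_um = 300, seed = 5)
  arbd <- grow_arbor(cfgd)
  fpd <- render_footprint(arbd, lay, cfgd, n_spikes = 1)
  fard <- which(dist_to_arbor(lay, arbd) > 10 * cfgd$lambda_um)
  expect_gt(length(fard), 0)
  expect_lt(max(fpd$v_n[fard]), 0.01 * 15)

  # averaging 14 trials leaves ~0.27 of the single-trial noise on
  # signal-free electrodes
  cfg2 <- sim_config(soma = c(110, 100), noise_uV = 5,
                     amp_range_uV = c(0, 0), ais_amp_uV = 0, seed = 6)
  fp14 <- render_footprint(grow_arbor(cfg2), lay, cfg2, n_spikes = 14)
  resid <- apply(fp14$waveforms, 1, sd)
  expect_equal(mean(resid), 5 / sqrt(14), tolerance = 0.05)
  expect_equal(round(1 / sqrt(14), 2), 0.27)
})

test_that("simulated recordings carry Poisson spikes recoverable by detection", {
  lay <- hex_layout(4, 4, 18)
  cfg <- sim_config(soma = c(27, 23), rate_hz = 0, noise_uV = 5, seed = 7)
  arb <- grow_arbor(cfg)
  silent <- simulate_recording(arb, lay, cfg, duration_s = 1)
  expect_length(silent$spike_times_ms[[1]], 0)
  expect_equal(sd(silent$traces), 5, tolerance = 0.05)

  # Poisson event count at 1 Hz for 115 s
  cfg1 <- sim_config(soma = c(27, 23), rate_hz = 1, seed = 8)
  rec <- simulate_recording(arb, lay, cfg1, duration_s = 115)
  expect_lt(abs(length(rec$spike_times_ms[[1]]) - 115), 3 * sqrt(115))

  # closed loop: detection on the electrode over the AIS recovers >= 95%
  # of the true events at this SNR
  cfg2 <- sim_config(soma = c(27, 23), rate_hz = 3, noise_uV = 5, seed = 9)
  rec2 <- simulate_recording(arb, lay, cfg2, duration_s = 20)
  dsoma <- sqrt((lay$x_um - 27)^2 + (lay$y_um - 23)^2)
  tr <- bandpass(rec2$traces[which.min(dsoma), ], rec2$fs_khz)
  ev <- detect_spikes(tr, rec2$fs_khz)
  truth <- rec2$spike_times_ms[[1]]
  hit <- vapply(truth, function(t0) any(abs(ev$time_ms - t0) < 1), logical(1))
  expect_gte(mean(hit), 0.95)

  # determinism end to end
  expect_identical(simulate_recording(arb, lay, cfg2, 2),
                   simulate_recording(arb, lay, cfg2, 2))
})
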