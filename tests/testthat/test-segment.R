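test_that("delay-SD map computes neighbourhood sample SDs", {
  lay <- hex_layout(5, 7, 18)
  # assign delays so one interior electrode's 7-member patch holds 0..6 ms
  center <- 17  # row 2, col 3: interior
  nb <- hex_neighborhood(lay, center, 1)
  tau <- rep(2, nrow(lay))
  tau[match(nb, lay$id)] <- 0:6
  fp <- delay_footprint(lay, tau)
  dm <- delay_sd_map(fp, lay, min_members = 5)
  i <- match(center, lay$id)
  expect_equal(dm$s_tau_ms[i], sd(0:6), tolerance = 1e-9)
  expect_equal(sd(0:6), 2.160247, tolerance = 1e-6)

  # all delays equal: zero SD everywhere valid
  fp0 <- delay_footprint(lay, rep(1.5, nrow(lay)))
  dm0 <- delay_sd_map(fp0, lay)
  expect_true(all(dm0$s_tau_ms[dm0$valid] == 0))

  # edge electrodes have small neighbourhoods and are invalid
  expect_false(dm$valid[1])
  expect_true(all(dm$n_members[!dm$valid] < 5))

  # shift invariance: adding a constant to all delays leaves the map alone
  set.seed(22)
  tau2 <- runif(nrow(lay), 0, 4)
  dm2 <- delay_sd_map(delay_footprint(lay, tau2), lay)
  dm2s <- delay_sd_map(delay_footprint(lay, tau2 + 1.3), lay)
  expect_equal(dm2s$s_tau_ms, dm2$s_tau_ms, tolerance = 1e-9)
})

test_that("expected delay SDs match their uniform-interval derivations", {
  # background: T/sqrt(12), 2.3 ms at T = 8
  expect_equal(round(expected_background_sd(8), 1), 2.3)
  expect_equal(expected_background_sd(0), 0)
  # the sample SD of N = 7 draws has a small negative bias relative to the
  # population SD, so the Monte-Carlo mean sits ~2-3% below T/sqrt(12)
  set.seed(10)
  mc <- mean(replicate(1e4, sd(runif(7, 0, 8))))
  expect_equal(mc, expected_background_sd(8), tolerance = 0.03)

  # axonal: r/(c sqrt(3)) microseconds; ~30 us over 0.3-0.44 m/s at 18 um
  expect_equal(expected_axon_sd(18, 0.3), 34.64, tolerance = 1e-3)
  expect_equal(expected_axon_sd(0, 0.3), 0)
  rng <- expected_axon_sd(18, c(0.3, 0.44))
  expect_equal(round(mean(rng) / 10) * 10, 30)
  expect_error(expected_axon_sd(18, 0), "> 0")

  # equals the Monte-Carlo mean sample SD of delays uniform on width 2r/c
  width <- 2 * 18 / 0.35  # us
  expect_equal(width / sqrt(12), expected_axon_sd(18, 0.35), tolerance = 1e-9)
  mc2 <- mean(replicate(1e4, sd(runif(7, 0, width))))
  expect_equal(mc2, expected_axon_sd(18, 0.35), tolerance = 0.03)
})

test_that("valley threshold lands at the density minimum between the modes", {
  # bimodal mixture with known components: find the analytic minimum
  T_ms <- 8
  set.seed(11)
  n <- 2000
  s <- c(rtruncexp(round(0.3 * n), 80), rbeta(round(0.7 * n), 14, 36)) *
    (T_ms / 2)
  s_min <- threshold_from_valley(s, T_ms)
  expect_equal(attr(s_min, "method"), "valley")

  dens <- function(x) 0.3 * dtruncexp(x / 4, 80) / 4 +
    0.7 * dbeta(x / 4, 14, 36) / 4
  grid <- 10^seq(log10(0.02), log10(1.5), length.out = 2000)
  # minimum of the density *per log-s* (the histogram is log-binned)
  true_min <- grid[which.min(dens(grid) * grid)]
  expect_lt(abs(log10(s_min) - log10(true_min)), 0.35)

  # background-only scores: no axonal mode, NA threshold
  set.seed(12)
  bg <- rbeta(2000, 14, 36) * (T_ms / 2)
  s_bg <- threshold_from_valley(bg, T_ms)
  expect_true(is.na(s_bg))
  expect_equal(attr(s_bg, "method"), "none")

  expect_error(threshold_from_valley(runif(10), 8), "at least 50")
})

test_that("delay-based segmentation recovers the arbor and rejects noise", {
  # low-noise footprint of a straight axon leading away from the soma:
  # almost all electrodes within one pitch of the arbor (and clear of the
  # dominant AIS field) are selected, essentially none beyond three
  # pitches (where the decaying signal is buried in the noise)
  lay <- hex_layout(40, 40, 18)
  cfg <- sim_config(soma = c(120, 120), init_dir_rad = pi / 4,
                    angle_sd_rad = 0.05, branch_prob = 0,
                    max_length_um = 600, noise_uV = 1.5,
                    amp_range_uV = c(15, 15), seed = 31)
  arbor <- grow_arbor(cfg)
  nrn <- list(layout = lay, cfg = cfg, arbor = arbor,
              fp = render_footprint(arbor, lay, cfg, n_spikes = 14))
  seg <- segment_axon(nrn$fp, nrn$layout)
  darb <- dist_to_arbor(nrn$layout, nrn$arbor)
  dsoma <- sqrt((lay$x_um - 120)^2 + (lay$y_um - 120)^2)
  dm <- seg$map
  gate <- dm$tau_ms > nrn$fp$tau_ais + 0.05
  near <- which(darb <= 18 & dsoma > 120 & dm$valid & gate)
  expect_gt(length(near), 30)
  expect_gte(mean(near %in% match(seg$electrodes, nrn$layout$id)), 0.9)
  far <- match(seg$electrodes, nrn$layout$id)
  expect_lte(sum(darb[far] > 3 * 18), 0.02 * length(far))

  # pure-noise footprint: empty or near-empty selection
  lay <- nrn$layout
  set.seed(13)
  noise_fp <- footprint(matrix(rnorm(nrow(lay) * 161, sd = 1), nrow(lay)),
                        seq(-2, 6, by = 0.05), lay$id, n_spikes = 14)
  seg0 <- segment_axon(noise_fp, lay)
  expect_lte(length(seg0$electrodes), 0.05 * nrow(lay))

  # electrodes with smooth delays *before* the AIS peak are excluded
  expect_true(all(dm$tau_ms[match(seg$electrodes, dm$electrode_id)] >
                    nrn$fp$tau_ais + 0.05))

  # amplitude-rescaling invariance: method II uses delays only
  fp3 <- footprint(nrn$fp$waveforms * 3, nrn$fp$t_ms, nrn$fp$electrode_id,
                   nrn$fp$n_spikes)
  seg3 <- segment_axon(fp3, nrn$layout)
  expect_setequal(seg3$electrodes, seg$electrodes)
})

test_that("amplitude-threshold segmentation is monotone and less sensitive", {
  lay <- hex_layout(6, 6, 18)
  t_ms <- seq(-2, 6, by = 0.05)
  # craft a footprint whose best score is 4 sigma: k = 5 selects nothing
  set.seed(14)
  wav <- matrix(rnorm(36 * length(t_ms)), 36)
  wav[5, 80] <- -4 * mad(wav[5, -(60:100)])
  fp <- footprint(wav, t_ms, lay$id, 1)
  expect_length(segment_axon(fp, lay, "I", k = 5)$electrodes, 0)

  # lowering k never removes electrodes
  nrn <- paper_like_neuron(32)
  s5 <- segment_axon(nrn$fp, nrn$layout, "I", k = 5)
  s3 <- segment_axon(nrn$fp, nrn$layout, "I", k = 3)
  expect_true(all(s5$electrodes %in% s3$electrodes))

  # weak axonal signals fall below 5 s_n but still have locked delays, so
  # the delay method captures electrodes that amplitude thresholding
  # misses, and separates the score classes better overall (larger AUC)
  seg2 <- segment_axon(nrn$fp, nrn$layout, "II")
  expect_gt(length(seg2$electrodes), 20)
  missed <- setdiff(seg2$electrodes, s5$electrodes)
  expect_gt(length(missed) / length(seg2$electrodes), 0.1)
  tab <- compare_methods(list(nrn$fp), nrn$layout)
  expect_gt(tab$auc_II, tab$auc_I)
})
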