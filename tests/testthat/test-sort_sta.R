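test_that("waveform extraction centres 61-sample windows on the peak", {
  fs <- 20
  tr <- rnorm(61)
  tr[31] <- -10  # global minimum at the centre
  ev <- data.frame(sample = 31)
  w <- extract_waveforms(tr, ev, fs)
  expect_equal(dim(w), c(1L, 61L))
  expect_equal(as.numeric(w[1, ]), tr)

  # events too close to the edge are excluded and counted
  ev2 <- data.frame(sample = c(5, 31, 60))
  w2 <- extract_waveforms(tr, ev2, fs)
  expect_equal(nrow(w2), 1)
  expect_equal(attr(w2, "n_excluded"), 2L)

  # every row of detected-event waveforms has its minimum at the centre
  set.seed(6)
  tr3 <- rnorm(20000, sd = 5)
  tr3[seq(1000, 19000, by = 1500)] <- runif(13, -120, -60)
  ev3 <- detect_spikes(tr3, fs, s_v = 5)
  w3 <- extract_waveforms(tr3, ev3, fs)
  expect_gt(nrow(w3), 5)
  expect_true(all(apply(w3, 1, which.min) == attr(w3, "center")))
})

test_that("PCA features capture the waveform energy", {
  # waveforms lying in an exact 2-D subspace
  set.seed(7)
  basis <- matrix(rnorm(2 * 61), 2, 61)
  coef <- matrix(rnorm(80), 40, 2)
  waves <- coef %*% basis
  f2 <- pca_features(waves, n_components = 2)
  expect_equal(attr(f2, "energy_fraction"), 1, tolerance = 1e-10)

  # reference eigen-decomposition of the covariance on a fixed matrix
  m <- matrix(sin(seq_len(20 * 61) / 7) + rep(rnorm(20), 61), 20, 61)
  f <- pca_features(m, n_components = 3)
  cv <- cov(m)
  eg <- eigen(cv, symmetric = TRUE)
  ref <- scale(m, center = TRUE, scale = FALSE) %*% eg$vectors[, 1:3]
  for (k in 1:3) {
    expect_equal(abs(cor(f[, k], ref[, k])), 1, tolerance = 1e-6)
  }
  expect_equal(attr(f, "energy_fraction"),
               sum(eg$values[1:3]) / sum(eg$values), tolerance = 1e-8)

  # a two-template mixture at realistic SNR concentrates > 85% of the
  # energy in the first ten components
  t_ms <- seq(-1.5, 1.5, by = 0.05)
  tpl1 <- -200 * exp(-t_ms^2 / 0.02)
  tpl2 <- -120 * exp(-t_ms^2 / 0.08) + 40 * exp(-(t_ms - 0.5)^2 / 0.1)
  mix <- rbind(t(replicate(150, tpl1 + rnorm(61, sd = 5))),
               t(replicate(150, tpl2 + rnorm(61, sd = 5))))
  f10 <- pca_features(mix, n_components = 10)
  expect_gte(attr(f10, "energy_fraction"), 0.85)

  expect_error(pca_features(mix[1:5, ], n_components = 10), "at least")
})

test_that("mixture clustering separates units and is label-agnostic", {
  set.seed(8)
  blob1 <- cbind(rnorm(120), rnorm(120))
  blob2 <- cbind(rnorm(120) + 10, rnorm(120) + 10)  # 10 sigma apart
  feats <- rbind(blob1, blob2)
  truth <- rep(1:2, each = 120)
  lab <- cluster_spikes(feats, seed = 1)
  expect_equal(attr(lab, "G"), 2L)
  # compare as a partition, not by label identity
  expect_equal(length(unique(paste(lab, truth))), 2)

  lab1 <- cluster_spikes(blob1, seed = 1)
  expect_equal(attr(lab1, "G"), 1L)
})

test_that("cluster acceptance applies the event-count floor", {
  labels <- rep(c(1, 2), times = c(3000, 2000))
  expect_equal(filter_clusters(labels), 1L)
  expect_equal(filter_clusters(rep(1:3, each = 10)), integer(0))
  expect_equal(filter_clusters(rep(1:3, each = 10), min_events = 0), 1:3)
})

test_that("spike-triggered averaging recovers signal and shrinks noise", {
  fs <- 20
  n_samp <- 20000
  sig <- numeric(n_samp)
  tpl <- -50 * exp(-seq(-1, 1, by = 1 / fs)^2 / 0.02)
  trig <- c(2000, 6000, 10000, 14000) / fs  # ms
  for (t0 in trig) {
    i <- round(t0 * fs) + 1 + seq(-fs, fs)
    sig[i] <- sig[i] + tpl
  }
  block <- structure(list(traces = rbind(sig, sig), fs_khz = fs,
                          electrode_id = c(0, 1), config_id = 1L),
                     class = "recording_block")
  sta <- spike_triggered_average(block, trig)
  expect_equal(sta$n_spikes, 4)
  i0 <- which.min(abs(sta$t_ms))
  expect_equal(sta$waveforms[1, i0], -50, tolerance = 1e-9)

  # pure-noise STA: averaged-trace SD ~ raw SD / sqrt(n), n = 14 and 100
  set.seed(9)
  for (n in c(14, 100)) {
    noise_block <- structure(
      list(traces = matrix(rnorm(40 * 120000, sd = 5), 40), fs_khz = fs,
           electrode_id = 1:40, config_id = 1L),
      class = "recording_block")
    trig_n <- seq(10, 5990, length.out = n)
    sta_n <- spike_triggered_average(noise_block, trig_n)
    ratio <- mean(apply(sta_n$waveforms, 1, sd)) / 5
    expect_equal(ratio, 1 / sqrt(n), tolerance = 3 / sqrt(n))
  }
})

test_that("footprints assemble across configurations order-independently", {
  lay <- hex_layout(12, 12, 18)
  cfg <- sim_config(soma = c(90, 80), bounds = c(20, 180, 20, 160),
                    noise_uV = 0.2, max_length_um = 800, seed = 10)
  arb <- grow_arbor(cfg)
  rec <- simulate_recording(arb, lay, cfg, duration_s = 4, seed = 11)
  trig <- rec$spike_times_ms[[1]]
  expect_gt(length(trig), 2)

  # split the electrodes into three "configurations"
  parts <- split(seq_len(nrow(lay)), rep(1:3, length.out = nrow(lay)))
  partials <- lapply(seq_along(parts), function(k) {
    sub <- structure(list(traces = rec$traces[parts[[k]], , drop = FALSE],
                          fs_khz = rec$fs_khz,
                          electrode_id = lay$id[parts[[k]]],
                          config_id = k), class = "recording_block")
    spike_triggered_average(sub, trig)
  })
  fp <- assemble_footprint(partials)
  expect_s3_class(fp, "axon_footprint")
  expect_setequal(fp$electrode_id, lay$id)
  fp_rev <- assemble_footprint(rev(partials))
  expect_equal(fp_rev$waveforms, fp$waveforms)

  # single partial assembles to itself
  fp1 <- assemble_footprint(partials[1])
  expect_equal(fp1$waveforms, partials[[1]]$waveforms)

  # near-noiseless STA delays match the ground-truth arbor delays
  pts <- do.call(rbind, lapply(seq_along(arb$branches), function(i)
    cbind(arb$branches[[i]]$points,
          arbor_delays(arb, cfg$velocity_mps)[[i]])))
  darb <- dist_to_arbor(lay, arb)
  near <- which(darb < 10 & fp$tau_ms[match(lay$id, fp$electrode_id)] > 0.3)
  expect_gt(length(near), 3)
  for (i in near) {
    d2 <- (pts[, 1] - lay$x_um[i])^2 + (pts[, 2] - lay$y_um[i])^2
    expect_lt(abs(fp$tau_ms[match(lay$id[i], fp$electrode_id)] -
                    pts[which.min(d2), 3]), 0.06)
  }

  # conflicting duplicate coverage: the higher-spike-count average wins
  dup <- partials[[1]]
  dup$n_spikes <- partials[[1]]$n_spikes - 1L
  dup$waveforms <- partials[[1]]$waveforms + 99
  expect_warning(fp_dup <- assemble_footprint(c(partials, list(dup))),
                 "covered by several")
  expect_equal(fp_dup$waveforms, fp$waveforms)
})

test_that("duplicate footprints merge by amplitude-map similarity", {
  lay <- hex_layout(14, 14, 18)
  cfg <- sim_config(soma = c(45, 45), bounds = c(30, 200, 30, 180),
                    max_length_um = 800, seed = 12)
  arb <- grow_arbor(cfg)
  fp_a <- render_footprint(arb, lay, cfg, n_spikes = 200, seed = 13)
  fp_b <- render_footprint(arb, lay, cfg, n_spikes = 200, seed = 14)

  # same neuron, split events: re-merges to one footprint
  merged <- merge_duplicate_footprints(list(fp_a, fp_b))
  expect_length(merged, 1)
  expect_equal(sum(merged[[1]]$n_spikes),
               sum(fp_a$n_spikes) + sum(fp_b$n_spikes))

  # disjoint arbors stay separate
  cfg2 <- sim_config(soma = c(185, 160), bounds = c(30, 200, 30, 180),
                     max_length_um = 800, seed = 15)
  fp_c <- render_footprint(grow_arbor(cfg2), lay, cfg2, n_spikes = 200)
  expect_length(merge_duplicate_footprints(list(fp_a, fp_c)), 2)

  # identical copies merge trivially
  expect_length(merge_duplicate_footprints(list(fp_a, fp_a)), 1)
})
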