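#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. Defaults follow
#' the regime of dissociated cortical cultures on an 18-um-pitch HD-MEA:
#' action-potential conduction velocity 0.3-0.44 m/s (central value 0.35),
#' axonal negative peaks of 5-20 uV against about 5 uV RMS total noise, and
#' spike-triggered averaging over about 14 events per recording
#' configuration.
#'
#' @param velocity_mps Axonal conduction velocity c in m/s.
#' @param step_um Growth step length of the branching random walk (um).
#' @param angle_sd_rad Angular jitter (SD of the per-step heading change).
#' @param branch_prob Probability of spawning a new branch at each step.
#' @param max_length_um Total arbor length budget (um).
#' @param amp_range_uV Range of axonal spike peak amplitudes at the axon
#'   (uV). Amplitudes vary smoothly along each branch (an AR(1) profile,
#'   correlation length a few steps), emulating varicosities and calibre
#'   changes; the default 5-20 uV is the typical range of axonal signals
#'   against ~5 uV RMS noise.
#' @param width_ms Spike template width (ms).
#' @param lambda_um Amplitude decay length: an electrode at distance d from
#'   the axon sees amplitude `amp_uV / (1 + (d/lambda_um)^2)`.
#' @param noise_uV Single-trial additive Gaussian noise SD (uV RMS).
#' @param rate_hz Poisson firing rate (Hz).
#' @param ais_amp_uV Peak amplitude of the axon initial segment (AIS) source
#'   at the soma (uV); the AIS dominates the extracellular field and serves
#'   as the trigger site.
#' @param ais_lead_ms How much the AIS negative peak precedes the trigger
#'   time (ms).
#' @param bounds Optional growth bounds `c(xmin, xmax, ymin, ymax)` (um);
#'   steps reflect at the bounds so the arbor stays on the array.
#' @param soma Soma position `c(x, y)` in um.
#' @param init_dir_rad Optional initial heading of the root branch
#'   (radians); drawn uniformly when `NULL`.
#' @param seed Integer seed; all randomness in the simulator flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(velocity_mps = 0.35, step_um = 10, angle_sd_rad = 0.4,
                       branch_prob = 0.02, max_length_um = 2500,
                       amp_range_uV = c(5, 20), width_ms = 0.5,
                       lambda_um = 15,
                       noise_uV = 5, rate_hz = 2, ais_amp_uV = 150,
                       ais_lead_ms = 0.05, bounds = NULL, soma = c(0, 0),
                       init_dir_rad = NULL, seed = 1L) {
  stopifnot(velocity_mps > 0, step_um > 0, branch_prob >= 0, branch_prob <= 1,
            max_length_um > 0, width_ms > 0, lambda_um > 0, noise_uV >= 0,
            rate_hz >= 0, length(amp_range_uV) == 2,
            diff(amp_range_uV) >= 0, all(amp_range_uV >= 0))
  structure(as.list(environment()), class = "sim_config")
}

#' Grow a branching axonal arbor
#'
#' Seeded branching random walk from the soma: at each step the heading
#' jitters by a Gaussian angle, the tip advances by `step_um`, and with
#' probability `branch_prob` a daughter branch is spawned at the current
#' point. Growth stops when the total arbor length reaches
#' `max_length_um`. When `cfg$bounds` is set, steps reflect at the bounds.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed (defaults to `cfg$seed`).
#' @return An object of class `sim_arbor`: list with `soma`, and `branches`,
#'   each branch a list with `points` (n x 2 matrix, um), `pathlen`
#'   (cumulative path length from the soma, um, non-decreasing), `amp_uV`
#'   (local spike peak amplitude at each point), `parent` (index of the
#'   parent branch, `NA` for the root).
#' @export
grow_arbor <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  reflect <- function(p, dir) {
    b <- cfg$bounds
    if (is.null(b)) return(list(p = p, dir = dir))
    if (p[1] < b[1]) { p[1] <- 2 * b[1] - p[1]; dir <- pi - dir }
    if (p[1] > b[2]) { p[1] <- 2 * b[2] - p[1]; dir <- pi - dir }
    if (p[2] < b[3]) { p[2] <- 2 * b[3] - p[2]; dir <- -dir }
    if (p[2] > b[4]) { p[2] <- 2 * b[4] - p[2]; dir <- -dir }
    list(p = p, dir = dir)
  }
  amp_of <- function(z)
    cfg$amp_range_uV[1] + diff(cfg$amp_range_uV) * stats::pnorm(z)
  rho <- 0.8  # AR(1) persistence of the along-axon amplitude profile
  z0 <- stats::rnorm(1)
  # active branch state: point, heading, pathlen and amplitude state at tip
  branches <- list(list(points = matrix(cfg$soma, 1, 2),
                        pathlen = 0, amp_uV = amp_of(z0),
                        parent = NA_integer_))
  dir0 <- if (is.null(cfg$init_dir_rad)) stats::runif(1, 0, 2 * pi) else
    cfg$init_dir_rad
  tips <- list(list(b = 1L, p = cfg$soma, dir = dir0, len = 0, z = z0))
  total <- 0
  k <- 0L
  while (total < cfg$max_length_um) {
    k <- k %% length(tips) + 1L  # round-robin over active tips
    tip <- tips[[k]]
    tip$dir <- tip$dir + stats::rnorm(1, 0, cfg$angle_sd_rad)
    p <- tip$p + cfg$step_um * c(cos(tip$dir), sin(tip$dir))
    rf <- reflect(p, tip$dir)
    tip$p <- rf$p; tip$dir <- rf$dir
    tip$len <- tip$len + cfg$step_um
    tip$z <- rho * tip$z + sqrt(1 - rho^2) * stats::rnorm(1)
    total <- total + cfg$step_um
    br <- branches[[tip$b]]
    br$points <- rbind(br$points, tip$p)
    br$pathlen <- c(br$pathlen, tip$len)
    br$amp_uV <- c(br$amp_uV, amp_of(tip$z))
    branches[[tip$b]] <- br
    tips[[k]] <- tip
    if (stats::runif(1) < cfg$branch_prob) {
      nb <- length(branches) + 1L
      branches[[nb]] <- list(points = matrix(tip$p, 1, 2),
                             pathlen = tip$len, amp_uV = amp_of(tip$z),
                             parent = tip$b)
      side <- sample(c(-1, 1), 1)
      tips[[length(tips) + 1L]] <-
        list(b = nb, p = tip$p, dir = tip$dir + side * pi / 4,
             len = tip$len, z = tip$z)
    }
  }
  structure(list(soma = cfg$soma, branches = branches), class = "sim_arbor")
}

#' @export
print.sim_arbor <- function(x, ...) {
  L <- max(vapply(x$branches, function(b) max(b$pathlen), numeric(1)))
  cat(sprintf("Simulated axonal arbor: %d branches, max path length %.0f um\n",
              length(x$branches), L))
  invisible(x)
}

#' Conduction delays along an arbor
#'
#' Delay at an arbor point is its path length from the soma divided by the
#' conduction velocity: 300 um at 0.3 m/s gives 1 ms.
#'
#' @param arbor A [grow_arbor()] result.
#' @param velocity_mps Conduction velocity c in m/s (> 0).
#' @return A list, one numeric vector of delays (ms) per branch,
#'   non-decreasing along each branch.
#' @export
arbor_delays <- function(arbor, velocity_mps) {
  stopifnot(inherits(arbor, "sim_arbor"))
  if (!is.numeric(velocity_mps) || velocity_mps <= 0)
    stop("'velocity_mps' must be > 0")
  lapply(arbor$branches, function(b) (b$pathlen / 1000) / velocity_mps)
}

# all arbor points with delays and local amplitudes: x, y, delay_ms, amp_uV
arbor_point_table <- function(arbor, velocity_mps) {
  del <- arbor_delays(arbor, velocity_mps)
  do.call(rbind, lapply(seq_along(arbor$branches), function(i) {
    cbind(arbor$branches[[i]]$points, del[[i]], arbor$branches[[i]]$amp_uV)
  }))
}

#' Resample an arbor into a ground-truth point set
#'
#' Resamples every branch polyline at arc-length intervals of at most
#' `spacing_um`; the resulting points (all lying on the original polylines)
#' serve as the ground-truth set A in Hausdorff-distance evaluation.
#'
#' @param arbor A [grow_arbor()] result.
#' @param spacing_um Maximum spacing between consecutive points (um).
#' @return Numeric matrix with columns `x_um`, `y_um`.
#' @export
ground_truth_points <- function(arbor, spacing_um) {
  stopifnot(inherits(arbor, "sim_arbor"))
  if (!is.numeric(spacing_um) || spacing_um <= 0)
    stop("'spacing_um' must be > 0")
  pts <- lapply(arbor$branches, function(b) {
    s <- b$pathlen - b$pathlen[1]  # arc length within branch
    L <- s[length(s)]
    if (L == 0) return(b$points[1, , drop = FALSE])
    n <- ceiling(L / spacing_um) + 1
    at <- seq(0, L, length.out = n)
    cbind(stats::approx(s, b$points[, 1], xout = at)$y,
          stats::approx(s, b$points[, 2], xout = at)$y)
  })
  out <- do.call(rbind, pts)
  colnames(out) <- c("x_um", "y_um")
  out
}

# biphasic (negative-dominant) extracellular spike template, unit peak ~1
spike_template <- function(t_ms, width_ms = 0.5) {
  sn <- width_ms / 5
  sp <- width_ms / 2.5
  -exp(-t_ms^2 / (2 * sn^2)) +
    0.45 * exp(-(t_ms - 0.7 * width_ms)^2 / (2 * sp^2))
}

# noiseless footprint signal for one arbor on a layout:
# list(signal = electrodes x samples matrix, t_ms)
footprint_signal <- function(arbor, layout, cfg, t_pre_ms = -2, t_post_ms = 6,
                             fs_khz = 20) {
  pts <- arbor_point_table(arbor, cfg$velocity_mps)
  t_ms <- seq(t_pre_ms, t_post_ms, by = 1 / fs_khz)
  n_e <- nrow(layout)
  sig <- matrix(0, n_e, length(t_ms))
  d_soma <- sqrt((layout$x_um - arbor$soma[1])^2 +
                 (layout$y_um - arbor$soma[2])^2)
  for (i in seq_len(n_e)) {
    d2 <- (pts[, 1] - layout$x_um[i])^2 + (pts[, 2] - layout$y_um[i])^2
    j <- which.min(d2)
    a_ax <- pts[j, 4] / (1 + d2[j] / cfg$lambda_um^2)
    a_ais <- cfg$ais_amp_uV / (1 + (d_soma[i] / cfg$lambda_um)^2)
    sig[i, ] <- a_ax * spike_template(t_ms - pts[j, 3], cfg$width_ms) +
      a_ais * spike_template(t_ms + cfg$ais_lead_ms, cfg$width_ms)
  }
  list(signal = sig, t_ms = t_ms)
}

#' Render a simulated electrical footprint
#'
#' Forward model for the spike-triggered average: each electrode sees the
#' spike template centred at the delay of the nearest arbor point, scaled by
#' `A0 / (1 + (d/lambda_um)^2)` with d the distance to the arbor and A0 the
#' local axonal amplitude at that point (see `amp_range_uV`), plus
#' an AIS source at the soma, plus Gaussian noise of SD
#' `noise_uV / sqrt(n_spikes)` (the residual noise of an average of
#' `n_spikes` trials). Electrodes far from the arbor carry essentially pure
#' noise, so their negative-peak delays are uniform over the STA window.
#'
#' @param arbor A [grow_arbor()] result.
#' @param layout A [hex_layout()].
#' @param cfg A [sim_config()].
#' @param n_spikes Number of averaged trials (>= 1).
#' @param t_pre_ms,t_post_ms STA window boundaries relative to the trigger.
#' @param fs_khz Sampling rate (kHz).
#' @param seed Seed (defaults to `cfg$seed`).
#' @return An [footprint()] object with ground-truth attributes
#'   `arbor` and `cfg` attached.
#' @export
render_footprint <- function(arbor, layout, cfg, n_spikes = 14,
                             t_pre_ms = -2, t_post_ms = 6, fs_khz = 20,
                             seed = cfg$seed) {
  stopifnot(inherits(arbor, "sim_arbor"), inherits(layout, "hex_layout"))
  if (n_spikes < 1) stop("'n_spikes' must be >= 1")
  fs <- footprint_signal(arbor, layout, cfg, t_pre_ms, t_post_ms, fs_khz)
  set.seed(seed)
  noise <- matrix(stats::rnorm(length(fs$signal),
                               sd = cfg$noise_uV / sqrt(n_spikes)),
                  nrow(fs$signal), ncol(fs$signal))
  fp <- footprint(fs$signal + noise, fs$t_ms, layout$id, n_spikes)
  attr(fp, "arbor") <- arbor
  attr(fp, "cfg") <- cfg
  fp
}

#' Simulate a raw multichannel recording
#'
#' Generates Poisson spike trains for each neuron and inserts the neuron's
#' noiseless footprint waveforms into the traces at every spike time, on top
#' of additive Gaussian noise of SD `cfg$noise_uV`. Returns the true event
#' times, so closed-loop tests can score detection and averaging against
#' ground truth.
#'
#' @param arbors A list of [grow_arbor()] results (one per neuron).
#' @param layout A [hex_layout()]; traces are simulated for all of its
#'   electrodes.
#' @param cfg A [sim_config()].
#' @param duration_s Recording duration (s).
#' @param fs_khz Sampling rate (kHz).
#' @param seed Seed (defaults to `cfg$seed`).
#' @param config_id Configuration index stored with the block.
#' @return A list of class `recording_block`: `traces` (electrodes x
#'   samples, uV), `fs_khz`, `electrode_id`, `config_id`, and
#'   `spike_times_ms` (list of true event-time vectors, one per neuron).
#' @export
simulate_recording <- function(arbors, layout, cfg, duration_s, fs_khz = 20,
                               seed = cfg$seed, config_id = 0L) {
  stopifnot(inherits(layout, "hex_layout"), duration_s > 0, fs_khz > 0)
  if (inherits(arbors, "sim_arbor")) arbors <- list(arbors)
  set.seed(seed)
  n_samp <- round(duration_s * 1000 * fs_khz)
  traces <- matrix(stats::rnorm(nrow(layout) * n_samp, sd = cfg$noise_uV),
                   nrow(layout), n_samp)
  spike_times <- vector("list", length(arbors))
  for (k in seq_along(arbors)) {
    n_ev <- stats::rpois(1, cfg$rate_hz * duration_s)
    times <- sort(stats::runif(n_ev, 0, duration_s * 1000))
    spike_times[[k]] <- times
    if (n_ev == 0) next
    fs <- footprint_signal(arbors[[k]], layout, cfg,
                           t_pre_ms = -2, t_post_ms = 6, fs_khz = fs_khz)
    w <- ncol(fs$signal)
    off <- round(fs$t_ms[1] * fs_khz)
    for (tm in times) {
      i0 <- round(tm * fs_khz) + off + 1L
      sel <- seq(i0, i0 + w - 1L)
      ok <- sel >= 1L & sel <= n_samp
      if (any(ok)) traces[, sel[ok]] <- traces[, sel[ok]] + fs$signal[, ok]
    }
  }
  structure(list(traces = traces, fs_khz = fs_khz, electrode_id = layout$id,
                 config_id = config_id, spike_times_ms = spike_times),
            class = "recording_block")
}

#' @export
print.recording_block <- function(x, ...) {
  cat(sprintf("Recording block %s: %d electrodes x %d samples at %g kHz (%.1f s)\n",
              x$config_id, nrow(x$traces), ncol(x$traces), x$fs_khz,
              ncol(x$traces) / x$fs_khz / 1000))
  invisible(x)
}
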