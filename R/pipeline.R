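#' Pipeline configuration
#'
#' Collects every tunable of the mapping workflow. The defaults are the
#' standard operating point of the method: 20 kHz sampling, 100-3500 Hz
#' band-pass, detection threshold 5 x the robust noise SD with 0.5 ms dead
#' time, an STA window of -2..+6 ms (T = 8 ms), a 2500-event floor per
#' accepted cluster, 7-member neighbourhoods at scale 1 with at least 5
#' members, a 100 um fixed-electrode exclusion radius, 30 s per block-scan
#' configuration and 115 s per footprint configuration.
#'
#' The `sim` element configures the synthetic recording used by the
#' `simulate` stage; array and demo sizes (`n_rows`, `n_cols`,
#' `n_neurons`, `amplifiers`, `block_size`) size the simulated chip.
#'
#' @param fs_khz Sampling rate (kHz).
#' @param band Band-pass edges (Hz).
#' @param k Detection threshold multiplier.
#' @param dead_time_ms Detection dead time (ms).
#' @param t_pre_ms,t_post_ms STA window (ms), `t_pre_ms < 0 < t_post_ms`.
#' @param min_events Minimum events per accepted cluster.
#' @param scale,min_members Neighbourhood settings for segmentation.
#' @param fixed_exclusion_um Fixed-electrode exclusion radius (um).
#' @param block_scan_s Recording time per block-scan configuration (s).
#' @param t_config_s Recording time per footprint configuration (s).
#' @param n_rows,n_cols,pitch Simulated array geometry.
#' @param n_neurons Number of simulated neurons.
#' @param amplifiers Number of amplifiers of the simulated chip.
#' @param block_size Electrodes per block-scan configuration.
#' @param seed Master seed; all stage seeds derive from it.
#' @param sim A [sim_config()]; its seed/bounds are overridden by the
#'   pipeline.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fs_khz = 20, band = c(100, 3500), k = 5,
                            dead_time_ms = 0.5, t_pre_ms = -2,
                            t_post_ms = 6, min_events = 2500, scale = 1,
                            min_members = 5, fixed_exclusion_um = 100,
                            block_scan_s = 30, t_config_s = 115,
                            n_rows = 16, n_cols = 16, pitch = 18,
                            n_neurons = 3, amplifiers = 64,
                            block_size = 64, seed = 1L,
                            sim = sim_config()) {
  stopifnot(t_pre_ms < 0, t_post_ms > 0, fs_khz > 0, min_events >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

# deterministic per-stage seed stream (kept below 2^31)
stage_seed <- function(config, stage, i = 0L) {
  (as.integer(config$seed) * 1009L + match(stage, c(
    "simulate", "detect", "plan", "footprint", "segment", "evaluate")) *
     101L + as.integer(i)) %% 2147483647L
}

#' Run the mapping pipeline
#'
#' Executes the workflow end to end on a seeded synthetic culture:
#'
#' 1. `simulate` — build the array layout, grow one bounded arbor per
#'    neuron (somata spread across the array) and store ground truth;
#' 2. `detect` — block-scan the array, detect spikes, build the activity
#'    map and greedily select fixed (trigger) electrodes at putative AIS
#'    sites;
#' 3. `plan` — partition the remaining electrodes into switch-matrix
#'    configurations;
#' 4. `footprint` — simulate each configuration, detect and sort spikes on
#'    the fixed electrodes, spike-triggered-average every electrode and
#'    assemble per-neuron footprints (duplicates merged);
#' 5. `segment` — segment each footprint with both methods;
#' 6. `evaluate` — per-neuron AUCs, operating points and Hausdorff
#'    distances against the simulated ground truth.
#'
#' Each stage writes its artifact into `out_dir` (see [write_session()])
#' together with a JSON log of parameters, seed and result counts. The
#' whole run is reproducible bit-for-bit from `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output session directory.
#' @param stages Character vector of stages to run, or `"all"`.
#' @return The session list, invisibly.
#' @export
run_pipeline <- function(config, out_dir, stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "detect", "plan", "footprint", "segment",
                  "evaluate")
  if (identical(stages, "all")) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  log <- list(seed = config$seed, stages = stages,
              parameters = config[setdiff(names(config), "sim")],
              sim = unclass(config$sim))
  ses <- if (dir.exists(out_dir))
    tryCatch(read_session(out_dir), error = function(e) list()) else list()

  layout <- ses$layout
  if ("simulate" %in% stages) {
    layout <- hex_layout(config$n_rows, config$n_cols, config$pitch)
    margin <- 2 * config$pitch
    bounds <- c(margin, max(layout$x_um) - margin,
                margin, max(layout$y_um) - margin)
    set.seed(stage_seed(config, "simulate"))
    somata <- spread_somata(config$n_neurons, bounds,
                            min_dist = config$fixed_exclusion_um)
    ses$arbors <- lapply(seq_len(config$n_neurons), function(i) {
      cfg_i <- config$sim
      cfg_i$soma <- somata[i, ]
      cfg_i$bounds <- bounds
      grow_arbor(cfg_i, seed = stage_seed(config, "simulate", i))
    })
    ses$ground_truth <- lapply(ses$arbors, ground_truth_points,
                               spacing_um = config$pitch / 2)
    names(ses$ground_truth) <- seq_along(ses$arbors)
    ses$layout <- layout
    log$simulate <- list(n_neurons = config$n_neurons,
                         electrodes = nrow(layout))
  }
  if (is.null(layout)) stop("no layout: run the 'simulate' stage first")

  if ("detect" %in% stages) {
    if (is.null(ses$arbors)) stop("no arbors: run 'simulate' first")
    blocks <- split(layout$id,
                    ceiling(seq_along(layout$id) / config$block_size))
    events <- lapply(seq_along(blocks), function(b) {
      sub <- subset_layout(layout, blocks[[b]])
      rec <- sim_block(ses$arbors, sub, config,
                       duration_s = config$block_scan_s,
                       seed = stage_seed(config, "detect", b), id = b)
      detect_block(rec, k = config$k, dead_time_ms = config$dead_time_ms,
                   band = config$band)
    })
    ses$events <- do.call(rbind, events)
    amap <- activity_map(ses$events, layout$id)
    ses$fixed_ids <- select_fixed_electrodes(
      amap, layout, min_dist_um = config$fixed_exclusion_um,
      max_n = max(1L, config$amplifiers %/% 2L))
    log$detect <- list(n_events = nrow(ses$events),
                       n_active = sum(amap$count > 0),
                       fixed_electrodes = ses$fixed_ids)
  }

  if ("plan" %in% stages) {
    if (is.null(ses$fixed_ids)) stop("no fixed electrodes: run 'detect' first")
    ses$configurations <- build_configurations(
      layout, ses$fixed_ids, config$amplifiers,
      seed = stage_seed(config, "plan"))
    log$plan <- list(
      n_configurations = length(ses$configurations),
      check = n_configurations(nrow(layout), config$amplifiers,
                               length(ses$fixed_ids)))
  }

  if ("footprint" %in% stages) {
    if (is.null(ses$configurations)) stop("no configurations: run 'plan' first")
    partials <- list()  # per fixed electrode, one partial per configuration
    counts <- list()
    for (cf in ses$configurations) {
      ids <- c(cf$fixed, cf$variable)
      sub <- subset_layout(layout, ids)
      rec <- sim_block(ses$arbors, sub, config,
                       duration_s = config$t_config_s,
                       seed = stage_seed(config, "footprint", cf$index),
                       id = cf$index)
      for (fe in cf$fixed) {
        tr <- bandpass(rec$traces[match(fe, rec$electrode_id), ],
                       rec$fs_khz, config$band)
        ev <- detect_spikes(tr, rec$fs_khz, k = config$k,
                            dead_time_ms = config$dead_time_ms)
        if (nrow(ev) < 2) next
        triggers <- sort_trigger_events(tr, ev, rec$fs_khz,
                                        seed = stage_seed(config,
                                                          "footprint",
                                                          1000L + fe))
        if (length(triggers) < 2) next
        sta <- spike_triggered_average(rec, triggers,
                                       config$t_pre_ms, config$t_post_ms)
        if (is.null(sta)) next
        key <- as.character(fe)
        partials[[key]] <- c(partials[[key]], list(sta))
        counts[[key]] <- (counts[[key]] %||% 0L) + sta$n_spikes
      }
    }
    keep <- names(counts)[unlist(counts) > config$min_events]
    fps <- lapply(keep, function(key)
      assemble_footprint(partials[[key]], fixed_ids = ses$fixed_ids,
                         neuron = as.integer(key)))
    fps <- merge_duplicate_footprints(fps)
    names(fps) <- vapply(fps, function(f) as.character(f$neuron),
                         character(1))
    ses$footprints <- fps
    log$footprint <- list(n_candidate = length(counts),
                          n_accepted = length(keep),
                          n_neurons = length(fps))
  }

  if ("segment" %in% stages) {
    if (is.null(ses$footprints)) stop("no footprints: run 'footprint' first")
    nbrs <- lapply(layout$id, function(e)
      hex_neighborhood(layout, e, config$scale))
    ses$segmentations <- lapply(ses$footprints, function(fp) {
      list(segment_axon(fp, layout, "II", scale = config$scale,
                        min_members = config$min_members,
                        neighborhoods = nbrs),
           segment_axon(fp, layout, "I", k = config$k))
    })
    sizes <- vapply(ses$segmentations, function(s)
      length(s[[1]]$electrodes), integer(1))
    log$segment <- list(
      n_segmented = length(sizes),
      electrodes_selected = unname(sizes),
      arbors_over_50_electrodes = sum(sizes > 50))
  }

  if ("evaluate" %in% stages) {
    if (is.null(ses$segmentations)) stop("no segmentations: run 'segment' first")
    gt <- match_ground_truth(ses$footprints, ses$arbors, ses$ground_truth,
                             layout)
    ses$evaluation <- compare_methods(
      unname(ses$footprints), layout, ground_truths = gt,
      scale = config$scale, min_members = config$min_members, k = config$k,
      seed = stage_seed(config, "evaluate"))
    log$evaluate <- list(
      mean_auc_I = mean(ses$evaluation$auc_I),
      mean_auc_II = mean(ses$evaluation$auc_II),
      auc_II_wins = sum(ses$evaluation$auc_II > ses$evaluation$auc_I))
  }

  write_session(list(layout = ses$layout, config = unclass(config)[
    setdiff(names(config), "sim")], events = ses$events,
    arbors = ses$arbors, fixed_ids = ses$fixed_ids,
    configurations = ses$configurations,
    footprints = ses$footprints, segmentations = ses$segmentations,
    ground_truth = ses$ground_truth), out_dir)
  if (!is.null(ses$evaluation))
    utils::write.csv(ses$evaluation, file.path(out_dir, "evaluation.csv"),
                     row.names = FALSE)
  write_json(log, file.path(out_dir, "log.json"))
  invisible(ses)
}

# scatter somata with a minimum separation (greedy, seeded by caller)
spread_somata <- function(n, bounds, min_dist) {
  pts <- matrix(numeric(), 0, 2)
  tries <- 0
  while (nrow(pts) < n && tries < 10000) {
    p <- c(stats::runif(1, bounds[1], bounds[2]),
           stats::runif(1, bounds[3], bounds[4]))
    if (!nrow(pts) || min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >
        min_dist)
      pts <- rbind(pts, p)
    tries <- tries + 1
  }
  if (nrow(pts) < n)
    stop("could not place ", n, " somata at least ", min_dist, " um apart")
  pts
}

# simulate one configuration's recording with the simulator's noise model
sim_block <- function(arbors, sub_layout, config, duration_s, seed, id) {
  cfg <- config$sim
  simulate_recording(arbors, sub_layout, cfg, duration_s,
                     fs_khz = config$fs_khz, seed = seed, config_id = id)
}

# spike-sort the events of one trigger electrode and return the trigger
# times of its dominant accepted cluster
sort_trigger_events <- function(trace, events, fs_khz, seed) {
  half <- round(1.5 * fs_khz)
  ok <- events$sample - half >= 1 & events$sample + half <= length(trace)
  waves <- extract_waveforms(trace, events, fs_khz)
  kept <- events$time_ms[ok]
  if (nrow(waves) < 12) return(kept)  # too few events to sort
  nc <- min(10L, nrow(waves) - 1L, ncol(waves))
  feats <- pca_features(waves, n_components = nc)
  labels <- cluster_spikes(feats, seed = seed)
  main <- as.integer(names(which.max(table(labels))))
  kept[labels == main]
}

# pair each footprint's AIS with the nearest simulated soma
match_ground_truth <- function(footprints, arbors, ground_truth, layout) {
  if (is.null(arbors)) return(NULL)
  somata <- do.call(rbind, lapply(arbors, `[[`, "soma"))
  lapply(footprints, function(fp) {
    j <- match(fp$ais_electrode, layout$id)
    d <- sqrt((somata[, 1] - layout$x_um[j])^2 +
              (somata[, 2] - layout$y_um[j])^2)
    ground_truth[[which.min(d)]]
  })
}
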