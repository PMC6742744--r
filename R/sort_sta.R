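#' Extract spike waveforms around detected events
#'
#' Cuts a window from 1.5 ms before to 1.5 ms after the negative peak of
#' each event (61 samples at 20 kHz). Events too close to the trace edges
#' are skipped; the number skipped is reported in the `n_excluded`
#' attribute.
#'
#' @param trace Filtered trace (uV).
#' @param events Event table from [detect_spikes()] (needs column `sample`).
#' @param fs_khz Sampling rate (kHz).
#' @param pre_ms,post_ms Window half-widths (ms).
#' @return Numeric matrix (events x samples) of class `waveform_set`, with
#'   attributes `fs_khz`, `n_excluded`, `center` (column of the peak).
#' @export
extract_waveforms <- function(trace, events, fs_khz, pre_ms = 1.5,
                              post_ms = 1.5) {
  pre <- round(pre_ms * fs_khz)
  post <- round(post_ms * fs_khz)
  ok <- events$sample - pre >= 1 & events$sample + post <= length(trace)
  rows <- lapply(events$sample[ok], function(s) trace[(s - pre):(s + post)])
  w <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(), 0, pre + post + 1)
  structure(w, fs_khz = fs_khz, n_excluded = sum(!ok), center = pre + 1L,
            class = c("waveform_set", class(w)))
}

#' Principal-component spike features
#'
#' Projects waveforms onto their first `n_components` principal axes; these
#' low-dimensional features carry most of the energy of the signal and are
#' the input to mixture-model clustering.
#'
#' @param waves Waveform matrix (events x samples), e.g. a `waveform_set`.
#' @param n_components Number of components to keep (default 10).
#' @return Score matrix (events x components) with attribute
#'   `energy_fraction`, the fraction of total variance captured.
#' @export
pca_features <- function(waves, n_components = 10) {
  waves <- unclass(waves)
  if (nrow(waves) < n_components)
    stop("need at least ", n_components, " events for ", n_components,
         " components")
  p <- stats::prcomp(waves, center = TRUE)
  k <- min(n_components, ncol(p$x))
  structure(p$x[, seq_len(k), drop = FALSE],
            energy_fraction = sum(p$sdev[seq_len(k)]^2) / sum(p$sdev^2))
}

#' Cluster spike events with a Gaussian mixture
#'
#' Fits full-covariance Gaussian mixtures with 1..`k_max` components to the
#' feature matrix and keeps the penalized-likelihood (BIC) optimum,
#' assigning each event a hard label. The fit is deterministic given the
#' seed.
#'
#' @param features Feature matrix (events x dims), e.g. [pca_features()].
#' @param k_max Maximum number of mixture components.
#' @param seed Integer seed.
#' @return Integer vector of cluster labels (1-based), with attribute `G`
#'   (number of clusters chosen).
#' @export
cluster_spikes <- function(features, k_max = 6, seed = 1L) {
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("need at least 2 events to cluster")
  set.seed(seed)
  mclustBIC <- mclust::mclustBIC  # Mclust() resolves this in the caller
  fit <- tryCatch(
    mclust::Mclust(features, G = seq_len(min(k_max, nrow(features) - 1L)),
                   modelNames = "VVV", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit))  # degenerate features: everything in one cluster
    return(structure(rep(1L, nrow(features)), G = 1L))
  structure(as.integer(fit$classification), G = fit$G)
}

#' Accept clusters with enough events
#'
#' Clusters containing more than `min_events` events are assigned to
#' distinct neurons; smaller clusters are dropped because their
#' spike-triggered averages would be too noisy. The default of 2500 events
#' corresponds to about 14 spikes in each of 179 recording configurations,
#' i.e. a firing-rate floor of roughly 7 spikes/min at 115 s per
#' configuration.
#'
#' @param labels Cluster labels (from [cluster_spikes()]).
#' @param min_events Minimum event count (exclusive).
#' @return Sorted vector of accepted cluster ids.
#' @export
filter_clusters <- function(labels, min_events = 2500) {
  tab <- table(labels)
  ids <- names(tab)[tab > min_events]
  sort(as.integer(ids))
}

#' Spike-triggered average over one recording block
#'
#' Averages, for every electrode of the block, the trace windows
#' `[t_pre_ms, t_post_ms]` aligned to the trigger times. Averaging `n`
#' windows shrinks uncorrelated noise by `1/sqrt(n)`, revealing axonal
#' signals of a few microvolts.
#'
#' @param block A `recording_block`.
#' @param trigger_times_ms Trigger (spike) times in ms.
#' @param t_pre_ms,t_post_ms Window boundaries relative to the trigger
#'   (defaults -2 and +6 ms, total length T = 8 ms).
#' @return A list of class `sta_partial`: `waveforms` (electrodes x
#'   samples), `t_ms`, `electrode_id`, `n_spikes`, `config_id`; or `NULL`
#'   if no trigger falls inside the usable bounds.
#' @export
spike_triggered_average <- function(block, trigger_times_ms, t_pre_ms = -2,
                                    t_post_ms = 6) {
  fs <- block$fs_khz
  i_pre <- round(t_pre_ms * fs)
  i_post <- round(t_post_ms * fs)
  n_samp <- ncol(block$traces)
  centers <- round(trigger_times_ms * fs) + 1L
  centers <- centers[centers + i_pre >= 1 & centers + i_post <= n_samp]
  if (!length(centers)) return(NULL)
  acc <- matrix(0, nrow(block$traces), i_post - i_pre + 1L)
  for (c0 in centers)
    acc <- acc + block$traces[, (c0 + i_pre):(c0 + i_post), drop = FALSE]
  dimnames(acc) <- NULL
  list(waveforms = acc / length(centers),
       t_ms = seq(i_pre, i_post) / fs,
       electrode_id = block$electrode_id,
       n_spikes = length(centers),
       config_id = block$config_id) |>
    structure(class = "sta_partial")
}

#' Assemble a footprint from per-configuration averages
#'
#' Combines the spike-triggered averages of all recording configurations
#' into one whole-array footprint: variable electrodes contribute from
#' their own configuration, fixed electrodes from the configuration where
#' they were averaged over the most spikes (a warning is raised when an
#' electrode is covered twice with different data). The result is invariant
#' to the order of the partials.
#'
#' @param partials List of `sta_partial` objects (NULLs are dropped).
#' @param fixed_ids Optional trigger-electrode ids used to locate the AIS.
#' @param neuron Optional neuron identifier.
#' @return An [footprint()] object.
#' @export
assemble_footprint <- function(partials, fixed_ids = NULL, neuron = NA) {
  partials <- Filter(Negate(is.null), partials)
  if (!length(partials)) stop("no usable spike-triggered averages")
  t_ms <- partials[[1]]$t_ms
  rows <- list(); nsp <- list(); dup <- integer()
  for (p in partials) {
    if (!isTRUE(all.equal(p$t_ms, t_ms)))
      stop("partials have differing STA windows")
    for (i in seq_along(p$electrode_id)) {
      eid <- p$electrode_id[i]
      key <- as.character(eid)
      if (!is.null(rows[[key]])) {
        if (!eid %in% fixed_ids) dup <- c(dup, eid)
        if (p$n_spikes <= nsp[[key]]) next
      }
      rows[[key]] <- p$waveforms[i, ]
      nsp[[key]] <- p$n_spikes
    }
  }
  if (length(dup))
    warning("electrode(s) ", paste(unique(dup), collapse = ", "),
            " covered by several configurations; keeping the average with",
            " the most spikes", call. = FALSE)
  ids <- sort(as.integer(names(rows)))
  keys <- as.character(ids)
  footprint(do.call(rbind, rows[keys]), t_ms, ids,
            n_spikes = unlist(nsp[keys]), fixed_ids = fixed_ids,
            neuron = neuron)
}

#' Merge duplicate footprints
#'
#' Spike sorting on different trigger electrodes can split one neuron into
#' several clusters whose footprints are essentially identical. Footprints
#' whose amplitude maps (restricted to electrodes where either exceeds
#' 3 x its residual noise) have cosine similarity above the threshold are
#' merged: their waveforms are pooled by spike-count-weighted averaging and
#' the footprint statistics recomputed.
#'
#' @param footprints List of [footprint()] objects on the same electrode set.
#' @param similarity_threshold Cosine-similarity threshold (default 0.95).
#' @return List of merged footprints (length <= input length).
#' @export
merge_duplicate_footprints <- function(footprints,
                                       similarity_threshold = 0.95) {
  n <- length(footprints)
  if (n < 2) return(footprints)
  sim <- function(a, b) {
    use <- a$v_n > 3 * a$s_n | b$v_n > 3 * b$s_n
    if (!any(use)) return(0)
    va <- a$v_n[use]; vb <- b$v_n[use]
    sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  }
  # union-find over similar pairs
  grp <- seq_len(n)
  find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sim(footprints[[i]], footprints[[j]]) > similarity_threshold) {
      grp[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(unique(roots), function(r) {
    members <- footprints[roots == r]
    if (length(members) == 1L) return(members[[1]])
    # pool events: per-electrode spike-count-weighted average
    ns <- Reduce(`+`, lapply(members, `[[`, "n_spikes"))
    wav <- Reduce(`+`, lapply(members, function(f)
      f$waveforms * f$n_spikes)) / ns
    footprint(wav, members[[1]]$t_ms, members[[1]]$electrode_id,
              n_spikes = ns, neuron = members[[1]]$neuron)
  })
}
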