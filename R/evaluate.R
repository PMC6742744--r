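#' Hausdorff distance between two point sets
#'
#' `H(A, E) = max{ sup_a inf_e d(a,e), sup_e inf_a d(a,e) }` with Euclidean
#' `d`; the standard computer-vision measure of how strongly two shapes
#' differ, used here to compare a segmentation (electrode coordinates, E)
#' with a ground-truth arbor point set (A) expressed in the same frame.
#' Directed distances are computed exactly over all pairs.
#'
#' @param A,E Non-empty numeric matrices of points (rows) in um.
#' @return The Hausdorff distance in um.
#' @export
hausdorff_distance <- function(A, E) {
  A <- as.matrix(A); E <- as.matrix(E)
  if (!nrow(A) || !nrow(E)) stop("point sets must be non-empty")
  pracma::hausdorff_dist(A, E)
}

# per-electrode scores of the two segmentation methods on a footprint;
# method II scores are taken from the after-AIS (causality-gated)
# electrodes, the population its threshold operates on
method_scores <- function(fp, layout, scale = 1, min_members = 5,
                          neighborhoods = NULL, guard_ms = 0.05) {
  idx <- match(layout$id, fp$electrode_id)
  if (anyNA(idx)) stop("footprint does not cover all layout electrodes")
  dm <- delay_sd_map(fp, layout, scale, min_members, neighborhoods)
  T_ms <- footprint_window(fp)
  gated <- dm$valid & dm$tau_ms > fp$tau_ais + guard_ms
  if (sum(gated) < 50) gated <- dm$valid
  list(
    score_I = log(fp$v_n[idx] / fp$s_n[idx]),
    score_II = pmin(pmax(dm$s_tau_ms[gated] / (T_ms / 2), 0), 1),
    gated = gated, delay_map = dm, T_ms = T_ms
  )
}

#' Compare the two segmentation methods on a set of footprints
#'
#' For each footprint, fits the score mixtures of both methods
#' (see [fit_score_mixture()]), derives their ROC curves and AUCs, and
#' reports the TPR/FPR at each method's operating threshold: `log(k)` on
#' the amplitude scores for method I, and the automatic valley threshold
#' (normalized by T/2) for method II. When ground-truth arbor point sets
#' are supplied, the Hausdorff distance between each method's selected
#' electrodes and the ground truth is added (`NA` for empty selections).
#'
#' @param footprints List of [footprint()] objects.
#' @param layout A [hex_layout()].
#' @param ground_truths Optional list of point matrices (same length as
#'   `footprints`), e.g. from [ground_truth_points()].
#' @param scale,min_members Neighbourhood settings for method II.
#' @param k Amplitude threshold multiplier of method I.
#' @param seed Seed for the mixture fits.
#' @return Data frame with one row per neuron: `neuron`, `auc_I`,
#'   `auc_II`, `tpr_I`, `fpr_I`, `tpr_II`, `fpr_II`, `s_min_ms` (the
#'   automatic valley threshold) and, with ground truth,
#'   `hausdorff_I_um`, `hausdorff_II_um`. The fitted ROC curves are
#'   attached as attribute `rocs`.
#' @export
compare_methods <- function(footprints, layout, ground_truths = NULL,
                            scale = 1, min_members = 5, k = 5, seed = 1L) {
  stopifnot(length(footprints) >= 1)
  nbrs <- lapply(layout$id, function(e) hex_neighborhood(layout, e, scale))
  rocs <- vector("list", length(footprints))
  rows <- vector("list", length(footprints))
  for (i in seq_along(footprints)) {
    fp <- footprints[[i]]
    sc <- method_scores(fp, layout, scale, min_members, nbrs)
    fit_I <- fit_score_mixture(sc$score_I, "normal", seed = seed)
    fit_II <- fit_score_mixture(sc$score_II, "beta-truncexp", seed = seed)
    roc_I <- roc_from_mixture(fit_I)
    roc_II <- roc_from_mixture(fit_II)
    op_I <- operating_point(fit_I, log(k))
    s_min <- threshold_from_valley(sc$delay_map$s_tau_ms[sc$gated], sc$T_ms)
    op_II <- if (is.na(s_min)) list(tpr = NA_real_, fpr = NA_real_) else
      operating_point(fit_II, as.numeric(s_min) / (sc$T_ms / 2))
    row <- data.frame(
      neuron = if (is.na(fp$neuron)) i else fp$neuron,
      auc_I = roc_I$auc, auc_II = roc_II$auc,
      tpr_I = op_I$tpr, fpr_I = op_I$fpr,
      tpr_II = op_II$tpr, fpr_II = op_II$fpr,
      s_min_ms = as.numeric(s_min))
    if (!is.null(ground_truths)) {
      gt <- ground_truths[[i]]
      hd <- function(seg) {
        j <- match(seg$electrodes, layout$id)
        if (!length(j)) return(NA_real_)
        hausdorff_distance(gt, cbind(layout$x_um[j], layout$y_um[j]))
      }
      row$hausdorff_I_um <- hd(segment_axon(fp, layout, "I", k = k))
      row$hausdorff_II_um <- hd(segment_axon(fp, layout, "II", scale = scale,
                                             min_members = min_members,
                                             neighborhoods = nbrs))
    }
    rows[[i]] <- row
    rocs[[i]] <- list(I = roc_I, II = roc_II)
  }
  structure(do.call(rbind, rows), rocs = rocs,
            class = c("method_comparison", "data.frame"))
}

#' Benchmark both segmentation methods on a simulated cohort
#'
#' Generates `n_neurons` independent simulated neurons under the standard
#' study conditions (5 uV RMS total noise averaged over 14 spikes, axonal
#' peaks 5-20 uV, conduction velocity 0.35 m/s, 18 um pitch, T = 8 ms STA
#' window) — one bounded arbor per neuron on its own array — and runs
#' [compare_methods()] against the simulated ground truth.
#'
#' @param n_neurons Number of simulated neurons.
#' @param seed Master seed; each neuron's arbor, amplitudes and noise
#'   derive from it.
#' @param n_rows,n_cols,pitch Array geometry.
#' @param n_spikes Spikes averaged per electrode.
#' @param sim_args Named list of overrides passed to [sim_config()].
#' @return The [compare_methods()] table (one row per neuron).
#' @export
benchmark_methods <- function(n_neurons = 20, seed = 1L, n_rows = 40,
                              n_cols = 40, pitch = 18, n_spikes = 14,
                              sim_args = list()) {
  layout <- hex_layout(n_rows, n_cols, pitch)
  margin <- 2 * pitch
  bounds <- c(margin, max(layout$x_um) - margin,
              margin, max(layout$y_um) - margin)
  fps <- vector("list", n_neurons)
  gts <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    s_i <- (as.integer(seed) * 7919L + i * 104729L) %% 2147483647L
    set.seed(s_i)
    soma <- c(stats::runif(1, bounds[1] + 50, bounds[2] - 50),
              stats::runif(1, bounds[3] + 50, bounds[4] - 50))
    cfg <- do.call(sim_config, c(list(soma = soma, bounds = bounds,
                                      seed = s_i), sim_args))
    arb <- grow_arbor(cfg)
    fps[[i]] <- render_footprint(arb, layout, cfg, n_spikes = n_spikes)
    fps[[i]]$neuron <- i
    gts[[i]] <- ground_truth_points(arb, pitch / 2)
  }
  compare_methods(fps, layout, ground_truths = gts, seed = seed)
}
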