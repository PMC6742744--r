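#' Local delay-variance map
#'
#' The negative-peak delay of a footprint is smooth along an axon but
#' uniform-random on background electrodes. To quantify local smoothness,
#' the delay is sampled over each electrode's hexagonal neighbourhood
#' (N <= 7 members at ring radius `scale` x pitch) and the sample standard
#' deviation `s_tau` (denominator N-1) is computed. Electrodes whose
#' neighbourhood has fewer than `min_members` members (array edge) are
#' flagged invalid: the sample SD of very few delays is too noisy to
#' classify.
#'
#' @param fp An [footprint()] covering all electrodes of `layout`.
#' @param layout A [hex_layout()].
#' @param scale Neighbourhood ring radius in units of the pitch.
#' @param min_members Minimum neighbourhood size for a valid statistic.
#' @param neighborhoods Optional precomputed list of neighbourhood id
#'   vectors (one per layout electrode, as from [hex_neighborhood()]);
#'   supplying it avoids recomputation when mapping many neurons on the
#'   same layout.
#' @return Data frame of class `delay_sd_map`: `electrode_id`, `tau_ms`,
#'   `s_tau_ms`, `n_members`, `valid`.
#' @export
delay_sd_map <- function(fp, layout, scale = 1, min_members = 5,
                         neighborhoods = NULL) {
  stopifnot(inherits(fp, "axon_footprint"), inherits(layout, "hex_layout"))
  idx <- match(layout$id, fp$electrode_id)
  if (anyNA(idx)) stop("footprint does not cover all layout electrodes")
  tau <- fp$tau_ms[idx]
  if (is.null(neighborhoods))
    neighborhoods <- lapply(layout$id, function(e)
      hex_neighborhood(layout, e, scale))
  s <- n_m <- numeric(nrow(layout))
  for (i in seq_len(nrow(layout))) {
    mem <- match(neighborhoods[[i]], layout$id)
    n_m[i] <- length(mem)
    s[i] <- if (n_m[i] >= 2) stats::sd(tau[mem]) else NA_real_
  }
  structure(data.frame(electrode_id = layout$id, tau_ms = tau, s_tau_ms = s,
                       n_members = as.integer(n_m),
                       valid = n_m >= min_members),
            scale = scale, window_ms = footprint_window(fp),
            class = c("delay_sd_map", "data.frame"))
}

#' Expected delay SD of background electrodes
#'
#' On background electrodes the negative peak of the averaged trace falls
#' anywhere in the STA window of length T, so neighbourhood delays are
#' i.i.d. uniform on an interval of width T and the mean sample SD is
#' `T / sqrt(12)` — 2.3 ms for T = 8 ms. This is the location of the broad
#' background mode of the `s_tau` distribution.
#'
#' @param T_ms Total STA window length (ms).
#' @return Expected SD in ms.
#' @export
expected_background_sd <- function(T_ms) {
  stopifnot(T_ms >= 0)
  T_ms / sqrt(12)
}

#' Expected delay SD of axonal electrodes
#'
#' Along an axon passing a neighbourhood of electrodes spaced `r_um` apart,
#' delays spread over an interval of width `2 r / c`, giving a mean sample
#' SD of `r / (c sqrt(3))` — around 30 us for r = 18 um and conduction
#' velocities of 0.3-0.44 m/s. Axonal `s_tau` values are therefore about
#' two orders of magnitude below the background mode.
#'
#' @param r_um Electrode distance (um).
#' @param c_mps Conduction velocity (m/s, > 0).
#' @return Expected SD in microseconds.
#' @export
expected_axon_sd <- function(r_um, c_mps) {
  stopifnot(r_um >= 0)
  if (any(c_mps <= 0)) stop("'c_mps' must be > 0")
  r_um / (c_mps * sqrt(3))
}

#' Automatic valley threshold for the delay-SD statistic
#'
#' Places the segmentation threshold `s_min` at the density minimum between
#' the sharp axonal mode of `s_tau` (near zero) and the broad background
#' mode near `T/sqrt(12)`. Because the two modes differ by about two orders
#' of magnitude, the histogram uses Freedman-Diaconis bins on log-spaced
#' values, smoothed by a 3-bin moving average; the threshold is the
#' (log-space) midpoint of the lowest stretch between the two peaks. When
#' no axonal mode is present the function falls back to the crossing point
#' of the components of a fitted beta + truncated-exponential mixture (see
#' [fit_score_mixture()]), and returns `NA` when that mixture assigns the
#' axonal component negligible weight — i.e. no axon found.
#'
#' @param s_values Valid `s_tau` values (ms); at least 50 required.
#' @param T_ms Total STA window length (ms).
#' @param min_axon_frac Minimum fraction of values in the axonal region for
#'   the valley search to proceed.
#' @return `s_min` in ms (or `NA` when no axonal mode is detectable), with
#'   attribute `method` one of "valley", "mixture", "none".
#' @export
threshold_from_valley <- function(s_values, T_ms, min_axon_frac = 0.02) {
  s_values <- s_values[is.finite(s_values)]
  if (length(s_values) < 50)
    stop("need at least 50 valid s_tau values to place a threshold")
  bg <- expected_background_sd(T_ms)
  x <- log10(pmax(s_values, 1e-4))
  split <- log10(bg / 8)  # boundary between axonal and background regions
  n_axon <- sum(x < split)
  if (n_axon >= max(5, min_axon_frac * length(x))) {
    bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)
    if (bw <= 0) bw <- diff(range(x)) / 30
    breaks <- seq(min(x) - bw, max(x) + bw, by = bw)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    cnt <- as.numeric(stats::filter(h$counts, rep(1 / 3, 3)))
    cnt[is.na(cnt)] <- h$counts[is.na(cnt)]
    centers <- h$mids
    lo_reg <- which(centers < split)
    hi_reg <- which(centers >= split & centers <= log10(bg) + 2 * bw)
    if (length(lo_reg) && length(hi_reg)) {
      p_ax <- lo_reg[which.max(cnt[lo_reg])]
      p_bg <- hi_reg[which.max(cnt[hi_reg])]
      if (p_bg > p_ax + 1L) {
        between <- seq(p_ax + 1L, p_bg - 1L)
        vmin <- min(cnt[between])
        plateau <- between[cnt[between] <= vmin + 1e-9]
        s_min <- 10^mean(range(centers[plateau]))
        return(structure(s_min, method = "valley"))
      }
    }
  }
  # fallback: crossing point of the fitted mixture components
  xs <- pmin(pmax(s_values / (T_ms / 2), 1e-6), 1 - 1e-6)
  fit <- tryCatch(fit_score_mixture(xs, type = "beta-truncexp"),
                  error = function(e) NULL)
  if (is.null(fit) || fit$weights["P"] < 0.05)
    return(structure(NA_real_, method = "none"))
  ratio <- function(x)
    log(fit$weights["P"] * dtruncexp(x, fit$params["lambda_P"])) -
      log(fit$weights["N"] *
            stats::dbeta(x, fit$params["alpha_N"], fit$params["beta_N"]))
  upper <- (fit$params["alpha_N"] - 1) /
    (fit$params["alpha_N"] + fit$params["beta_N"] - 2)  # beta mode
  if (!is.finite(upper) || upper <= 1e-5) upper <- 0.5
  cross <- tryCatch(stats::uniroot(ratio, c(1e-5, upper))$root,
                    error = function(e) NA_real_)
  if (is.na(cross)) return(structure(NA_real_, method = "none"))
  structure(as.numeric(cross * T_ms / 2), method = "mixture")
}

#' Segment the axonal arbor of a neuron
#'
#' Classifies electrodes of a footprint as axonal by one of two methods:
#'
#' * **Method II** (delay-based, the default): electrodes whose local
#'   delay SD `s_tau` (see [delay_sd_map()]) falls below the automatically
#'   placed valley threshold `s_min`, and whose negative peak appears
#'   *after* the peak at the axon initial segment (causality gate
#'   `tau > tau_AIS + guard`), are selected. The method uses delays only,
#'   so it is invariant to amplitude rescaling.
#' * **Method I** (amplitude threshold): electrodes whose negative-peak
#'   amplitude exceeds `k` times the residual noise of their averaged
#'   trace (`v_n > k s_n`) are selected.
#'
#' @param fp An [footprint()].
#' @param layout A [hex_layout()] covered by the footprint.
#' @param method `"II"`/`"delay"` or `"I"`/`"amplitude"`.
#' @param scale Neighbourhood scale for method II.
#' @param min_members Minimum valid neighbourhood size for method II.
#' @param s_min Optional fixed threshold (ms) overriding the automatic one.
#' @param guard_ms Causality-gate guard (one sample period by default), so
#'   the AIS itself is not selected.
#' @param k Threshold multiplier for method I.
#' @param neighborhoods Optional precomputed neighbourhoods (method II).
#' @return Object of class `axon_segmentation`: list with `neuron`,
#'   `method` ("I" or "II"), `params`, `electrodes` (selected ids), `map`
#'   (per-electrode statistics with a `selected` flag).
#' @examples
#' lay <- hex_layout(24, 24)
#' cfg <- sim_config(soma = c(200, 180),
#'                   bounds = c(0, max(lay$x_um), 0, max(lay$y_um)),
#'                   max_length_um = 1500, seed = 7)
#' fp <- render_footprint(grow_arbor(cfg), lay, cfg)
#' seg <- segment_axon(fp, lay)
#' print(seg)
#' @export
segment_axon <- function(fp, layout, method = c("II", "I", "delay", "amplitude"),
                         scale = 1, min_members = 5, s_min = NULL,
                         guard_ms = 0.05, k = 5, neighborhoods = NULL) {
  stopifnot(inherits(fp, "axon_footprint"))
  method <- match.arg(method)
  method <- switch(method, delay = "II", amplitude = "I", method)
  if (method == "II") {
    dm <- delay_sd_map(fp, layout, scale, min_members, neighborhoods)
    if (is.null(s_min)) {
      # the causality gate comes first: electrodes whose negative peak
      # precedes the AIS peak (background or AIS-dominated) cannot be
      # axonal, so the threshold is placed on the after-AIS distribution
      gated <- dm$valid & dm$tau_ms > fp$tau_ais + guard_ms
      s_use <- dm$s_tau_ms[if (sum(gated) >= 50) gated else dm$valid]
      s_min <- threshold_from_valley(s_use, footprint_window(fp))
    }
    sel <- if (is.na(s_min)) rep(FALSE, nrow(dm)) else
      dm$valid & dm$s_tau_ms < s_min & dm$tau_ms > fp$tau_ais + guard_ms
    sel[is.na(sel)] <- FALSE
    map <- dm
    map$selected <- sel
    params <- list(s_min_ms = as.numeric(s_min),
                   threshold_method = attr(s_min, "method") %||% "fixed",
                   scale = scale, min_members = min_members,
                   guard_ms = guard_ms)
  } else {
    idx <- match(layout$id, fp$electrode_id)
    if (anyNA(idx)) stop("footprint does not cover all layout electrodes")
    sel <- fp$v_n[idx] > k * fp$s_n[idx]
    map <- data.frame(electrode_id = layout$id, v_n = fp$v_n[idx],
                      s_n = fp$s_n[idx], tau_ms = fp$tau_ms[idx],
                      selected = sel)
    params <- list(k = k)
  }
  structure(list(neuron = fp$neuron, method = method, params = params,
                 electrodes = layout$id[sel], map = map,
                 ais_electrode = fp$ais_electrode),
            class = "axon_segmentation")
}

#' @export
print.axon_segmentation <- function(x, ...) {
  cat(sprintf("Axon segmentation (method %s)%s: %d of %d electrodes selected\n",
              x$method,
              if (is.na(x$neuron)) "" else paste0(", neuron ", x$neuron),
              length(x$electrodes), nrow(x$map)))
  if (x$method == "II")
    cat(sprintf("  s_min = %s ms (%s), scale %d; AIS electrode %d\n",
                format(x$params$s_min_ms, digits = 3),
                x$params$threshold_method, x$params$scale, x$ais_electrode))
  else
    cat(sprintf("  amplitude threshold k = %g (v_n > k s_n)\n", x$params$k))
  invisible(x)
}

#' @export
summary.axon_segmentation <- function(object, ...) {
  m <- object$map
  cat("Axon segmentation summary\n")
  print(object)
  if (object$method == "II") {
    cat(sprintf("  valid neighbourhoods: %d/%d; s_tau median %.3g ms (selected) vs %.3g ms (rest)\n",
                sum(m$valid), nrow(m),
                stats::median(m$s_tau_ms[m$selected]),
                stats::median(m$s_tau_ms[m$valid & !m$selected])))
  } else {
    cat(sprintf("  v_n/s_n median %.2f (selected) vs %.2f (rest)\n",
                stats::median(m$v_n[m$selected] / m$s_n[m$selected]),
                stats::median(m$v_n[!m$selected] / m$s_n[!m$selected])))
  }
  invisible(object)
}

#' Plot an axon segmentation
#'
#' @param x An `axon_segmentation`.
#' @param layout The [hex_layout()] it was computed on.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.axon_segmentation <- function(x, layout, ...) {
  stopifnot(inherits(layout, "hex_layout"))
  i <- match(x$map$electrode_id, layout$id)
  graphics::plot(layout$x_um[i], layout$y_um[i], asp = 1, pch = 16,
                 col = ifelse(x$map$selected, "firebrick", "grey80"),
                 cex = 0.6, xlab = "x (um)", ylab = "y (um)", ...)
  j <- which(layout$id == x$ais_electrode)
  graphics::points(layout$x_um[j], layout$y_um[j], pch = 3, cex = 2)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
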