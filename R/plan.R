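#' Number of switch-matrix configurations to scan the whole array
#'
#' With `e` electrodes, `a` amplifiers and `n` fixed (always-connected)
#' trigger electrodes, the remaining `e - n` electrodes are tiled in batches
#' of `a - n` variable electrodes, so the whole array is scanned in
#' `ceiling((e - n) / (a - n))` configurations. The ceiling guarantees
#' coverage of every electrode.
#'
#' @param e Electrode count.
#' @param a Amplifier count (`n < a <= e`).
#' @param n Fixed-electrode count (`0 <= n < a`).
#' @return Integer configuration count.
#' @examples
#' n_configurations(11011, 126, 62)  # 172
#' @export
n_configurations <- function(e, a, n) {
  check_plan_args(e, a, n, n_min = 0)
  as.integer(ceiling((e - n) / (a - n)))
}

#' Mean number of configurations per neuron
#'
#' `C(n) = (e - n) / ((a - n) * n)`, un-rounded: the per-neuron cost of
#' scanning the array while recording `n` neurons in parallel. Minimising
#' it over `n` trades trigger channels against scan channels.
#'
#' @inheritParams n_configurations
#' @return The exact rational value (numeric).
#' @export
mean_configs_per_neuron <- function(e, a, n) {
  check_plan_args(e, a, n, n_min = 1)
  (e - n) / ((a - n) * n)
}

#' Optimal number of fixed electrodes
#'
#' The integer `n` in `(0, a)` minimising [mean_configs_per_neuron()]. The
#' continuous relaxation has its minimum at `n* = e (1 - sqrt(1 - a/e))`,
#' which tends to `a/2` for `e >> a` — about half of the amplifiers should
#' be connected to fixed electrodes; the better of `floor(n*)` and
#' `ceiling(n*)` is returned.
#'
#' @param e Electrode count.
#' @param a Amplifier count (>= 2).
#' @return Integer optimal fixed-electrode count.
#' @export
optimal_fixed_count <- function(e, a) {
  stopifnot(a >= 2, e >= a)
  n_star <- e * (1 - sqrt(1 - a / e))
  cand <- unique(pmin(pmax(c(floor(n_star), ceiling(n_star)), 1), a - 1))
  cand[which.min(vapply(cand, function(n)
    mean_configs_per_neuron(e, a, n), numeric(1)))]
}

#' Build the batch recording configurations
#'
#' Randomly permutes the non-fixed electrodes and partitions them into
#' batches of at most `a - |fixed|` variable electrodes; every non-fixed
#' electrode appears in exactly one batch, and the fixed electrodes are
#' part of every configuration.
#'
#' @param layout A [hex_layout()] (or an integer vector of electrode ids).
#' @param fixed_ids Ids of the fixed electrodes.
#' @param a Amplifier count (> `length(fixed_ids)`).
#' @param seed Integer seed for the random permutation.
#' @return List of configurations, each a list `index`, `fixed`, `variable`.
#' @export
build_configurations <- function(layout, fixed_ids, a, seed = 1L) {
  ids <- if (inherits(layout, "hex_layout")) layout$id else as.integer(layout)
  fixed_ids <- as.integer(fixed_ids)
  if (!all(fixed_ids %in% ids)) stop("unknown electrode id among 'fixed_ids'")
  if (length(fixed_ids) >= a)
    stop("need fewer fixed electrodes than amplifiers")
  varids <- setdiff(ids, fixed_ids)
  set.seed(seed)
  varids <- sample(varids)
  per <- a - length(fixed_ids)
  batches <- split(varids, ceiling(seq_along(varids) / per))
  lapply(seq_along(batches), function(i)
    list(index = i, fixed = fixed_ids, variable = as.integer(batches[[i]])))
}

#' Scan-time budget
#'
#' Throughput arithmetic for a scan of `n_configs` configurations recorded
#' for `t_config_s` seconds each, shared by `n_neurons` in parallel.
#'
#' @param n_configs Number of configurations.
#' @param t_config_s Recording time per configuration (s, default 115).
#' @param n_neurons Number of neurons recorded in parallel.
#' @return List with `total_s`, `total_min`, `per_neuron_s`.
#' @export
scan_time_budget <- function(n_configs, t_config_s = 115, n_neurons) {
  total <- n_configs * t_config_s
  list(total_s = total, total_min = total / 60,
       per_neuron_s = total / n_neurons)
}

#' Noise-averaging arithmetic
#'
#' `sta_noise_factor(n)` is the residual-noise factor `1/sqrt(n)` after
#' spike-triggered averaging of `n` events. `rms_noise_total()` combines
#' uncorrelated noise sources in quadrature (e.g. circuit, electrode and
#' biological background noise). `sta_duration_factor()` is the factor by
#' which the recording time per configuration must grow to reach the same
#' averaged noise on a noisier system: the squared ratio of total noises.
#'
#' @param n Number of averaged events.
#' @return A numeric scalar.
#' @export
sta_noise_factor <- function(n) {
  stopifnot(n >= 1)
  1 / sqrt(n)
}

#' @rdname sta_noise_factor
#' @param ... Uncorrelated RMS noise components (uV).
#' @export
rms_noise_total <- function(...) {
  sqrt(sum(c(...)^2))
}

#' @rdname sta_noise_factor
#' @param noise_uV,ref_noise_uV Total RMS noise of the system under
#'   consideration and of the reference system (uV).
#' @export
sta_duration_factor <- function(noise_uV, ref_noise_uV) {
  (noise_uV / ref_noise_uV)^2
}

check_plan_args <- function(e, a, n, n_min) {
  stopifnot(length(e) == 1, length(a) == 1, length(n) == 1)
  if (n < n_min) stop("'n' must be >= ", n_min)
  if (n >= a) stop("'n' (fixed electrodes) must be smaller than 'a' (amplifiers)")
  if (a > e) stop("'a' must not exceed 'e'")
  invisible(TRUE)
}
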