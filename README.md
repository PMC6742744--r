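# axonmap

Mapping the axonal arbors of individual neurons from high-density
microelectrode-array (HD-MEA) recordings.

Cultured neurons on CMOS HD-MEAs (thousands of electrodes at ~18 µm pitch)
produce extracellular spikes whose largest negative peak marks the axon
initial segment (AIS), while the arbor itself leaves signals of only a few
microvolts. `axonmap` implements the full analysis chain that turns raw
multichannel voltage traces into per-neuron axonal maps:

* **Detection** — 2nd-order Butterworth band-pass (100–3500 Hz), robust
  noise estimation `s_V = 1.4826·MAD`, negative-threshold spike detection at
  `5 s_V` with 0.5 ms dead time, and whole-array activity/AIS maps.
* **Scan planning** — switch-matrix configuration arithmetic
  `c(n) = ⌈(e−n)/(a−n)⌉` for `e` electrodes, `a` amplifiers and `n` fixed
  trigger electrodes, with the optimal split `n ≈ a/2`, plus random batch
  construction and throughput/noise-budget helpers.
* **Footprints** — per-trigger-electrode spike sorting (PCA features,
  full-covariance Gaussian mixtures with penalized-likelihood model
  selection), spike-triggered averaging over an 8 ms window
  (`Δt_pre = −2 ms`, `Δt_post = +6 ms`), and assembly of the per-neuron
  electrical footprint across configurations.
* **Segmentation** — the core statistic: per electrode, the sample standard
  deviation `s_τ` of the negative-peak delays over its 7-member hexagonal
  neighbourhood. Background electrodes have delays uniform over the STA
  window, so `s̄ = T/√12` (2.3 ms at T = 8 ms); electrodes along an axon
  share delays to within `r/c`, so `s̄ = r/(c√3)` (~30 µs at r = 18 µm,
  c = 0.3–0.44 m/s). A threshold `s_min` placed automatically in the valley
  between these two modes, combined with the causality gate
  `τ > τ_AIS`, yields the axonal electrode set ("method II"). The classic
  amplitude threshold `V_n > 5 s_n` ("method I") is provided for
  comparison.
* **Evaluation** — Hausdorff distance against ground-truth arbor point
  sets, and ROC/AUC from fitted score mixtures: two normals on
  `log(V_n/s_n)` for method I, and a beta + truncated-exponential mixture
  (`λe^{−λx}/(1−e^{−λ})` on [0, 1]) on `s_τ/(T/2)` for method II.
* **Simulation** — a seeded generator of branching arbors with conduction
  delays (0.3–0.44 m/s), distance-decaying spike templates (axonal peaks
  5–20 µV, ~5 µV RMS noise), Poisson firing and raw recordings with ground
  truth, used throughout the tests.

## Worked example

Simulate one neuron under the standard conditions and segment its arbor:

```r
library(axonmap)

lay <- hex_layout(40, 40, pitch = 18)           # 1600 electrodes
cfg <- sim_config(soma = c(350, 300),
                  bounds = c(20, 680, 20, 590), seed = 3)
arb <- grow_arbor(cfg)
fp  <- render_footprint(arb, lay, cfg, n_spikes = 14)
seg <- segment_axon(fp, lay)                    # method II (delay-based)
seg
#> Axon segmentation (method II): 98 of 1600 electrodes selected
#>   s_min = 0.147 ms (valley), scale 1; AIS electrode 779

cm <- compare_methods(list(fp), lay,
                      ground_truths = list(ground_truth_points(arb, 9)))
round(cm$auc_I, 3); round(cm$auc_II, 3)
#> [1] 0.895
#> [1] 0.999
```

The delay-variance statistic separates axon from background far better
than amplitude thresholding (AUC 0.999 vs 0.895 here), and the selected
electrodes track the true arbor to within ~71 µm Hausdorff distance.
`run_pipeline()` chains simulation, block-scan detection, configuration
planning, spike sorting, footprint assembly, segmentation and evaluation
into one seeded, bit-reproducible run; `exec/axonmap` exposes the same
stages as a command-line tool, e.g.

```sh
exec/axonmap plan --electrodes 11011 --amplifiers 126 --fixed 62
#> fixed electrodes: 62
#> configurations:   172
#> configurations/neuron: 2.76
```

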