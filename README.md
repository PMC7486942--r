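# locreset

Quantitative analysis of transcription-factor localization dynamics in
live-cell time-lapse microscopy, built around the observation that
*localization-resets* — single fast cycles of nuclear exit and re-entry
of a factor such as YAP — rather than static nuclear enrichment, drive
target-gene transcription.  The package is aimed at groups doing
endogenous-tag imaging (nuclear stain + fluorescent-protein reporter,
optionally an MS2/MCP nascent-transcription channel) who need a tested,
scriptable pipeline from raw stacks to per-cell kinetic statistics.

## What it computes

* **Segmentation and tracking** — Perona–Malik enhancement plus a
  gradient-sum term; global-Otsu 2D segmentation and a
  percentile-derivative (dI/dP) local threshold for 3D stacks of
  unequally bright nuclei; seeded-watershed splitting; Hungarian
  distance-minimizing frame linking.
* **N/C ratio** — mean nuclear over mean cytoplasmic background-
  subtracted intensity: a 3-plane nuclear mask centred on the brightest
  stain plane, the lower 35th percentile of nuclear reporter pixels
  excluded as nucleolar, and a 0.5 µm cytoplasmic ring;
  `N/C = (⟨I_nuc⟩ − b) / (⟨I_ring⟩ − b)`.  Local density is the count
  of centroids within 250 px.
* **Localization fluctuations** — maximal monotone runs of the N/C
  trace with net amplitude ≥ 0.12, continuity broken when the signal
  moves < 0.005 over any 3-frame window; cohort fraction, frequency
  and amplitude statistics.
* **Nascent transcription** — per-nucleus LoG spot candidates above the
  99.97th intensity percentile, scored by a 37-pixel disk / 32-pixel
  shell integrated intensity; pulse tracking; activity time courses;
  mitosis alignment with the daughter-OR rule.
* **FRAP and transport** — radial pure-diffusion and
  reaction–diffusion (single binding mode: `∂f/∂t = D_f∇²f − k*_on f +
  k_off c`, `Keq = k*_on/k_off`, bound fraction `Keq/(1+Keq)`) forward
  models, Levenberg–Marquardt carpet fitting, 30×5 bootstrap
  uncertainty, SSD-plus-plausibility model selection, and specific
  import/export rates from the frames-1–4 slope of postbleach-
  normalized compartment traces.
* **Synthetic scenes** — movies, spot channels, FRAP carpets and
  two-pool bleach traces with exported ground truth, used throughout
  the test suite.

## Worked example

Simulate a small monolayer in which one cell is programmed with a
localization-reset (N/C dip of 0.6 starting at frame 6), then segment,
track, quantify and detect fluctuations:

```r
library(locreset)

cfg <- scene_config(shape = c(T = 24L, Z = 3L, Y = 160L, X = 160L),
                    n_cells = 4L, noise_sd = 4, seed = 7L)
ev  <- data.frame(cell = 2L, onset = 6L, type = "reset",
                  amplitude = 0.6, duration = 9L)
scene  <- generate_monolayer_movie(cfg, nc_program(4, baseline = 1.8,
                                                   events = ev))
maps   <- lapply(1:24, function(t)
  segment_nuclei_3d(scene$movie$channels$stain[, , , t])$labels)
tracks <- link_tracks(maps, gate = 12)

for (id in sort(unique(tracks$track_id))) {
  # ... build masks per frame, nc_ratio(), detect_fluctuations(); see
  # run_pipeline() for the assembled version
}
```

Output:

```
track 1: mean N/C 1.81, 0 fluctuation event(s)
track 2: mean N/C 1.81, 0 fluctuation event(s)
track 3: mean N/C 1.71, 2 fluctuation event(s)
  start_frame end_frame direction amplitude
1           6        10  decrease 0.6087060
2          10        15  increase 0.5993377
track 4: mean N/C 1.81, 0 fluctuation event(s)
```

The three unperturbed cells recover the programmed baseline of 1.8
within 1% and show no events; the programmed reset appears as one
decrease and one increase event of amplitude ≈ 0.6 at the programmed
frames (the nuclear-exodus and re-entry halves of the reset).

The same stages are available as a pipeline (`run_pipeline()`, YAML
configuration, CSV outputs and a JSON manifest) and from the shell via
`inst/cli/locreset` with `simulate`, `run`, stage, `frap-fit` and
`transport-rate` subcommands.

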