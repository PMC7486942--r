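---
title: "Methods: quantifying localization-resets, nascent transcription, and nucleocytoplasmic transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying localization-resets, nascent transcription, and nucleocytoplasmic transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locreset)
```

## The problem

Transcription factors such as YAP shuttle between the nucleus and the
cytoplasm, and their compartmental distribution — summarized by the
nuclear-to-cytoplasmic concentration ratio, N/C — encodes upstream
signalling.  Beyond the steady-state N/C, *localization-resets* (a single
fast cycle of nuclear exit and re-entry, on a 0.5–2 h timescale) carry
information that a static snapshot misses, and nascent-transcription
reporters (MS2 stem-loops bound by a fluorescent coat protein) make the
downstream transcriptional response visible as a bright nuclear spot.
This package implements the full measurement chain for such experiments:
nucleus segmentation and tracking in time-lapse movies, N/C
quantification, reset detection, spot calling with mitosis-aligned
statistics, and kinetic analysis of FRAP and compartment-bleach data.
A synthetic-microscopy generator with exported ground truth underpins
the test suite.

## Segmentation and tracking

Nuclear-stain frames are first enhanced with Perona–Malik anisotropic
diffusion (10 iterations, conduction coefficient `kappa = 30` intensity
units, explicit scheme with a stability-capped step) followed by
addition of the L1 sum of absolute first spatial derivatives.  The
diffusion flattens intranuclear texture while preserving edges; the
derivative term lifts nucleus boundaries before thresholding.  A
constant image is a fixed point of the whole operation.

2D segmentation thresholds the enhanced image globally (Otsu by
default; a fixed value can be supplied), fills holes, and splits
touching nuclei with a watershed of the smoothed Euclidean distance
transform.  The seed depth `seed_h` (default 1 px of distance) plays
the role of h-maxima suppression: shallower splits are merged.  Regions
below `min_area` (default 40 px) are discarded.  Re-running the
procedure on an already separated mask changes nothing.

3D segmentation handles fields where nuclei differ several-fold in
absolute brightness (variable expression of a diffuse nuclear marker),
where no global threshold works.  After enhancement, a permissive lower
bound (0.6 × Otsu by default) proposes candidate regions containing at
least one local intensity maximum; each region is then re-thresholded
at the percentile where the derivative of its intensity–percentile
curve, dI/dP, peaks.  That peak marks the background-to-foreground
boundary of the region's own histogram, so the rule is invariant to
affine rescaling of a region's intensities.  When several significant
peaks exist (a nucleolus adds a second intensity jump inside the
nucleus) the *first* — lowest-percentile — significant peak is used,
since the background boundary always precedes interior structure;
interior holes cut by the threshold are re-closed before the final
watershed, because nuclei are solid.  dI/dP is tabulated on a
0.5-percentile grid and smoothed with a 5-point moving average; a peak
is "significant" when it exceeds 5 × the median derivative.  Regions
smaller than `min_region_px` (50 px) skip refinement and are flagged.

Tracking links consecutive frames by minimizing total centroid
displacement with an exact Hungarian assignment (a greedy
nearest-neighbour fallback is available), with links beyond a gate
(default 15 px) forbidden.  Unmatched nuclei terminate or start tracks.
The solver is validated against exhaustive permutation on small
instances.  The movies the defaults are tuned for move nuclei by a few
pixels per frame; the gate should be set to a few times the typical
displacement but below the typical internuclear distance.

## N/C quantification

For each cell the nuclear mask is the label restricted to a 3-plane
volume centred on the plane of maximal stain intensity (a 2D image
degenerates to a single plane).  Because the reporter is physically
excluded from nucleoli, the strictly lowest 35% of reporter intensities
inside the nuclear mask are removed before averaging; ties at the
percentile value are kept, so a nucleus with 1000 distinct intensities
loses exactly 350 pixels.  The cytoplasmic compartment is a ring
extending 0.5 µm outward from the nucleus boundary (Euclidean distance
threshold rather than structuring-element dilation, for isotropy at
1–2 px radii; 0.5 µm rounds to 2 px at 0.276 µm/px), minus every
nuclear label.  The N/C ratio is

$$
N/C \;=\; \frac{\langle I_{\mathrm{nuc,excl}}\rangle - b}
               {\langle I_{\mathrm{ring}}\rangle - b},
$$

with the background $b$ defaulting to the mode of the intensity
histogram outside all dilated nuclei (the camera offset plus ambient
level).  A non-positive denominator yields a missing value rather than
a spurious ratio.  Local cell density is the number of centroids within
a 250 px search radius, *including the cell itself* (so an isolated
cell has density 1 — the self-count makes the constant offset
explicit).  Cytoplasm-localized sensors are measured as the mean over
the same ring.  Per-cell traces can be normalized to a pretreatment
window (mean over the window becomes 1), and qPCR tables are reduced
with the standard $2^{\Delta C_t}$ fold change normalized to a
reference gene.

## Localization-fluctuation detection

A fluctuation event is a maximal run in which the N/C trace moves
continuously in one direction.  Two parameters define the detector,
both in N/C units: the minimum net amplitude of a run, 0.12, and the
stagnation rule — if the signal changes by less than 0.005 over any
sliding 3-frame window, continuity is broken there.  The implementation
scans for maximal segments in which (i) every non-zero step has the
same sign and (ii) every complete 3-frame window moves by at least
0.005; both conditions are hereditary under taking subsegments, so
maximal runs are well defined and a two-pointer scan finds exactly the
segments a brute-force enumeration finds (this equivalence is asserted
on random traces in the test suite).  Zero steps are tolerated inside a
run — only the windowed stagnation rule, not single flat frames, breaks
continuity — and the window slides by one frame with the change
measured as |last − first|.  Missing frames split a trace into
independently scanned segments, mirroring the exclusion of flagged
track intervals.  Threshold comparisons carry a 1 × 10⁻¹² absolute
slack so that traces constructed to sit exactly on a boundary (a net
rise of exactly 0.12 accumulated in binary-inexact steps) are
classified by their intended value.  Amplitude is the *net* change over
the run, not peak-to-trough within it.  Cohort statistics report the
fraction of cells with at least one event, per-cell event frequency
over the observed span, and amplitude quartiles, optionally per region
of interest.

## Nascent-transcription spots

Candidate spots are detected per nucleus in two steps: a
Laplacian-of-Gaussian filter (σ = 1.5 px, matching a
diffraction-limited spot of ~2–3 px FWHM at the magnifications these
movies use) localizes blob maxima, and a rank threshold keeps pixels
whose *raw* intensity exceeds the 99.97th percentile of all pixels in
that nucleus — exactly the top 0.03%, i.e. at most 3 pixels of a
10,000-px nucleus.  Per-nucleus percentiles make detection independent
of each nucleus's absolute brightness, and affine rescaling of a
nucleus leaves its candidate set unchanged.  Each candidate is then
scored with a shell mask centred on it: the inner disk holds the 37
pixels closer than 3.5 px, the shell the 32 pixels between 3.5 and
4.5 px (7 and 9 px diameters; both counts equal brute-force
enumeration).  The integrated intensity is the disk sum minus
37 × the shell mean; candidates clipped by the image border are
excluded.  The pass threshold defaults to 5 × the standard deviation of
the background-corrected integrated intensity sampled at random
positions in spot-free nuclei, and is configurable.

Passing spots are assigned to cells through the (frame, label) pairs of
the track table.  Within a cell, simultaneous spots are ranked by
intensity and threaded by rank, so a second allele forms a second
concurrent pulse thread without requiring sub-nuclear spot tracking.
Consecutive detections merge into pulses, bridging up to one missed
frame by default.  The activity time course is the per-frame fraction
of tracked cells with a detectable transcribing locus, optionally
normalized to a pretreatment window.

Division annotations (parent, two daughters, cytokinesis frame)
re-centre time at cytokinesis.  After division a cell counts as
transcribing if *either* daughter does: the premitosis nucleus is
diploid, each daughter inherits one reporter cassette, so the OR rule
monitors the same number of cassettes before and after division.  The
premitosis mean activity is normalized to 1, and the aligned N/C trace
concatenates the parent trace with the daughters' per-frame mean.

## FRAP and transport kinetics

Line-FRAP acquisitions (a 2-px line bisecting a circular bleach spot,
scanned at millisecond rates) are normalized per position by the
prescan mean, corrected for acquisition bleaching with a
monoexponential fitted to the far-field positions (outer 15% of the
line at each end; a background acquisition taken after the bleach can
be substituted), averaged across the two line rows, and folded about
the bleach centre located by an inverted-Gaussian fit of the first
postbleach profile.  The result is a recovery carpet: normalized
fluorescence over radius × time.

Two forward models are fitted.  Pure diffusion evolves the free pool by
the radially symmetric diffusion equation.  The reaction–diffusion
model adds one pseudo-first-order binding mode to immobile sites:

$$
\frac{\partial f}{\partial t} = D_f \nabla^2 f - k^*_{on} f + k_{off} c,
\qquad
\frac{\partial c}{\partial t} = k^*_{on} f - k_{off} c,
$$

with prebleach equilibrium $f/c = k_{off}/k^*_{on}$ and observed signal
$f + c$.  Derived quantities are $K_{eq} = k^*_{on}/k_{off}$ and the
bound fraction $K_{eq}/(1 + K_{eq})$ — 0.5 when the equilibrium
constant is 1.  The spatial operator is a conservative finite-volume
discretization of the radial Laplacian with zero-flux boundaries
(80 cells to a default domain radius of 3 × the farthest observation;
total signal is conserved to 10⁻⁶ over arbitrary spans).  Because the
semi-discrete system is linear and autonomous it is propagated
*exactly* in time through the eigendecomposition of the symmetrized
operator (similarity transform by $\sqrt{r}$ and, for the two-pool
system, $\sqrt{k_{off}/k^*_{on}}$, which makes the operator symmetric),
rather than by implicit time stepping — this removes time-step error
entirely and lets the pure-diffusion model reuse one eigendecomposition
across all diffusivities during fitting.  The scheme converges at
second order to the closed-form spreading-Gaussian solution, and
setting $k^*_{on} = 0$ reproduces pure diffusion exactly.

Fitting is Levenberg–Marquardt least squares on log-parameters over the
whole carpet.  By default the initial condition is the *measured* first
postbleach profile (as an inverted-Gaussian fit) and model time runs
from that frame; a caller-supplied geometry switches to evolving the
geometry's analytic bleach profile from time zero.  Model selection
prefers reaction–diffusion only when it improves the sum of squared
residuals by more than 10% *and* its free diffusivity is physically
plausible (default band 1–30 µm²/s: a ~100 kDa protein diffuses at
roughly 21 µm²/s, so fitted effective diffusivities of ~40 µm²/s
indicate an overparameterized fit and the pure-diffusion model is
reported instead).  Parameter uncertainty follows the experimental
design of fitting 30 bootstrap averages of 5 experiments drawn with
replacement; the bootstrap is seeded and reproducible.

Compartment-bleach experiments estimate first-order transport rates.
After bleaching the nucleus (import) or the cytoplasm (export), the
nuclear signal change from the first postbleach frame is divided by the
postbleach intensity of the *source* compartment — cytoplasm for
import, nucleus for export — making the rate independent of expression
level; the specific rate is the ordinary-least-squares slope over the
first four frames (30 s at the 10 s frame interval; frames are indexed
1-based in this window, all other APIs are 0-based).  Export traces
decay, so the export rate is the negated slope.  The slope of
$1 - e^{-kt}$ sampled this way is biased low by a factor
$\approx 1 - 15(k_{import} + k_{export})$ (seconds); the bias is below
10% only while $(k_{import}+k_{export}) \cdot 30\,\mathrm{s} \lesssim
0.2$.  Crucially, both estimators share the same relaxation constant
$k = k_{import} + k_{export}$, so the bias cancels *exactly* in the
import/export ratio — the ratio estimator is unbiased on noiseless
two-pool traces at any rate magnitude, which is what the acceptance
script exploits.

## The synthetic generator

`generate_monolayer_movie()` renders elliptical nuclei with smooth
Fourier boundary jitter, a nucleolus, and a surrounding cytoplasmic
territory, moving by a reflected Gaussian random walk with an overlap
tolerance.  The reporter channel realizes a programmed N/C(t) per cell
under exact conservation: each cell carries a fixed protein total and
the compartment concentrations are derived from the current N/C and
compartment volumes, so a localization-reset redistributes signal
without creating or destroying it.  Nucleoli are rendered at a dimmed
nuclear concentration and enter the budget as reduced effective nuclear
volume.  The nucleolus occupies 25% of the nuclear area by default:
the fixed 35th-percentile exclusion rule presumes nucleoli of roughly
that size, and emulating much smaller nucleoli would make the rule cut
mostly noise pixels and bias the nuclear mean upward — a property of
the exclusion rule worth knowing when applying it to cell types with
small nucleoli.  Baseline cytoplasmic concentrations are ~100 intensity
units over a background of 100, and noise is Poisson shot noise plus
Gaussian read noise plus a constant camera offset.  `generate_spot_movie()`
adds a telegraph-model transcription locus per cell at a fixed
intranuclear position, rendered as a 2D Gaussian over diffuse nuclear
coat-protein background.  `simulate_compartment_bleach()` returns the
exact closed-form relaxation of the two-pool exchange ODE.

What the generator does *not* emulate — photobleaching during the
timelapse, optical aberrations, 3D point-spread functions, cell–cell
mechanics, or division imagery beyond label bookkeeping — bounds what
passing tests demonstrate: the pipeline's estimators are validated for
correctness and calibration on data satisfying their assumptions, not
for robustness to every artifact of real acquisitions.

## Numerical choices and problem sizes

Percentile computations use R's default (type 7) quantiles; the
nucleolar exclusion removes strictly-below pixels and keeps ties, and
the spot threshold keeps strictly-above pixels, making both counts
deterministic on distinct-valued inputs.  The test suite and acceptance
script run on deliberately small instances — movies of 96–220 px and
1–15 frames, cohorts of tens of cells, FRAP carpets of ~25 radii ×
~40 log-spaced times, a 3 × 3 × 2 reaction–diffusion recovery grid —
chosen so the full suite completes in well under a minute while still
exercising every code path at the tolerances stated in the tests.
Log-spaced FRAP sampling out to ~2 s resolves diffusion at ~20 µm²/s
and out to ~120–150 s resolves binding at $k_{off} = 0.05$/s.

## Known limitations

The reaction–diffusion model has one binding mode; two-state binding or
anomalous diffusion are out of scope.  Spot threading by intensity rank
does not follow alleles spatially.  Manual track curation is replaced
by a `flagged` column in the tracks table.  The density measure counts
centroids in a fixed pixel radius and ignores image borders, so
densities of border cells are underestimated.  The fluctuation
detector's strict sign rule means genuinely non-monotone excursions are
reported as separate events in each direction.
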