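---
title: "Quantifying tissue cohesion during neuroectoderm involution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue cohesion during neuroectoderm involution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohesiontrack)
```

## The biological question

During *C. elegans* head morphogenesis (roughly 300–400 minutes
post-fertilization), the pharyngeal primordium retracts from the anterior of
the embryo into a bulb, driven by apical constriction. Over the same hour,
the head neurons — the neuroectoderm — roll circumferentially around the
pharynx toward the ventral midline and internalize. The working model is
mechanical: the retracting pharynx is the force generator, a group of
"interface" neurons adheres to its basal surface and is pulled along, and
cohesion within the neuroectoderm sheet propagates the movement to the rest
of the chain, so that left and right leading edges converge and meet at the
midline. Loss of HMR-1/cadherin severs both couplings: the pharynx still
retracts, but the neurons detach, drift slightly anterior, and the bilateral
leading edges never meet.

`cohesiontrack` implements the computational side of testing this model on
lineage-resolved 4D nuclear tracking data:

1. **contact graphs** — approximate cell–cell contacts at each timepoint as
   the Delaunay 1-skeleton (the dual of the Voronoi diagram) of the nuclear
   centroids;
2. **the cohesion screen** — for every neuron, the fraction of timepoints at
   which it still touches at least one of the pharyngeal cells that were its
   neighbors at the start of involution; neurons above 75% are the interface
   set;
3. **motion analysis** — smoothing, differencing, and pairwise Pearson
   correlation of 3D velocity series, the statistic behind the
   movement-path correlation heatmaps;
4. **measurements** — left–right separation at closest approach, pharynx
   retraction from the anterior pole, net displacement, convergence, ROI
   quantification of max-projected image stacks, and Student *t* tests;
5. **a synthetic-embryo generator** — a kinematic model of the whole process
   with known ground truth, which is what the test suite and the acceptance
   script recover parameters from.

## Contact graphs from nuclear positions

Real contact areas require a membrane label; nuclear tracking provides only
centroids. Following standard practice, a pair of cells is considered "in
contact" at a frame when their Voronoi cells share a facet, i.e. when the
pair is an edge of the 3D Delaunay tetrahedralization of that frame's
nuclear positions. No installed R library provides 3D Delaunay
tetrahedralization, so `delaunay_edges()` implements incremental
Bowyer–Watson insertion directly: coordinates are rescaled to the unit box,
four auxiliary vertices 10^4 box-lengths away bound the construction, and
each insertion replaces the simplices whose circumsphere contains the new
point. The test suite checks exactness against an independent brute-force
oracle — an edge `(a, b)` is Delaunay if and only if some 4-point subset
containing `a` and `b` has an empty circumsphere — on fifty random point
sets, and checks invariance under rigid motion.

Numerical edge cases are handled deterministically: exactly coincident
points are perturbed by a seed-free 10^-6 µm offset keyed to row order
(with a warning), cospherical degeneracies fall back to a deterministic
growing jitter, and coplanar inputs are an error because a 3D contact graph
is undefined for them. Graphs are always built on calibrated micron
coordinates; building them on anisotropic pixel/plane units would distort
the Voronoi geometry, so `contact_graph()` refuses uncalibrated recordings.

Delaunay adjacency is a generous notion of contact: an edge can connect two
nuclei across many microns of interstitial space if no other nucleus lies
between. Since nuclei in these embryos are about 3 µm across, the screen
analyses in this package prune edges longer than 1.5× the median edge
length of the frame (roughly 7 µm) via the `prune_factor` argument. The
package-wide default remains `prune_factor = 0`: pruning is never applied
silently, it is an explicit analysis choice.

## The cohesion screen

`contact_persistence(recording, t0, t1)` computes, for every cell labeled
`neuron`, its pharyngeal Delaunay neighbors at `t0` and then counts the
frames in `[t0, t1]` at which at least one initial neighbor is still
adjacent. The published screen used a 65-frame window at 75 s per frame;
percentages are `100 * count / 65` rounded half-up to one decimal, which
reproduces every printed value of the published persistence table
(shipped as `inst/extdata/table1_persistence.csv`):

```{r table1}
tab <- read_persistence_table(
  system.file("extdata", "table1_persistence.csv", package = "cohesiontrack"))
all(tab$percent_recomputed == tab$percent)
screen_interface(tab, threshold = 0.75)
```

Cells and their ancestors are treated as equivalent across divisions, on
both sides of a contact: a neuron born mid-window inherits its mother's
trajectory (`concat_through_division()`, daughter wins at the division
frame), and a contact with the daughter of an initial neighbor still
counts. The window start `t0` — the onset of pharynx retraction — is
supplied by the caller, not auto-detected.

## Velocity correlation

Trajectories are assembled through divisions, smoothed with a centered
moving average whose window shrinks at the track ends (so output length
equals input length), and differenced into per-frame 3D displacement
vectors. For a cell pair, the three velocity components are flattened into
a single vector of length `3 (T - 1)` and correlated with Pearson's *r*:
one value per pair, +1 for identical motion and −1 for opposite motion.
Pairs with zero variance return `NA` and are excluded from heatmaps.
Matrices from replicate embryos are combined entry-wise
(`average_correlation_matrices()`), as in the published three-embryo
heatmaps.

Two analysis parameters deserve explanation:

* **Smoothing window.** The original analysis used an automatically chosen
  smoothing scale, which is not reproducible. The package default is an
  explicit 5 frames. For the correlation analyses of the synthetic cohorts
  we use 7 frames, the smallest odd window at which the residual jitter
  velocity `sqrt(2) * sigma / w` (with the generator's sigma = 0.5 µm)
  falls below half the mean leading-edge speed (~0.25 µm/frame); at
  stronger smoothing the noise floor of uncorrelated cells starts to rise.
* **Analysis window.** Correlations are computed over the involution phase
  itself — 48 frames, i.e. 60 min at 75 s/frame — rather than the longer
  65-frame screen window, since frames after arrival at the midline carry
  no directed motion.

## Measurements

`lr_separation()` operationalizes "distance between the left and right
leading edges" as the closest nucleus pair between the two cell groups,
per frame, returning the minimum over the window and the frame where it is
attained (the published measurement was drawn by hand on membrane-labeled
images; nuclei are what tracks provide). `pharynx_retraction()` likewise
uses the pharyngeal nucleus closest to the anterior-pole landmark as the
pharynx tip proxy, and reports the change in pole-to-tip distance over the
window. Both deviations from the image-based originals are deliberate and
documented here. `roi_mean_minus_background()` reproduces the image-side
quantification logic — max projection of a slice range, mean inside an
ROI, minus the mean of a background ROI outside the embryo — on plain 3D
arrays; it is exercised on synthetic fixtures only, since the raw
micrographs are not deposited. `group_ttest()` wraps the classical Student
*t* (pooled or Welch, one- or two-tailed, optionally paired) with the
convention that the one-tailed alternative is "first group exceeds the
second".

## The synthetic embryo

The generator (`synthetic_embryo_config()`, `simulate_embryo()`) is a
kinematic, prescribed-displacement model — the analysis consumes
trajectories, so simulating mechanics would be unconstrained invention.
Coordinates: +x anterior, +y dorsal, +z embryo right, midline at z = 0.
Populations and update rules, per frame:

* **Pharynx** (default 20 cells): an apex cell plus rings of four on a
  cylinder (radius 4 µm, anteroposterior extent 8–20 µm) that translates
  posteriorly by `retraction_um` (default 18 µm; mutant preset 17 µm, the
  two observed means) over the window, with a mild radial contraction
  whose depth scales with the programmed retraction.
* **Interface neurons** (default 6): a ventral shell 2.5 µm off the
  pharynx surface. Each is paired with its nearest pharyngeal cell at the
  first frame and each frame receives `attachment` times that partner's
  displacement plus `(1 - attachment)` times an anterior drift.
* **Chain neurons** (default 10 per side): the neuroectoderm sheet, two
  anteroposterior columns per side of cells spaced 2.6 µm along a
  flat-bottomed superellipse contour (semi-axes 15 µm wide, 10 µm tall,
  exponent 4 — mounted embryos flatten ventrally). The leading edge starts
  where the left–right gap equals `start_gap_um` (default 25 µm) and moves
  toward the ventral midline at constant arc speed, stopping at nuclear
  contact (`end_gap_um`, default 2 µm) after 48 frames (60 min). Each
  following link repeats its predecessor's arc step lagged one frame,
  scaled by `chain_cohesion`; `(1 - chain_cohesion)` of the motion is
  replaced by anterior drift.
* **Static populations**: bilateral amphid clusters on the lateral
  mid-shell (the classic non-involuting control), a dorsal hypodermal
  arch, and unscreened interior cells — a lateral/dorsal mid-shell, a
  posterior plug, and a ventral-cord floor. These exist because Voronoi
  contact screens are only meaningful in a packed tissue: in an
  artificially empty embryo, Delaunay edges span open corridors tens of
  microns long and the screen stops measuring adhesion.
* **Noise and drift**: every cell gets i.i.d. Gaussian jitter
  (`noise_sd_um`, default 0.5 µm) per frame and axis from a single seeded
  stream; identical `(config, seed)` gives bit-identical output. The
  anterior drift of uncoupled cells (0.2 µm/frame) follows a per-cell,
  slowly wandering bearing — a unit anterior bias with AR(1) lateral
  jitter (correlation time ~10 frames). Detached cells meander; giving
  them a micrometer-coherent common velocity would itself be an artifact,
  and it would register as spurious positive velocity correlation among
  mutant neurons.

Ground truth (designated interface set, interface–pharynx pairing, chain
ordering, noise-free trajectories, ideal leading-edge gap per frame) is
returned alongside the recording, which is what makes parameter-recovery
testing possible: the screen must find exactly the designated interface
neurons in wild type and none in the mutant; correlation must be positive
ipsilateral, negative contralateral, and near zero in the mutant; the
measured retraction, separation and convergence must match the programmed
values within noise.

What the generator does *not* emulate: cell divisions on the real
schedule (an optional scripted division exists purely to exercise lineage
concatenation), hypodermal closure dynamics, temporally autocorrelated
tracking noise, mechanical interactions, or the anterior interface group.
Passing recovery tests on this generator therefore demonstrates that the
pipeline measures what it claims to measure on data with known truth — not
that real embryos behave like the generator.

## Numerical choices, collected

* Persistence percentages and proportions round half-up to one decimal
  (base R's `round()` is banker's rounding and does not reproduce the
  published table).
* Delaunay: unit-box rescaling; super-tetrahedron at 10^4; relative
  insphere tolerance 10^-12; duplicate-point jitter 10^-6 µm keyed to
  insertion order; coplanarity rejected at a 10^-9 relative singular-value
  threshold.
* Screen analyses prune contact edges at 1.5× the median frame edge
  length; the package default is no pruning.
* Smoothing windows must be odd so the moving average stays centered;
  window 1 is the identity.
* At a division frame the daughter's observation supersedes the mother's.
* Missing frames inside an analysis window are an error, never silently
  interpolated — interpolation would corrupt velocity series.
* Calibration (x, y divided by pixels-per-micron, z multiplied by the
  plane step) is a one-way state change; calibrating twice is an error.

## Problem sizes

The shipped analyses and tests run synthetic embryos of ~110 cells over 65
frames; screens build one contact graph per frame (about a second per
embryo), and the recovery suites use 20 seeds per genotype. These sizes
were chosen so the full pipeline — cohorts, screens, correlations,
measurements — reruns from scratch in a few minutes on a laptop while
keeping every statistical margin comfortable.

## Known limitations

* Contact is nuclear-proximity-based; true membrane contact areas need a
  membrane channel and are out of scope.
* The screen assumes tissue labels are correct and total over screened
  cells; it errors rather than guessing.
* The Bowyer–Watson construction is floating-point, not exact-arithmetic;
  pathological near-cospherical inputs are resolved by deterministic
  jitter rather than simulation-of-simplicity.
* Replay of the published image-derived fluorescence values is impossible
  from the text alone (raw recordings are not deposited); the ROI
  machinery is therefore validated on synthetic stacks.
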