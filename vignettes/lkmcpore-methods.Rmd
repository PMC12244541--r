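---
title: "From segmentation maps to intrathrombus diffusivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From segmentation maps to intrathrombus diffusivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lkmcpore)
```

## The problem

Platelet masses (hemostatic plugs, thrombi) are not homogeneous: a densely
packed core and a loosely packed shell differ sharply in how much
plasma-accessible pore space they leave between cells, and therefore in how
fast proteins can move through them. Serial block-face scanning electron
microscopy resolves this microstructure at 8 nm in-plane resolution, and
segmentation models turn those images into cell-probability or
gradient-flow maps. `lkmcpore` covers the downstream half of that workflow:

1. turn a rendered segmentation map into a binary **pore/cell lattice**
   by brightness thresholding,
2. simulate **hindered tracer diffusion** on that lattice with a
   next-reaction lattice kinetic Monte Carlo (LKMC) engine,
3. **calibrate** the binarization threshold functionally, by requiring the
   simulated diffusivity to match the one obtained on a manually labelled
   ground-truth domain, and
4. map diffusivity and porosity **spatially** with a staggered-subdomain
   decomposition.

Because no imaging data ship with the package, a first-class synthetic
module generates platelet-packing-like domains and emulated grayscale
renderings, so every stage is testable end to end.

## The simulation model

A domain is a square lattice with spacing $h$ (default 8 nm, matching the
imaging resolution); each site is *pore* (accessible) or *cell* (blocked).
Tracers do not interact with each other, only with cell sites; a tracer
occupies one site, which makes $h$ an upper bound on the effective
molecular radius.

Each of the four directional hops of each particle is an independent event.
A hop pending at system time $t_\mathrm{sys}$ is assigned the tentative time

$$t_\mathrm{event} = t_\mathrm{sys} - \frac{h^2 \ln r}{D_p}, \qquad r \sim U(0,1],$$

an exponential waiting time with rate $D_p/h^2$ per direction. The globally
earliest event executes, the clock advances to it, and the moved particle's
four tentative times are redrawn; hops into cell sites get a
sentinel-infinite time and are re-examined at the next redraw. The event
queue is an indexed binary heap keyed by tentative time with deterministic
tie-breaking, and all randomness flows through R's seeded RNG, so runs are
bit-reproducible.

**Why a per-direction rate.** The hop rate could be read per particle or
per direction. Only the per-direction reading makes the unhindered
mean-squared displacement equal $4 D_p t$ in 2D, so that the estimator
below recovers $D_p$ in free space; the per-particle alternative would
yield $D_p/4$. The free-space calibration test pins this choice down.

**Mirror boundaries.** The finite field of view is tiled by reflected
images: an unbounded coordinate $x$ folds to the domain by the symmetric
reflection $m = x \bmod 2N$, $x' = m$ if $m < N$ else $2N - 1 - m$.
Particles move on unfolded coordinates (so displacement accumulates
physically); legality is checked on folded coordinates. A particle can in
principle traverse arbitrarily many reflected tiles.

**Diffusivity estimation.** The ensemble MSD
$\mathrm{MSD}(t) = \frac1n \sum_i |\mathbf r_i(t) - \mathbf r_i(0)|^2$
is sampled at 31 uniform times over $[0, t_\mathrm{end}]$ and
$D = \text{slope}/4$ is fitted by ordinary least squares **with a free
intercept** over $t \ge 1\,\mathrm{ms}$. The burn-in discards the
short-time regime in which particles diffuse freely before feeling the
pore geometry; the free intercept absorbs the offset that regime leaves
behind. (The pointwise variant $\mathrm{MSD}(t_\mathrm{end})/4t_\mathrm{end}$
is available via `method = "endpoint"` for comparison; whether to fit with
an intercept was genuinely open, and the intercept form was chosen for its
insensitivity to the burn-in offset.) With the defaults
($D_p = 10^{-6}\,\mathrm{cm^2/s}$, $t_\mathrm{end} = 3\,\mathrm{ms}$) the
diffusion length $\sqrt{4 D_p t_\mathrm{end}} \approx 1.1\,\mu m$ exceeds
half the 2 µm analysis subdomain, so local geometry is well explored.

## Binarization and its polarity

A grayscale map (RGB inputs are collapsed with the NTSC luma weights
$0.299R + 0.587G + 0.114B$, rounding half to even) is thresholded at a
brightness threshold value (BTV) in $[0,255]$. Two polarities exist and the
package exposes both:

* `dark_pore` (default): brightness $<$ BTV becomes pore. Raising the
  threshold monotonically *increases* porosity, which matches rising
  diffusivity-versus-threshold sweeps, and is the natural reading when
  cell material renders bright (high cell probability = bright = cell).
* `dark_cell`: brightness $<$ BTV becomes cell; the mirrored rule, with
  porosity monotonically decreasing in the threshold.

The synthetic grayscale emulator therefore renders cell sites bright
(mean 200) and pore sites dark (mean 20) by default, so that the default
polarity round-trips exactly on noiseless renderings. Both monotonicity
directions are asserted in tests.

## Functional calibration of the threshold

Pixel-overlap scores (IoU) judge a segmentation by geometry; *functional
accuracy* judges it by whether simulations on the thresholded domain
reproduce the transport behaviour of the ground truth. `sweep_btv()`
computes $D/D_{GT}$ across a threshold grid — with common random numbers
across thresholds, so the curve reflects geometry rather than sampling
noise — and `find_optimal_btv()` averages curves across images, takes the
**first upward crossing of ratio 1** (linearly interpolated) as the
optimal threshold, and reports the contiguous threshold interval with mean
ratio in $[0.9, 1.1]$ as a tolerance band. A missing crossing is reported
as absent, never fabricated; crossing-with-interpolation was chosen over
closest-point because it is deterministic and grid-refinable
(`calibrate_btv(refine = TRUE)` re-sweeps at step 1 around the coarse
crossing).

The lattice-spacing sensitivity harness (`btv_spacing_sensitivity()`)
repeats the sweep at coarsened spacings. A coarse site ($k \times k$ fine
pixels) is pore **only if all fine pixels are pore**: a tracer occupying
one coarse site must fit through the pore, consistent with the spacing
acting as an upper bound on the effective molecular radius.

## Spatial mapping

`local_diffusivity_map()` decomposes the parent domain into staggered
square subdomains (defaults: 250 sites = 2 µm windows every 125 sites =
1 µm, so a 1250-site = 10 µm parent yields $9 \times 9 = 81$ windows and a
$10 \times 10$ output grid). Each subdomain runs an **independent**
simulation with mirror boundaries at the subdomain edge — cells near dense
walls see only their local geometry — and each subdomain's $D/D_p$ is
attributed to the output cells its footprint covers; overlapping
attributions are averaged **unweighted**. Subdomains with no pore sites
contribute $D = 0$ (keeping the grid complete) and are visible in the
coverage metadata. Parents whose site counts are not multiples of the
stagger are cropped bottom/right with a message. All reported
diffusivities are normalized by the free diffusivity $D_p$.

## The synthetic generator

The generator emulates the three packing classes of platelet-mass imagery
— `sparse` (shell-like, target porosity 0.33), `dense` (core-like, target
porosity 0.11), `dense_rbc` (dense plus one red-blood-cell-sized
inclusion) — plus `hybrid` (sparse and dense side by side).

Packings are built as **gap-separated Voronoi tessellations**: random
generator points grow convex platelet-like cells, each shrunk back from
its Voronoi boundary by a per-generator margin, so neighbouring platelets
are separated by plasma channels whose width is the sum of the adjoining
margins. The site-to-edge distance is normalized by the subtended angle
($\mathrm{dist} = (d_2 - d_1)/2\sin(\theta/2)$), without which channels
balloon where the two nearest generators are seen nearly collinearly.
Class defaults:

* **dense**: uniform 40 nm channels (five sites — the modal pore width of
  tightly packed platelet regions), giving the narrow pore-width
  distribution characteristic of cores (measured mean ≈ 37 nm);
* **sparse**: variable 40–300 nm channels, giving the wide long-tailed
  distribution of loose shells (median ≈ 160–200 nm across seeds);
* a fraction of platelet–platelet interfaces is **sealed** (full contact:
  default 0.3 for dense classes, 0.1 for sparse). Sealing creates dead
  ends and tortuous detours; it is what couples local diffusivity to local
  porosity instead of letting every channel network transport at
  $\sim D_p/2$ regardless of porosity. Seal decisions are a deterministic
  hash of the generator pair, so domains are reproducible.

An earlier design — unions of non-overlapping rejection-placed ellipses
with a hard minimum gap — cannot reach the target coverages: random
sequential adsorption of hard convex particles jams near 55% area
coverage, below the 67% (sparse) and 89% (dense) these porosities demand,
and freely overlapping unions at those coverages leave largely
*disconnected* pore pockets, which is not how plasma space in a platelet
aggregate behaves. The Voronoi mechanism reaches any target porosity with
a connected channel network by construction. An ellipse-union mode
(`ellipse_count`, with morphological closing of the cell phase at the
minimum gap) is retained for explicitly controlled geometries.

Porosity is tuned by adding generators under **overshoot rejection**:
porosity is not monotone in the generator count (few-generator
configurations have wide near-equidistant bands), so proposals that would
overshoot the target by more than 0.045 are rejected unless they reduce
porosity, and generation stops inside the band — achieved porosities land
within ±0.05 of target (measured 0.110–0.148 dense, 0.33–0.36 sparse
across seeds). An unattainable target errors, naming the attained value.

The grayscale emulator draws per-site brightness from class-conditional
normal distributions (cell 200 ± 15, pore 20 ± 15 by default), applies a
Gaussian blur (1 px), and clips to 8 bits. It emulates the *structure*
binarization assumes — a bimodal brightness field aligned with the true
classes — but not the failure modes of a real segmentation model
(systematic boundary errors, class confusion, spatially correlated
artefacts). Passing calibration tests on emulated maps therefore
demonstrates the calibration machinery, not segmentation quality on real
electron-microscopy data.

## Numerical and degenerate-input choices

* **Pore widths** are measured by local thickness — twice the radius of
  the largest disc that fits in the pore and covers the site — computed
  from the Euclidean distance transform with edge correction
  $r = d - 0.5$ (a one-site channel has width one site). The image border
  counts as solid. Discreteness biases even-width channels low by one
  site; odd widths are exact.
* **IoU** of two empty cell sets is 1 (identical sets). The IoU batch
  summary's default standard error is $\sigma/n$ — the formula printed by
  the imaging literature this package accompanies — with the conventional
  $\sigma/\sqrt n$ as a switch.
* **Event ties** in the queue break by event index; ties are measure-zero
  in exact arithmetic.
* **Zero-pore domains** are rejected by the engine; zero-pore subdomains
  inside a heatmap contribute $D = 0$ rather than aborting the map.
* A fitted MSD slope below zero (possible for trapped ensembles plus
  noise) clamps $D$ to 0 with a warning.
* $r = 0$ draws are excluded by construction ($r \in (0,1]$), avoiding
  infinite logarithms.

## Problem sizes used by the tests

Unit tests run reduced ensembles (40–200 particles, 1–2 ms horizons,
60–150-site domains) chosen so each oracle's Monte-Carlo error is small
relative to its assertion band. The acceptance suite runs the study
conditions proper — 250 × 250 sites, 1000 tracers, 3 ms, 1 ms burn-in —
for the free-space ($D/D_p \in [0.95, 1.05]$) and single-file channel
($D/D_p \in [0.45, 0.55]$) calibrations, and 120–500 particles for the
class-ordering and threshold-sweep properties, where only orderings and
signs are asserted. At these sizes a single-domain $D/D_p$ estimate
carries roughly 3% (1000 tracers) to 15% (150 tracers) standard error,
which the assertion tolerances reflect.

## Known limitations

* 2D only; the engine's data layout would extend to a third dimension,
  but no 3D lattices, z-interpolation, or volumetric analyses are
  provided.
* No advection, reactions, particle–particle interactions, or
  anomalous-diffusion exponent fitting.
* The synthetic classes emulate packing statistics, not platelet
  ultrastructure (granules, pseudopodia, fibrin) or real segmentation
  failure modes; optimal thresholds calibrated on emulated maps say
  nothing about the thresholds appropriate for any particular real
  dataset.
* Local thickness is one of several defensible pore-width measures; chord
  length distributions would differ systematically.
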