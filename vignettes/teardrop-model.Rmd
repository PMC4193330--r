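---
title: "The teardrop model: medial-axis coding and closure feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The teardrop model: medial-axis coding and closure feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teardrop)
```

## The problem and the model

Figure-ground segregation — deciding which parts of an image are object and
which are background — is accompanied in visual cortex by *interior
enhancement*: a neuron fires more when its receptive field (RF) lies inside a
figure than on the background, even when the pixels inside the RF are
identical. This package implements a recurrent rate model of the primate
ventral stream in which interior enhancement arises because populations of
cells with jittered RF sizes and positions jointly detect a figure's **medial
axis** (skeleton), and feedback carrying **closure** evidence enhances
activity inside figures while suppressing it outside.

The model is a stack of retinotopic layers on a raster canvas (64 × 64 px by
default), all sharing seven RF scales with radii in geometric progression
from 3 to 24 px (`default_radii()`):

1. **Edge stage** (lumped retina/LGN/V1): `compute_edge_map()` converts a
   display's figure boundary into polarity-insensitive oriented energy in 8
   channels spanning 180°, confined to within 1 px of the boundary. Texture-
   defined figures contribute energy on their orientation-contrast outline
   only, so a uniform texture produces an empty edge map.
2. **Curved contour cells** (model V4): `build_arc_bank()` and
   `curved_response()`. Each cell matches one of eight 45° arcs of a circle
   of its scale's radius, sampling the arc at ~1 px spacing with the circle's
   tangent orientation and a squared-cosine orientation tuning (half-width
   22.5°, so corners partially drive two adjacent arcs). Templates carry unit
   weight mass per (arc, scale) and a radial thickness of `ring_width` pixels.
3. **Convex cells** (model PIT): `annulus_drive()`. A convex cell sums the
   eight arc responses of its scale centred on its position — an annular
   on-surround RF — and is gated to zero unless at least `opposing_gate`
   active arc pairs lie at least a quarter circle apart, so contours on one
   side of the RF alone never drive it. Convex cells are the model's
   medial-axis point detectors and its readout layer.
4. **Teardrop cells** (model AIT): `teardrop_drive()`. A teardrop cell of
   size σ and integration direction d reads an ordered chain of convex
   cells whose scales fall from σ to 1 with distance from the cell's
   position. Its drive is the geometric mean of the chain — conjunctive, so
   one silent link collapses the evidence. Eight directions at 45° spacing
   share the offset-0 (largest) sample.

Three recurrent interactions shape the convex layer
(all collected by `step_model()` into shunting dynamics):

* **Cross-scale competition** (`cross_scale_competition()`): scales sharing a
  position inhibit each other through a quadratic signal, sharpening the
  scale profile toward the best-fitting annulus.
* **Closure feedback** (`teardrop_feedback()`): at each position the closure
  evidence for scale *s* sums a steep (Hill-4) sigmoid of the strongest
  teardrop activity of size ≥ *s* per direction and subtracts the agreement
  threshold `theta_F`. Multi-directional agreement (the signature of an RF
  on a medial axis) makes it positive; the signed signal, delivered in
  proportion to the local teardrop activation and spread over part of the
  RF (`fb_spread`), multiplies the feedforward drive when positive and adds
  to the shunting inhibition when negative. A silent teardrop layer sends no
  feedback, so the feedforward sweep can bootstrap before feedback engages —
  mirroring the late onset of interior enhancement in cortex.
* **Coarse-to-fine recurrent inhibition** (`convex_recurrent_inhibition()`):
  convex cells receive inhibition only from larger-scale cells. Because the
  curved cells that drive a large cell also drive a cancelling interneuron,
  only the large cell's activity *excess* over its feedforward expectation —
  the feedback-sustained part, as arises over a concave "negative part"
  spanned by a false medial axis — is passed on, around the large cell's RF
  centre.

Every layer obeys shunting (membrane) dynamics
\(\dot x = -Ax + (B - x)E - (D + x)I\) with \(A = B = 1, D = 0\), integrated
with the exponential-Euler update: exact for inputs held constant over a
step, unconditionally inside \([-D, B]\), and converging to
\((BE - DI)/(A + E + I)\) without overshoot. The two feedback pathways are
individually lesionable (`lesion_config()`), giving the four standard
conditions: Feedback-Intact, Convex-Only, Teardrop-Only, No-Feedback.

## Stimuli and ground truth

`make_rectangle_set()` (64 rectangles, aspect 1/8–8 as an 8 × 8 side grid),
`make_c_shape_set()` (96 C-shapes: 16 equally spaced aspects in [1/4, 4] × 6
arm thicknesses), `make_cross_set()` (36), `make_square_texture_set()` (36),
and `make_block_set()` (seeded random-block figures grown from a base
rectangle by attaching 4 / 16 / 32 edge-adjacent blocks for the low /
medium / high complexity classes; each display is a deterministic function
of its seed). `make_exemplars()` returns the eight worked figures; their
sizes were fixed once so that the model's RF radii bracket each figure's
inscribed radius (square 17 px ≈ twice the fourth radius, C-shape 30 px
outer with 6 px arms, cross 33/9, texture elements 13 px with 7 px gaps,
bar 4 px wide — thinner than the smallest annulus).

Ground truth skeletons come from `compute_medial_axis()`: strict-ridge
anchors of the Euclidean distance transform connected by anchor-protected
morphological thinning. The skeleton of a connected figure is connected and
agrees with a brute-force distance-ridge enumeration to within one pixel on
rectangles (the tests enumerate all sides up to 32 px). Even figure widths
put the continuous axis between pixel rows; thinning then keeps one of the
two plateau rows, which is why comparisons carry a ±1 px tolerance.

## Indices

`ioi()`, `mai()` and `bi()` are normalised contrasts \((\bar A_1 - \bar
A_2)/(\bar A_1 + \bar A_2)\) of mean activity over complementary regions
(figure vs ground; within 1 px of the skeleton vs the rest of the interior;
within 1 px of the boundary vs everything else), so they live in \([-1, 1]\)
and ignore activity rescaling. Indices are computed on the per-position
maximum of convex activity over scales (the package default;
`metrics_report()` additionally quotes the dominant-scale MAI).
`scale_profile_kurtosis()` treats the per-scale maxima, normalised to unit
sum, as a mass over the scale index and returns the Pearson kurtosis
\(\mu_4/\mu_2^2\): large when the active cells share one RF size.
`readout_medial()` reports the dominant scale (ties toward the smaller) and
the pixels within `rho_readout` of its peak — a plain peak readout, not a
probabilistic decode.

## Parameters that matter

All constants live in `sim_params()`. The governing equations of the
original dynamical system are not published in full, so the gains and
thresholds here are this package's own calibration, chosen once so that:

* a 60/40 two-scale contrast resolves past a 0.6 winner share within 100
  steps (`g_comp = 8`);
* closure feedback turns excitatory when roughly half of the integration
  directions carry strong chains (`theta_F = 1.9`, `sigma_g = 0.45`, Hill-4
  sigmoid) — three strongly or four moderately active directions excite, a
  single active direction inhibits;
* the exemplar square is dominated by the annulus matching its half-width,
  with the interior map concentrated on the skeleton, and the C-shape's
  medial response beats its concavity only when feedback is intact.

Two numbers deserve comment. `ff_expn = 4` applies an expansive exponent to
the gated annular drive before it enters the shunting excitation; it stands
in for the spatial sharpening that surround interactions would provide and
is what concentrates single-scale maps tightly enough around the medial
axis. `ring_width = 3` gives the annulus a radial thickness, which grades
responses off the exact tangency radius; without it activity maps are
all-or-none and the indices saturate. Integration uses `dt = 0.25`,
`n_steps = 400` and a convergence tolerance of `2e-4` on the largest
per-step change; equilibria are identical to three decimals across
`dt` in 0.1–0.3.

## What the generators emulate — and what they do not

The synthetic displays reproduce the classic electrophysiology stimuli:
luminance-defined convex and concave figures, multi-element textures, and an
orientation-contrast square with a background-only control whose pixels are
identical inside the probe region. They are noise-free binary rasters with
axis-aligned or circular boundaries; passing the tests therefore
demonstrates the mechanism (medial detection, closure gating, lesion
orderings), not robustness to photometric noise, clutter, occlusion, or
natural-image statistics. `load_image_display()` lets a thresholded natural
image be pushed through the model as a demonstration only.

## Numerical choices and degenerate inputs

Activity floors: the conjunctive teardrop drive floors convex activity at
`eps = 0.01` inside its geometric mean; the annular gate counts arcs active
above `gate_eps = 0.01`. Index contrasts return 0 with a warning on 0/0;
empty region masks are errors. Ties in the dominant-scale readout break
toward the smaller scale. Chains clipped by the canvas border renormalise by
the number of in-grid samples. A background-only display (empty figure mask,
allowed only for control stimuli) produces an empty edge map and a network
that stays exactly at rest.

## Analysis sizes

The worked analyses in the tests and the acceptance script run each
exemplar to equilibrium (~60–100 steps at the defaults, a few seconds
each); the lesion comparison uses a fixed 50-display low-complexity block
subset (seed 101) under all four conditions, and the kurtosis comparison
uses seeded 4-display subsamples of five display sets. `run_experiment()`
scales the same machinery to the full 500-display block classes when asked.

## Known limitations

* Curvature selectivity is expressed at the matched population: the cells
  whose arcs a circle traverses respond maximally at its center, and
  annular gating makes the convex layer strictly scale selective there.
  Field-averaged curved-cell activity, by contrast, always favours the
  smallest scales, because with unit template mass a short arc is locally
  indistinguishable from any extended contour it grazes; genuinely
  suppressing straight contours would need end-stopped (surround-inhibited)
  templates, which are not part of this mechanism set.

* The recurrent convex circuit, implemented as suppression of
  feedback-driven excess, is nearly silent at the chosen calibration: the
  conjunctive closure feedback already resolves the C-shape, so Convex-Only
  behaves like No-Feedback at equilibrium (the lesion orderings hold with
  equality). This mirrors the reported near-equality of those conditions on
  the in-out index, but it means the two pathways are not independently
  load-bearing here.
* Isotropic teardrop sampling makes responses to squares more punctate than
  to elongated rectangles of equal area; this is an artefact of the
  simplified grouping geometry, not a claim about cortex.
* Exact quantitative indices depend on the calibration above; reported
  values carry the tolerance stated with them and orderings are the robust
  results.
* No conduction delays, occlusion, depth cues, or concave-template cells.

```{r example, eval = FALSE}
# one worked run
run <- run_model(make_exemplars()$square, lesion_config("intact"), sim_params())
metrics_report(run)
```
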