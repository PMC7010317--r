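---
title: "Methods: blebbing morphometry and focal-adhesion quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blebbing morphometry and focal-adhesion quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

blebmorph quantifies three-channel fluorescence fields of adherent cells:
a whole-cell stain for the cell body, a DNA counterstain for nuclei, and
a focal-adhesion (FA) marker such as vinculin or FAK. Per cell it
measures boundary curvature, the nuclear/cytoplasmic marker intensity
ratio, the cell/nucleus area ratio, and the FA count, then classifies
membrane blebbing and compares groups. This vignette records the model,
the tunable parameters, and the design decisions, in the package's own
terms.

## Segmentation

**Cell bodies.** The cytoplasm channel is Gaussian-smoothed
(`smooth_sigma`, default 2 px) and thresholded at `threshold_factor`
(default 2.0) times the mean intensity of the dimmest `dim_fraction`
(default 20%) of pixels. The dimmest-quintile mean is a robust background
estimate in fields where cells cover a minority of pixels; the factor 2.0
places the cut well above background shading but far below cytoplasmic
signal. The mapping from background mean to threshold is a genuinely
open choice; we fixed the multiplier at 2.0 and exposed it.

Connected components (8-connectivity throughout the package) that contain
no nucleus are discarded as debris; components containing two or more
nuclei are treated as under-segmented and split; cells touching the image
border are dropped by default (`border_policy = "drop"`), the standard
high-content practice since their features are truncated. A nucleus is
"contained" in a region when the majority (> 50%) of its area overlaps
it — any-overlap counting would double-book nuclei that graze two
regions.

**Under-segmentation splitting.** A multi-nucleus region is re-thresholded
at `reseg_factor` (default 1.5) times the original threshold. Each
high-threshold component is assigned to the nucleus holding the majority
overlap and used as a seed; if any nucleus ends up seedless the nucleus
masks themselves become the seeds (logged). Seeds grow by synchronous
breadth-first geodesic dilation restricted to the region: the schedule is
deliberately synchronous so that "reached first" is well defined and the
resulting interface approximates an equidistant cut. Pixels contested
within one iteration go to the seed whose nucleus centroid is nearer
(Euclidean); remaining ties go to the lower label index. The output
always partitions the region into exactly one label per nucleus.

**Nuclei and focal adhesions: the phase stretch transform.** Both
punctate targets are segmented with the PST: the image is localized with
a Gaussian low-pass window in the frequency domain (width `lpf_sigma`,
cycles/px), multiplied by `exp(-i φ(u, v))` with the radially symmetric
warped kernel `φ(r) ∝ W·r·atan(W·r) − ln(1+(W·r)²)/2` normalized so
`max φ = phase_strength`, and the phase of the inverse transform is kept.
Every step before the final angle is linear, so the phase is exactly
invariant to positive rescaling of the input — thresholds expressed as
phase quantiles or absolute radians are both scale-free.

We threshold `|phase|` at `max(quantile(|phase|, phase_quantile),
phase_min)`; the absolute floor keeps featureless images empty and
stabilizes the cut when the edge-band fraction varies between scenes.
Two presets are shipped, tuned on synthetic fixtures (the original
optimization was empirical and unreported, so tuning on fixtures is the
only option):

* `pst_preset("nuclei")`: `lpf_sigma` 0.12, `phase_strength` 0.5, warp
  15, quantile 0.97; cleanup close(3) → fill holes → erode(7), minimum
  region 500 px. The thresholded phase forms a band straddling each
  nucleus outline; closing and filling recover the blob and the erosion
  returns the outer band edge to the true boundary.
* `pst_preset("fa")`: `lpf_sigma` 0.08, `phase_strength` 1, warp 15,
  quantile 0.97 with an absolute floor of 0.008 rad; cleanup opening(5),
  minimum region 10 px. The narrower frequency window suppresses the
  noise floor (which limits punctum detection) faster than it attenuates
  puncta; the opening detaches puncta from the thin phase ridges that
  trace cell and nucleus outlines.

Each FA candidate is then refined against the intensity image: its
neighbourhood is thresholded halfway between the local background
(median outside all candidates) and the candidate's 95th-percentile
intensity, and the connected component(s) overlapping the candidate
replace it. Refinement is applied only when the local contrast exceeds
1.5× and the refined component stays within twice the candidate's area
(with a 150 px floor); otherwise the raw candidate is kept and left to
the downstream filters. This keeps measured FA areas faithful to the
intensity support — important because the 30 px area rule is a hard
cutoff — without letting low-contrast ridges or whole-cell interiors
masquerade as puncta.

## Morphometry

**Boundary chain.** `trace_boundary()` extracts a sub-pixel contour at
the 0.5 iso-level of a lightly smoothed (σ = 1 px) mask; this keeps
perimeters of smooth shapes accurate to ~1%, where a raw pixel-chain
trace overestimates them by 5–7%. The trace is then resampled to uniform
2 px arc spacing (`resample_boundary()`), smoothed with a circular
Savitzky–Golay filter (window 9, polyorder 3), and curvature is taken at
each point as the inverse circumradius `κ = 4A/(abc)` of the triangle
through the point and its neighbours `step = 2` samples away. Curvature
is unsigned — the 1/r definition admits no sign — so concavities also
raise the mean, consistent with the rule's intent of flagging rough
boundaries.

The explicit resampling step is a deliberate choice: at the native
contour spacing (~0.8 px) the window-9/step-2 defaults sit too close to
the trace's sub-pixel jitter and inflate the mean curvature of an r = 50
circle by tens of percent, while after 2 px resampling the same defaults
recover 1/50 = 0.0200 px⁻¹ essentially exactly (the acceptance script
recomputes this). Window, order, spacing and step are all exposed.

**Features and classification.** The nuclear/cytoplasmic intensity ratio
uses *mean* intensities (nucleus mean over cytoplasm mean, cytoplasm =
cell minus nucleus); a ratio of integrated intensities would conflate the
compartments' very different areas with their brightness. Classification
uses strict inequalities, matching the printed "larger than"/"<" of the
three cutoffs (0.029 px⁻¹, 1.15, 4.5). The outlier filters (nucleus area
< 1000 px, cell area > 150 000 px) run independently of classification
and annotate each excluded record with the triggering rule.

## Focal-adhesion counting

Surviving FA components are assigned to the cell holding the majority of
their area (ties to the lower label). Filters: majority outside any cell,
or majority inside a nucleus → dropped; area < 30 px → dropped; mean
intensity ≤ the parent cell's whole-mask mean → dropped ("≤" because the
comparator's strictness is not prescribed; the choice only matters on
exact ties). The dataset-wide upper cutoff is the 99th percentile of
per-cell counts, pooled across all groups, with the linear-interpolation
percentile definition (R type 7) — percentile conventions differ across
software, so the convention is fixed and recorded in the run manifest.
Cells with ≤ 4 adhesions are removed by the lower cutoff. The realized
percentile value is computed once, attached to the output, and written
to the manifest.

## Group statistics

Blebbing frequencies are compared by two-sided Fisher's exact tests on
each pair of groups, using the point-probability ("minlike") convention —
the sum of hypergeometric probabilities of tables no more likely than
the observed one — implemented by direct enumeration and cross-checked
in the tests against both a literal enumeration oracle and
`stats::fisher.test`. "FDR" is read as Benjamini–Hochberg, the standard
referent absent other qualification; all pairwise comparisons form the
adjustment family, and the family size is visible in the output.

FA counts are log₁₀-transformed (their raw distribution is right-skewed)
and analysed by two-way fixed-effects ANOVA with interaction plus Tukey
HSD across the four factor-combination cell means. A pseudo-rank
multiple-contrast procedure is out of scope; the package instead emits a
rank-based alternative (pairwise Mann–Whitney U with BH adjustment)
alongside every ANOVA, and the two routes can be compared on any dataset.
Cells removed by the FA cutoffs never enter the group test; rerunning
unfiltered is a one-flag operation in the CLI. An all-identical response
is reported as a no-variance condition with p = 1 rather than an error.

## The synthetic-scene generator

`generate_scene()` renders seeded 768×768 px 16-bit fields with 10 cells
by default and returns complete ground truth. What it emulates:

* smooth spread fibroblasts: area-preserving ellipses (axis ratio
  U(1, 1.15)) with a ≤ 2%-per-harmonic low-frequency radial perturbation;
  cell radius ~ N(50, 6) px truncated to [36, 70] px — the lower
  truncation keeps true nucleus areas above the 1000 px outlier filter so
  that filter removes artifacts, not healthy simulated cells;
* blebbing cells: 6–12 semicircular beads of radius 0.15× the cell
  radius superposed on the ellipse — the bead-like protrusion phenotype;
  the construction is radial, hence always a simple polygon;
* one concentric nucleus per cell at 0.55× the cell radius (true
  cell/nucleus area ratio ≈ 3.3–4.1, inside the < 4.5 rule);
* FA puncta: 5–10 spots of 30–70 px per cell, placed in the cytoplasmic
  annulus with ≥ 10 px edge separation — the regime in which exact count
  recovery is a meaningful contract;
* adhesion-channel contrast: diffuse cytoplasm at 600, puncta at 2400,
  background 200; the nucleus is rendered at 0.8× the cytoplasmic level
  in blebbing cells and 1.6× in smooth cells, so the intensity-ratio
  criterion separates the classes in the direction the blebbing rule
  expects (high cytoplasmic marker signal in blebbing cells);
* optionally touching cell pairs (near-circles placed at 0.88× the sum
  of radii, overlap assigned to the nearer center in radius units) that
  merge into one cell-body region with two nuclei, exercising the
  splitter;
* Gaussian read noise (SD 30 by default) and optional Poisson shot
  noise, applied last and clipped to [0, 65535].

Rasterization uses one fixed convention everywhere: even-odd scanline
fill with pixel centers at integer coordinates. All draws flow through
one seeded generator (`withr::with_seed`), so a scene is a pure function
of its parameters and the caller's RNG state is never touched.

What it does **not** emulate: point-spread-function blur, uneven
illumination, photobleaching, apoptotic morphology, 3D structure,
overlapping cells beyond designated pairs, or FA shape/orientation
variety. Passing the synthetic validation therefore establishes that the
implementation is internally correct under the stated geometry and noise
— not that the shipped thresholds transfer to any particular microscope;
on real data the PST presets and the background-threshold factor are the
knobs expected to need re-tuning.

## Numerical choices and degenerate inputs

* 8-connectivity for all labelling (EBImage's labeller is 4-connected,
  so diagonal-touching components are merged by union-find).
* Sorting for the dimmest-fraction mean is stable; value ties break by
  pixel order, making the threshold deterministic.
* Savitzky–Golay smoothing uses circular padding, preserving closure and
  avoiding endpoint transients; `window = polyorder + 1` would be the
  exact-interpolation identity but windows must be odd, so the identity
  case is `polyorder = window − 1`.
* Collinear curvature triplets return κ = 0; coincident points are an
  error; traces need ≥ 8 points and masks ≥ 20 px.
* Empty segmentations are valid empty label maps, not errors; an
  unplaceable scene (too many/too large cells) errors with the density
  named.
* Fisher ties are included up to a 1e-12 relative tolerance; BH is
  `stats::p.adjust`.
* Validation problem sizes: 20 scenes × 10 cells for classifier and
  segmentation recovery (200 cells), 5 scenes for FA count recovery, 500
  replicates for the Fisher null-calibration (two groups of n = 100 at a
  null blebbing probability of 0.5, where the discrete test's exact size
  is closest to nominal), 10 000 draws for the ANOVA permutation
  cross-check. These sizes give stable metrics at desk scale; they are
  choices of the package's validation design, and all of them rerun from
  scratch in `scripts/acceptance.R`.

## Known limitations

* The PST parameter presets are tuned on synthetic fixtures; real
  micrographs will need preset adjustment, for which every parameter is
  exposed.
* Puncta closer than ~10 px can merge at segmentation; counts are only
  contractual at ≥ 10 px separation.
* The blebbing rule cannot distinguish apoptotic from non-apoptotic
  blebbing — it is a morphology classifier, not a fate readout.
* Field- and plate-level nesting is not modelled in the group tests
  (fixed-effects ANOVA only); a mixed-model layer would be the natural
  extension for multi-plate designs.
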