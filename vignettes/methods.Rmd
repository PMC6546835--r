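---
title: "Area-based quantification of immune-cell killing in 3D gels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Area-based quantification of immune-cell killing in 3D gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytotox3d)
```

## The assay and its quantification model

In a 3D cytotoxicity assay, target cells (for instance CFSE-labelled HeLa)
are embedded in a collagen gel and effector cells (for instance NK-92) are
seeded in the medium at the gel face. Effectors infiltrate the gel, contact
targets, and kill them; a membrane-impermeant dye such as propidium iodide
(PI) marks the dead cells. Three fluorescence channels are recorded: target,
effector, and dead stain. `cytotox3d` quantifies these images with a
deliberately simple *area-based* model that avoids instance segmentation:

1. **Binarization.** Each channel's z-projected image is thresholded at the
   arithmetic mean of its pixel intensities (the "Mean" auto-threshold).
   Foreground is *strictly above* the mean, so a constant image yields an
   empty mask rather than an all-foreground one.
2. **Counting.** The number of effectors in a region is the foreground area
   divided by the mean single-cell area from a manual calibration
   (`estimate_count()`); counts stay fractional, since areas divide
   inexactly and downstream statistics average them anyway.
3. **Live/dead conversion.** Live targets are extended while dead targets
   round up, so one dead cell occupies less area than one live cell. Dead
   target area is converted to an equivalent live-cell area by multiplying
   with the ratio of mean live to mean dead single-cell area, and

   $$\%\,\text{killed} \;=\; 100 \cdot
     \frac{r\,A_\text{dead}}{A_\text{live} + r\,A_\text{dead}},
     \qquad r = \bar a_\text{live} / \bar a_\text{dead}.$$

   We compute $r$ as the ratio of pooled means, not the mean of per-cell
   ratios: the protocol pools cells across raters (five raters selecting
   twenty cells each is the reference design), and the ratio of means is
   what makes the converted area an unbiased count-equivalent.
4. **Spatial profile.** A square region of interest (ROI) of side 700 um is
   split into seven 100-um depth bins, R0 to R6, counted from the gel-media
   interface. Per-bin effector counts and percent killed form the
   infiltration/killing profile; the pooled statistic uses R1-R5 only,
   because R0 and R6 sit at gel boundaries where the capillary meniscus
   makes edges ambiguous. All bins are still reported individually.
5. **Kinetics.** In time-lapse recordings, each kill is characterized by
   the *time for killing*: the interval from first effector-target contact
   to dye uptake in that target. Group comparisons use the classical
   pooled-variance two-tailed Student's t-test
   (df = $n_a + n_b - 2$), reported with a signed t statistic and both
   group means, with no direction assumed.

## Segmentation choices and their failure modes

The Mean threshold is a global statistic: its cutoff is
$\text{bg} + f\,(\text{fg} - \text{bg})$ for foreground fraction $f$. Two
degenerate regimes matter in practice and shaped the defaults:

* **Sparse channels.** When $f$ is a few percent, the cutoff sits close to
  the background and noise leaks through. The quantification path
  (`quantify_scene()`) therefore applies the standard cleanup used in
  interactive image analysis: a 3x3 median *despeckle* before thresholding,
  a 3x3 binary *opening* after it, and a minimum component area
  (default 25 um^2, i.e. about a quarter of a small cell). These steps do
  not systematically shift region areas, which is what counting depends on.
* **Signal-free channels.** With no signal at all, the mean equals the
  background level and about half of the noise lands above it. Two guards
  handle this: for endpoint images, a mask claiming more than 25% of the
  field is read as "no signal" (no stained channel plausibly covers a
  quarter of the field); for time-lapse dead-stain detection, one threshold
  is computed from the *temporal maximum projection* — which contains every
  pixel that is ever stained — and applied to all frames, so pre-kill
  frames stay clean.

Components are 8-connected; live/dead classification is per component, with
a component called dead when at least half of its pixels (default
`overlap_fraction = 0.5`) overlap dead-stain foreground. Bins with no
target area report an *undefined* (`NA`) percent killed rather than zero —
averaging zeros from empty bins would bias killing downward — and replicate
aggregation excludes them pairwise, reporting the per-bin n actually used.

## The synthetic world

No real microscopy data ships with the package; a seeded generator
(`generate_scene()`, `generate_timelapse()`) emulates the statistical
structure the analysis assumes, with exported ground truth so that every
stage is testable. Its fixed defaults are one "stated world":

| parameter | default | rationale |
|---|---|---|
| field / pixel | 700 x 700 um at 2 um/px | matches the ROI; cell-scale resolution |
| targets | 120, 30% dead | tens of cells per bin, as in real profiles |
| live target area | 400 +/- 60 um^2, axis ratio 2.5 | extended epithelial cell footprint |
| dead target area | 200 +/- 30 um^2, disc | rounded dead cell; live/dead ratio 2 |
| effectors | 150, decay length 150 um | monotone R1-R5 decline over the ROI |
| effector area | 120 +/- 20 um^2, disc | lymphocyte-sized |
| intensities | bg 20, fg 200, noise sd 5, 8-bit | clean but non-trivial separation |

Live targets are ellipses, dead targets and effectors discs — the simplest
parametric shapes with analytic areas that reproduce "extended versus
rounded". Cell placement is rejection sampling with a 2-pixel margin
(non-overlap keeps rendered components in one-to-one correspondence with
cells; the margin also survives the 3x3 median, which can bridge a
single-pixel gap). Overlap can be allowed explicitly for stress tests.
Noise is additive Gaussian on a flat background, clipped to the bit depth:
the simplest model that genuinely exercises thresholding. The dead-cell
count is exact (`round(n * dead_fraction)`), not binomial, so truth is
sharp.

Effector depths decay exponentially from the interface. Two refinements
are available beyond the default exact-count placement:

* `infiltration_mode = "flux"` seeds `n_effector_cells` at the face; each
  attempts a uniform depth and *enters* with probability $e^{-d/L}$, while
  blocked cells pile up at the face (half-normal depths, 15-um scale,
  overlap allowed — they crowd in projection). A denser matrix (shorter
  $L$) then shows fewer cells at every analysis depth plus a boundary
  accumulation, which is what raising collagen concentration does in real
  gels — and the boundary pile-up lands in R0, one of the bins the pooled
  statistic excludes for exactly such artifacts.
* `dead_placement = "exposure"` thins dead-target positions by
  $e^{-d/L}$, coupling killing spatially to where effectors reach. With
  it, a shorter decay length concentrates kills near (and beyond) the R0
  boundary and lowers the pooled R1-R5 killing — the qualitative
  density-versus-cytotoxicity trend.

The time-lapse model adds: a reflected Gaussian random walk for effectors
(6 um per 10-min frame by default); contact when the effector disc comes
within `contact_distance` (4 um) of the target's *actual ellipse outline*
(using the equivalent-radius shortcut logged contacts later than the
rendered masks touched); one kill draw per effector-target pair
(probability 0.6); rounding one frame after contact; dye onset at contact
plus a truncated-normal delay (40 +/- 10 min, matching the unimodal spread
of per-event killing times); and — importantly — the killer *docks* at its
victim until dye uptake, emulating the effector-target conjugate. Without
docking, a random walker need never touch the target's mask at all and
contact would be undetectable from rendered images.

What the generator does **not** emulate: point-spread blur and soft cell
edges, intensity variation within and between cells, autofluorescence
gradients, z-attenuation, touching-cell clumps (except the deliberate
face pile-up), target motility, serial killing, and division. A green test
therefore establishes that the *pipeline arithmetic and detection logic*
recover a known world — not that segmentation is robust to real optics.

## Event extraction

`extract_kill_events()` orchestrates kinetics end to end: per-frame
segmentation of each channel, greedy nearest-centroid tracking
(deterministic; ties broken by lowest id; no gap closing), sustained
dead-stain onset per target track (default 30% overlap held for 2 frames,
rejecting single-frame bleed-through flicker), and killer attribution. The
kill is attributed to the effector still in contact when the dye comes up
— the conjugated killer — rather than to the earliest toucher, which is
often a transient bystander; the event's contact time is the onset of that
effector's final contiguous contact run. Contact itself is operationalized
as mask adjacency after a 1-pixel dilation, since visual "contact" has no
unique pixel definition. Only events with both contact and uptake inside
the recording window are reported, so kills near the end of a recording
are conservatively dropped.

Timing granularity is the frame interval: detected uptake is quantized up
by half a frame on average, so recovered killing times carry a positive
bias of about half an interval. This is inherent to frame-based detection,
not a defect, and is why recovery is validated to within one frame
interval.

## Numerical and interface conventions

All physical quantities are um, um^2, and minutes; pixel indices are
1-based in R with the pixel-center convention (`x = (col - 0.5) *
pixel_size`), x increasing toward gel depth. Depth bins are half-open,
`[i w, (i+1) w)`, assigned by pixel center, so per-bin areas sum exactly
to the ROI area. Thresholding is strict (`>`); z-projection defaults to
maximum intensity (standard for sparse fluorescence; mean available).
TIFF I/O is a minimal built-in baseline dialect (uncompressed grayscale
8/16-bit multi-page, both byte orders on read) because the target
environment provides no TIFF package; it is validated against Python's
`tifffile` in the test suite, and interleaved RGB files are rejected with
instructions to split channels. Configurations are YAML (JSON parses as a
subset); unknown keys are rejected by name, and every threshold is checked
against its documented domain. Each pipeline stage is seeded from the
configuration, and identical configurations reproduce identical tables.

## Known limitations

* The area-based count is biased wherever cells genuinely overlap in
  projection; the generator's default non-overlap placement sidesteps what
  real confluent fields would suffer.
* Mean-threshold segmentation degrades for foreground fractions below a
  few percent even with despeckling; the signal-free guard only catches
  the extreme case.
* Tracking is greedy and merge-blind: crossing or touching effectors can
  swap identities. Attribution mitigates but cannot eliminate
  misassignment in crowded fields.
* The t-test assumes equal variances (the classical design choice here);
  with strongly unequal spreads a Welch correction would differ.
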