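---
title: "Quantifying chondrocyte viability, calcium signaling and expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chondrocyte viability, calcium signaling and expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondroquant)
```

chondroquant implements three quantification pipelines used in studies of
articular-cartilage chondrocyte mechanobiology, together with a synthetic
data generator that carries exact ground truth so that every stage of every
pipeline can be verified end to end:

1. **Impact viability**: how much chondrocyte death does an injurious
   impact cause, measured from paired pre/post live–dead confocal Z-stacks
   (calcein-AM marks esterase activity of living cells; ethidium
   homodimer-1 marks membrane-compromised dead cells)?
2. **Calcium responsiveness**: which cells respond to a channel agonist
   (e.g. the PIEZO1 activator Yoda1), and by how much does cytosolic
   Ca^2+^ rise, measured from per-cell ratiometric (Fura-2, 340/380 nm)
   time series?
3. **Expression quantification**: how strong is per-cell immunofluorescence
   (e.g. anti-PIEZO1) across the two articulating compartments of a joint,
   summarized as a control-normalized joint score?

This vignette documents the models, the parameters that matter, the
numerical choices, and what the simulations do and do not establish about
real data.

## Impact-viability imaging

### Pipeline

Each frame (pre- and post-impact) is a two-channel Z-stack. The analysis
is strictly 2-D, matching common practice for overview viability counts:

1. **Maximum-intensity projection** per channel: output pixel = max over
   planes. Projection is idempotent and preserves dimensions.
2. **Registration** of the two frames by integer translation. Specimens
   re-imaged in a fixed holder move essentially in-plane, so translation
   (no rotation/scale) is the model. The shift maximizing the normalized
   cross-correlation (NCC) within `max_shift` (default 50 px) is located
   by FFT cross-correlation of the mean-subtracted combined images and
   refined to the exact NCC maximum over the 8-neighbourhood of the peak.
   A score below `score_floor` (default 0.2) flags the alignment as
   low-confidence but still returns the offset. Registering (post, pre)
   yields the negated offset of (pre, post) on clean pairs.
3. **Otsu threshold** of the combined (elementwise-max of live and dead)
   projection: 256 equal-width bins over the observed min–max range
   regardless of bit depth; class means are computed from the actual pixel
   values in each bin, so the returned cut agrees exactly with an
   exhaustive per-level between-class-variance scan on integer images.
   Ties take the lowest maximizing cut. A constant image is an error — no
   separable classes exist.
4. **Distance-transform watershed segmentation** of the foreground: the
   Euclidean distance map seeds a watershed (EBImage) that splits touching
   cells; seed maxima closer than `min_separation` (default 5 µm, roughly
   one cell radius) are merged. Regions below `min_cell_area` (default
   20 µm², debris) are discarded. Areas are reported in µm² via
   `pixel_size`^2; coordinates are (row, col) pixel indices.
5. **Live/dead classification** per cell: the mean intensity of each cell
   in each channel is divided by that channel's Otsu threshold — a
   per-channel normalization that removes the arbitrary gain difference
   between fluorophores — and the larger scaled mean wins. Exact ties are
   classed *dead* by default: conservative for an injury assay, and
   configurable.
6. **Death-area quantification** inside the overlap ROI implied by the
   registration: the headline quantity is

   death area = (post dead area) − (pre dead area), clamped at 0,

   with the raw signed value retained, plus a dimensionless fraction
   (death area ÷ pre live area in the ROI). Counts use centroid-in-ROI
   membership; areas use per-pixel label membership. This definition is a
   design choice that must be stated prominently: the quantity "area of
   cell death induced by impact" admits several operationalizations, and
   this package fixes the post-minus-pre dead-area difference within the
   registered ROI, with area-based accounting only (individual cells are
   not tracked between frames). Both the absolute area (µm²) and the
   fraction are reported because either may be the quantity of interest.

An optional polygon/cap mask restricts analysis to the articular surface
in view (cells outside the curvature of the humeral head belong to
capsule/tendon stump tissue and are excluded in the source assay); since
the original manual ROI of any given study is unknowable, the mask is a
user input.

## Calcium trace analysis

Traces are per-cell series on a shared, strictly increasing time grid,
either calibrated concentrations (nM) or raw 340/380 ratios — the pipeline
is unit-agnostic and no ratio-to-concentration calibration is imposed
(an optional floor-guarded ratio helper, `compute_ratio()`, is provided).
Defaults mirror a 6-minute acquisition with agonist addition at 1 minute.

* **Baseline**: mean and sample SD over *all* samples strictly before the
  treatment time (the full pre-treatment window, not a trailing
  sub-window). At least 3 baseline samples are required.
* **Responsive-cell criterion**: a cell responds when its post-treatment
  maximum rises at least `k` baseline SDs above the baseline mean,
  `(peak − baseline mean) ≥ k × baseline SD`, with `k = 3` by default and
  the boundary inclusive. The response window runs from the treatment time
  to the end of the trace; no photobleach or drift correction is applied.
  The criterion is scale-equivariant and shift-invariant, and the
  responsive set shrinks monotonically as `k` grows.
* **Set-level summary**: resting Ca^2+^ averages the baselines of *all*
  cells; the evoked response Δ[Ca^2+^] averages (peak − baseline) over
  *responsive cells only* and is reported as missing — never as zero —
  when no cell responds. The responder fraction is reported alongside.

Where the averaging population was ambiguous (all cells vs responders),
the package uses all cells for the resting level and responders only for
the evoked delta; both choices are fixed, documented here, and exercised
by tests.

## Immunofluorescence quantification

* **Integrated density** of a cell = sum of pixel intensities over its
  mask (mean × area). It is additive over disjoint masks and linear in
  intensity. Optional constant background subtraction is off by default.
* **Circularity** = 4πA/P², clipped to [0, 1]. The perimeter is the length
  of the closed 8-connected boundary chain (unit lateral steps, √2
  diagonal steps) from the object contour. On rasters this yields ≈ 0.91
  for a disc of radius 20 px, π/4 within 0.02 for a large square, and
  < 0.2 for a 1×20 line — adequate to separate round chondrocytes from
  elongated debris, which is its only job here.
* **Selection**: cells with circularity ≥ `circularity_min` (default 0.8)
  are ranked most-circular-first, ties broken by descending area then
  ascending label, and the top `n_target` (default 20) per compartment are
  kept; shortfalls keep all qualifying cells and set an under-target flag.
  The ranking rule is a design choice — selection protocols in published
  workflows are rarely stated — and is deliberately deterministic so that
  identical inputs give identical selections. Results can be sensitive to
  this rule; it is configurable.
* **Joint score**: per-compartment means of integrated density are summed
  (humeral + glenoid) into one joint score, optionally normalized by a
  control joint score. A control normalized against itself is exactly 1.
  Compartment assignment uses user-supplied masks (anatomy is not inferred
  from pixels).

**Background caveat.** Without background subtraction the normalized score
estimates (µ_treated + b)/(µ_control + b), not the intensity ratio
µ_treated/µ_control, where b is the shared background contribution per
cell; in our simulations a true 0.6 ratio reads ≈ 0.63 uncorrected. When
the background level is known (as it is for synthetic data) the
constant-subtraction option recovers the ratio to within sampling error;
on real slides, equal staining batches and the control normalization
mitigate, but do not remove, this inflation toward 1.

## The synthetic-data generator

The generator is first-class, tested code; it exists so that every
quantification stage can be validated against exact ground truth without
any external download.

**What it emulates.** Disc-shaped cells (chondrocytes viewed en face)
placed without overlap, optionally inside a cap mask emulating the
spherical articular surface; a focal post-impact death region (cells
inside the impact radius die with elevated probability, switch entirely
from the live to the dead channel); an integer translation of the post
frame (specimen repositioning); 5 Z-planes with Gaussian defocus weights
so projection is exercised nontrivially; additive Gaussian image noise
clipped at zero; calcium traces with bounded baseline fluctuation and
rise-and-decay agonist transients whose noise-free sampled peak equals the
requested amplitude exactly; IF fields of elliptical cells (aspect ratio
derived from a target circularity via Ramanujan's perimeter formula) with
per-cell intensities drawn from compartment-specific truncated normals.

**Seed discipline.** Each spec carries one integer seed; substreams are
fixed offsets (placement at `seed`, state draws — death, responder labels,
intensities — at `seed + 1`, rendering noise at `seed + 2`/`seed + 3`), so
state draws can be replayed independently of placement, and identical
specs reproduce byte-identical outputs. Ground-truth tables rasterize back
to the noise-free images exactly.

**Trace noise is bounded by design.** The responsive-cell criterion
compares the maximum of ~100 post-treatment samples against a
3-SD threshold estimated from ~20 baseline samples. Under Gaussian-tailed
i.i.d. fluctuation this construction has a structural false-positive rate
above 20% *regardless of the noise magnitude or sampling interval* — the
expected maximum of 100 standard-normal draws is ≈ 2.5 SD, and the
estimated threshold is itself noisy. Resting Fura-2 baselines in healthy
cells do not behave this way: their fluctuations are small and bounded,
without spontaneous many-sigma excursions, which is precisely why the
3-SD peak criterion is usable in practice. The generator therefore draws
baseline fluctuation from a uniform (bounded) distribution with the
requested SD; a Gaussian option (`noise_dist = "gaussian"`) exists for
stress-testing the criterion's behaviour under heavy-tailed noise. A
floor parameter (`sd_floor`) keeps the response amplitude well-defined
when the baseline SD is taken to zero.

**Defaults** (stated as plausible-but-uncalibrated; acquisition metadata
such as magnification and SNR are generally unpublished): 384×384 px
fields at 1 µm/px, 150 cells of radius 4–7 µm, cell level 200 and
background 20 intensity units with noise SD 10; impact radius 60 µm with
death probabilities 0.85 inside / 0.05 outside and a (3, −2) px post
shift; 6-min traces sampled every 3 s, baseline 100 ± 5 nM, treatment at
60 s, 70% responders with 8-SD amplitude, rise/decay 4/45 s; IF fields
480×240 px, 25 cells per compartment, intensities 100 ± 15, circularity
0.75–1. A minimum rim gap of 2 px between generated cells keeps
"non-touching" fields actually separable after rasterization.

**What the simulations do not show.** No point-spread function, photon
(shot) noise, bleaching, uneven illumination, partial live/dead
transitions, cell motion other than rigid translation, 3-D overlap, or
out-of-focus debris. Passing on synthetic fields validates the
algorithmic contracts (counts, areas, offsets, criteria, scores are
computed correctly against known truth); it does not certify performance
on real micrographs, whose difficulty is dominated by exactly the effects
listed above.

## Experiments and statistics

`experiment_config()` + `run_experiment()` bind generator templates into
groups, generate and analyze every sample with identical parameters, and
compare the per-sample headline metrics (death area, evoked Δ[Ca^2+^], or
joint score) with the design-appropriate standard test: paired t for two
paired groups (injured limb vs contralateral control of the same animal),
pooled-variance unpaired t for two independent groups, one-way ANOVA for
more (no post-hoc tests, no multiple-testing correction — deliberately
thin, since inference machinery is base R's). α defaults to 0.05.

Paired designs share the *entire* generator stream between groups within
a pair — the same field, the same state draws — so identical templates
produce literally identical samples and a zero difference vector. Exact
degeneracies are flagged rather than emitting infinite statistics: all-zero
differences report p = 1; zero-variance nonzero differences report NA with
the `degenerate` flag.

Reports carry provenance (an FNV-1a hash of the canonical JSON of the
config, the master seed, per-sample seeds, package version) and are
byte-identical across re-runs of the same config.

## Verification problem sizes

The shipped test-suite checks run at sizes chosen to make their
statistical assertions sharp while staying quick on a laptop: 50 random
8-bit images against the exhaustive Otsu scan; noise-free fields of 1, 10
and 100 discs plus three default-noise fields for segmentation
recall/precision; 5 noise-free and 100 noisy registration trials with
shifts up to ±20 px; 20 fields for death-area recovery under certain
in-zone death; 400 cells for responder classification; 40 replicate
4-vs-4 paired experiments for the Δ[Ca^2+^] ordering; 5 sample pairs at
20 selected cells per compartment for the 0.6 expression-ratio recovery;
and 10⁴ null replicates for the type-I calibration of both t-tests.

## Known limitations

* Registration is integer-translation only; rotation, scale or nonrigid
  deformation produce a best-effort translation with a low NCC score.
* Watershed over-splits strongly elongated cells when `min_separation` is
  much smaller than the cell's long axis, and merges cells that touch
  along flat boundaries; both are controlled by one parameter.
* The live/dead rule is a two-channel dominance rule; partially stained
  (dying) cells are forced into one class.
* Death-area accounting is areal, not cellular: cell shrinkage or swelling
  between frames moves the raw signed value.
* The 20-cell selection rule and the circularity threshold materially
  shape IF scores and have no canonical published setting; treat
  cross-study comparisons of absolute joint scores with caution and rely
  on control-normalized values.
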