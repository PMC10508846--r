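# chondroquant

Quantification pipelines for articular-cartilage chondrocyte experiments,
written for researchers studying chondrocyte mechanobiology (impact injury,
mechanosensitive channels such as PIEZO1/TRPV4) who need reproducible,
testable replacements for one-off image-analysis scripts.

The package implements three analyses plus the machinery to validate them:

* **Impact viability** — from paired pre/post live–dead confocal Z-stacks
  (calcein-AM / ethidium homodimer-1): maximum-intensity projection, Otsu
  thresholding (256-bin, exhaustive-scan-exact), distance-transform
  watershed segmentation, per-cell live/dead classification, integer-
  translation registration of the pre/post frames by normalized
  cross-correlation, and the headline *impact-induced death area*

  `death area = max(0, dead area_post − dead area_pre)` within the
  registered overlap ROI (raw signed value and the fraction of pre-impact
  live area are also reported).

* **Calcium responsiveness** — per-cell ratiometric (340/380 nm) traces:
  baseline `[Ca²⁺]₀` = mean over the full pre-treatment window; a cell is
  *responsive* iff `peak − mean(baseline) ≥ k · SD(baseline)` (k = 3,
  boundary inclusive); the evoked response `Δ[Ca²⁺]` averages
  `peak − baseline` over responsive cells only.

* **Immunofluorescence quantification** — per-cell integrated density
  (Σ intensity over the cell mask) on thresholded images, circularity
  `4πA/P²` ROI selection (top 20 most-circular cells per compartment by
  default), per-compartment means, their sum as a whole-joint score, and
  normalization to a control joint score.

A synthetic-data generator (`generate_impact_pair()`, `generate_traces()`,
`generate_if_field()`) produces all three input types with exact ground
truth, and `experiment_config()` / `run_experiment()` drive simulated
group-comparison experiments through the standard paired/unpaired t-tests
or one-way ANOVA with byte-reproducible, provenance-stamped reports. See
the methods vignette (`vignettes/chondroquant-methods.Rmd`) for models,
parameter meanings and design rationale.

## Worked example

Simulate a 2 mJ-style impact experiment — 150 cells in a 384×384 µm field,
a 60 µm focal death region, the post frame translated by (5, 4) px — and
quantify it:

```r
library(chondroquant)

spec <- impact_spec(field_spec(seed = 11), post_shift = c(5, 4))
pair <- generate_impact_pair(spec)
analysis <- analyze_viability_pair(pair$pre, pair$post)
print(analysis)
#> <roi_alignment> offset (+5, +4) px, NCC 0.986
#> <viability_result>
#>   pre : 150 live / 0 dead, 13704 / 0 um^2
#>   post: 134 live / 16 dead, 12283 / 1421 um^2
#>   impact-induced death area: 1421 um^2 (raw +1421), fraction 0.104

sum(pair$truth$area_um2[pair$truth$post_state == "dead"])
#> [1] 1421
```

The registration recovered the simulated (5, 4) px specimen shift exactly;
16 of 150 cells died, and the measured death area (1421 µm², 10.4% of the
pre-impact live area in the ROI) matches the generator's ground truth
exactly in this noise setting.

Calcium traces work the same way — 200 cells, 6-min acquisition, agonist
at 60 s:

```r
sim <- generate_traces(trace_sim_spec(n_cells = 200, seed = 3))
analyze_traces(sim$traces, k = 3)
#> <responsiveness_result> 200 cell(s), 66% responsive (k = 3)
#>   resting [Ca2+]: 99.9 nM; evoked delta[Ca2+]: 44.5 nM
```

66% of cells met the 3-SD criterion (the simulated responder fraction is
0.7); resting calcium is recovered at 99.9 nM (true 100 nM) and the mean
evoked rise is 44.5 nM (simulated noise-free amplitude 40 nM, plus the
expected upward peak-of-noise contribution).

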