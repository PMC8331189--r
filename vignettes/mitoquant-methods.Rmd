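---
title: "Quantifying mitophagy and autophagy from tandem mCherry-GFP reporter images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitophagy and autophagy from tandem mCherry-GFP reporter images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoquant)
```

## The measurement problem

Tandem mCherry-GFP reporters exploit the pH sensitivity of GFP: a reporter
targeted to the outer mitochondrial membrane (the mito-QC design) or to
autophagosomes (the auto-QC design) fluoresces in both red and green in the
neutral cytosol, but once the tagged structure is delivered to a lysosome
the acidic lumen quenches GFP while mCherry persists. Mitophagy and
autophagic flux therefore appear as **red-only puncta**: mitolysosomes in
the mito-QC system; autolysosomes in the auto-QC system, where red+green
puncta are autophagosomes that have not yet fused with a lysosome.

`mitoquant` reimplements, as tested and reusable R code, the quantitation
chain used with such reporters:

1. **Despeckle** each channel with a median "fine filter".
2. Build a **ratio image** `(red + 1) / (green + 1)`, capped at 100.
3. **Mito-QC mode**: mitolysosomes are connected components of pixels with
   ratio `>= ratio_thr_high` *and* red `>= red_thr` (double thresholding:
   the second, red threshold rejects spurious high-ratio pixels where the
   reporter is barely expressed), within a region of interest.
4. **Auto-QC mode**: candidate objects are components of red
   `>= red_high_thr`; each object is classed autolysosome if its mean
   ratio is `>= ratio_thr_high`, autophagosome otherwise.
5. **Normalization**: per µm² of an immunolabelled cell-type stain (TH,
   Iba1, GFAP, calbindin), per counted cell body, or per single-cell ROI.
6. **Colocalization**: object-level overlap of puncta with a thresholded
   organelle stain (e.g. ATPB for mitochondria).
7. **Statistics**: percentage of mitophagic cells against a trimmed-mean
   threshold, per-subject averaging, one-/two-way ANOVA with Tukey HSD,
   TEM score aggregation, and the two-sample power calculation used for
   cohort sizing.

Because the microscopy data behind the original findings are not publicly
deposited, the package ships a synthetic scene generator with per-object
ground truth; every stage is validated against that oracle rather than
against irreproducible images.

## The synthetic stated world

`scene_spec()` fixes the world the generator draws from. The defaults
emulate a 63× confocal field of fibroblasts:

| knob | default | unit | why |
|---|---|---|---|
| `image_shape` | 256 × 256 | px | one field of view at desk-test scale |
| `pixel_size` | 0.2 | µm/px | Nyquist-ish sampling at 63×/1.4 |
| `n_cells` | 4 | – | a sparse culture field |
| `cell_radius_px` | 30 | px | 6 µm soma-scale cell disks |
| `mito_density` | 0.15 | – | fraction of cell area covered by network |
| `n_mitolysosomes_per_cell` | Poisson(4) | – | a handful per cell under basal conditions |
| `quench_factor` | 0.1 | – | acidified compartments retain 10% of GFP |
| `punctum_gain` / `red_gain` | 150 / 100 | a.u. | puncta brighter than the network |
| `background_level` | 10 | a.u. | camera offset + diffuse signal |
| `psf_sigma` | 1 | px | ~0.4 µm FWHM Gaussian PSF |
| `noise_model` | Poisson scale 1, read σ 2 | – | shot noise + read noise |
| `punctum_radius_px` | 2–3 | px | 0.8–1.2 µm mitolysosome diameter |
| `min_gap_px` | 4 | px | keeps puncta resolvable after blur |

Rendering order is: paint geometry → record ground truth → PSF blur
(kernel truncated at 3σ, so signal is *exactly* zero beyond the kernel
radius) → add background → Poisson shot noise → Gaussian read noise. Each
degradation stage can be disabled independently, so tests can isolate any
stage. Ground truth is always recorded before degradation.

Three design choices deserve comment:

* **Non-overlapping puncta.** Puncta of all classes are placed by
  rejection sampling with a minimum gap, so the ground-truth count is
  unambiguous (no merged objects). The gap (4 px) plus the truncated PSF
  guarantees two puncta can never bridge into one component in a
  noise-free image.
* **Punctum size.** A 2–5 px radius range is geometrically possible but
  radius-5 puncta plus the anti-overlap gap can exceed the packing
  capacity of a default cell at Poisson-tail counts, making the generator
  reject otherwise-valid worlds. The default range is therefore 2–3 px —
  which is also the more realistic mitolysosome diameter at this pixel
  size — and the layout sampler retries a fresh layout a few times before
  rejecting. Larger radii remain available through `punctum_radius_px`.
* **Named random substreams.** All randomness derives from one scene seed
  through named substreams (`counts`, `layout`, `labels`, `overlap`,
  `noise`), each consumed in a documented order. A test can therefore
  replay, say, the per-cell count draws independently of the layout — the
  re-draw oracles in the test suite do exactly this.

What a green test on this world does **not** establish: performance on
real tissue (anisotropic PSF, autofluorescence, uneven illumination,
overlapping cells, 3-D structure collapsed into projections), robustness
to segmentation of touching puncta, or the correctness of any particular
threshold value for a given microscope. Thresholds in the original
workflow were frozen per organ/experiment set but never published;
fidelity is at the level of the procedure, not bit-level reproduction of a
proprietary pipeline.

## Detection parameters

`threshold_config()` freezes one set of thresholds per experiment set:

* `ratio_thr_high = 2`: sits between the neutral-pH ratio (≈1, since red
  and green gains match) and the quenched ratio (≥3 at
  `quench_factor = 0.1`) in calibration scenes. In practice this value
  should be calibrated per batch, e.g. on a no-quench control.
* `red_thr = red_high_thr = 50`: above background (10) and diffuse
  cytosolic signal (≈30), below the blurred punctum core (≥75).
* `min_area_px = 4`, `connectivity = 8`: unstated in the original
  workflow; exposed and recorded in output provenance.
* The fine filter is a 3×3 median by default (the standard despeckle
  choice); the radius is configurable and idempotence is not assumed.

The ratio uses a +1 pseudocount rather than raw division: the original
software's divide-by-zero behaviour is unstated, and the pseudocount is
monotone, bounded (cap 100), and exact on integer-scaled intensities.

Classification in auto-QC mode is **object-level** (mean ratio per
object): a pixel-wise rule can split one object across the threshold and
count it twice. A `pixelwise = TRUE` mode is retained for fidelity
checks; with it, partition of detected area still holds but object counts
need not match the object-level rule.

## Statistics

* **Mitophagic-cell threshold**: the per-cell mitolysosome counts of the
  reference condition (untreated wild type) are reduced to a symmetric
  trimmed mean (default trim 0.2 per tail; an interquartile-fence rule is
  provided as an alternative because the original description does not
  fix the rule). Cells are called mitophagic when their count is
  *strictly above* the threshold; trimming influences only the
  threshold, never the classified data.
* **Unit of analysis**: image-level records are averaged per subject
  before any inference; the ANOVA runs on subject means.
* **Two-way ANOVA** uses the interaction model with type-II sums of
  squares (computed by nested-model RSS comparisons), the conventional
  default for unbalanced cohorts such as 5 knockouts vs 10 wild types.
  Tukey HSD compares all cell means with the Tukey–Kramer standard error;
  stars follow the {0.05, 0.01, 0.001, 0.0001} convention.
* **Power**: `sample_size_two_means()` is the normal-approximation
  two-sample equality design,
  `n = 2σ²(z₁₋α/₂ + z₁₋β)² / δ²`. With the pilot values (mean 60.6,
  SD 19.8, 40% detectable change, α = 0.05, power 0.8) it returns 10.47
  unrounded, 10 per group — both are reported because the unrounded value
  is what "~10" hides. The companion `power_two_means()` gives the
  analytic power at a fixed n; the test suite verifies that simulated
  two-group experiments at n = 10 reach this power within ±10 points
  (the normal approximation is slightly optimistic relative to the
  t-test actually run, ~78% vs ~75%).

## Numerical and degenerate-input choices

* Coordinates are 0-based row/col pixel indices; areas are reported in px
  and µm² (`area_µm² = area_px × pixel_size²`). Calibration is required:
  a file without pixel-size metadata and without an override fails hard
  rather than assuming 1 µm.
* Empty region masks yield an empty puncta set with a warning record;
  zero stained area or zero cell bodies yield `NA` with a warning, never
  division by zero. Empty puncta sets give `NA` colocalization
  percentages.
* Per-cell attribution uses the punctum centroid (a punctum belongs to at
  most one cell); colocalization uses pixel overlap (≥1 shared pixel by
  default, an overlap-fraction rule is configurable). These mirror the
  two distinct uses in the original workflow.
* Connected components use two-pass union-find (compiled); ties and label
  order are canonicalized, and equivalence with a brute-force flood fill
  is property-tested for both connectivities.
* The TIFF codec is deliberately minimal (uncompressed little-endian
  grayscale, one page per channel, 8/16-bit unsigned or 32/64-bit float):
  no TIFF library is available in the target environment. Channel order
  and pixel size ride in the ImageDescription tag; files read back
  losslessly at 64-bit and are readable by standard tools.

## Known limitations

* 2-D single planes only; no 3-D stacks, photobleaching, chromatic
  aberration, or pH-continuum modelling.
* No machine-learned segmentation, deconvolution, or time-lapse tracking.
* The automated cell-body counter (area-window rule, default 30–700 µm²)
  is validated only against synthetic truth; whether the original counts
  were manual is unknown.
* Mixed-effects modelling of image-within-subject nesting is out of
  scope; subjects are averaged, as in the original analysis.
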