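---
title: "Methods: segment occupancy and cross-modality morphometry of the inferior alveolar nerve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segment occupancy and cross-modality morphometry of the inferior alveolar nerve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iansegmap)
```

## The problem

The inferior alveolar nerve (IAN) runs inside the bony inferior alveolar
canal (IAC) of the mandible. CBCT images the canal's cortical boundaries
but not the nerve; 3D-DESS MRI shows the nerve as a hyperintense tubular
signal. Two questions drive the analysis this package implements:

1. *Where inside the canal does the nerve sit?* Answered by partitioning
   the canal cross-section into six segments on a coronal reference slice
   and scoring each segment for nerve signal, aggregated over a cohort
   into marginal and conditional occupancy percentages.
2. *How do canal and nerve calibers relate across modalities?* Answered
   by per-plane maximum-diameter morphometry of canal (CBCT, MRI) and
   nerve (MRI), per-observation conversion factors, and a paired Wilcoxon
   comparison of the two factor types.

Clinical image data of this kind are not publicly deposited, so the
package ships a phantom generator with fully known ground truth; all
validation is property- and simulation-based.

## The six-segment partition

On the reference slice, a *baseline* is placed through the alveolar crest
of the buccal cortical plate; its orientation defines "horizontal"
(default: the image row direction, configurable via
`baseline_angle_deg`, since the scanner's head orientation cannot be
recovered from pixels). The *midline* is the parallel line through the
nerve midpoint. The chord of the canal mask along the midline — the
intraosseous canal diameter — is divided into three equal-length thirds
by two perpendiculars. Each canal pixel is then labeled by the side test
against the midline (superior/inferior) crossed with its third
(buccal/middle/lingual), giving segments 1–3 superiorly and 4–6
inferiorly, with 1/4 buccal and 3/6 lingual. The buccal direction is
resolved from the anatomical side, so left and right partitions mirror
one another (`mirror_partition()` is an exact involution).

Numerical conventions, chosen for deterministic, pixel-exact tiling:

- Pixels exactly **on the midline** go to the inferior band; pixels
  exactly **on a perpendicular** go to the middle third (half-open
  interval convention).
- The chord is traced by marching along the midline in steps of a
  quarter pixel and taking the extreme in-mask parameters. Where the
  perpendiculars cut the chord is not uniquely determined by the verbal
  construction ("divided by two perpendiculars"); equal thirds of the
  chord is the only symmetric reading and is the default
  (`rule = "chord_thirds"`). The alternative reading — thirds of the
  mask's full projected extent — is available as `rule = "bbox_thirds"`
  and the rule used is recorded in every partition object.
- Coordinates are pixel indices with physical positions
  `(i - 0.5) * spacing` mm from the slice corner.

The implementation is validated against an independent scalar-loop
per-pixel classifier (exact label equality) and by a tiling property
(six disjoint labels exactly covering the mask) over hundreds of random
elliptical slices, plus rotation-covariance checks at the discretization
bound.

## Occupancy scoring

A segment is *visible* when the fraction of its area covered by the
nerve mask is at least the threshold (default 0.5). The rule is
**inclusive at exactly one half** — a fraction of precisely 0.5 counts as
visible. Scoring is 2D on the single coronal reference slice, matching a
reference-layer read-out; segments with zero area score 0 with a warning
flag. Cohort tables report, per segment, the marginal percentage of
records with visibility ("Generally Yes") and the 6×6 conditional
percentages ("If Segment i Yes"); joint counts are symmetric and
stratified tables pool additively, which the tests assert exactly. Every
table carries its `n_records`, so cohorts with absent sides (e.g. 36
evaluated nerves from 19 subjects) are transparent about denominators.

The hyperintensity mask itself is extracted by a global threshold at the
midpoint between the canal background level (10% quantile inside the
canal mask — robust even when the nerve fills most of the canal) and the
nerve peak (99.5% quantile), followed by selection of the connected
component containing the nerve midpoint. Extraction fails loudly (a
`segmentation_failure` condition, logged and excluded, never imputed)
when the canal shows no hyperintense class (`min_contrast = 30`
intensity units; keep this above roughly five times the image noise SD)
or no component contains the midpoint.

## Morphometry

Structures are segmented by seeded region growing (6-connected,
implemented as a vectorized frontier BFS), with intensity criteria
chosen per structure:

- **IAC on MRI**: everything brighter than the midpoint of the volume's
  dark tail (1% quantile, the cortical class) and its median (bone and
  canal interior). This keeps the criterion independent of whether the
  seed lands in interior or nerve tissue.
- **IAC on CBCT**: below 1.35× the local seed mean (the bright cortical
  ring and surrounding bone are excluded; the ring bounds the growth).
- **IAN on MRI**: above 0.72× the local seed mean at the nerve midpoint.

Growth that floods more than a configurable fraction of the volume
(default 25%) raises a leakage error; requesting the nerve on CBCT is a
modality error, since CBCT carries no nerve contrast. After growth,
in-plane holes are filled (so the canal mask includes the nerve it
contains) and a slice-wise morphological closing (radius 1 pixel) is
applied; the seed's connected component is returned together with all
parameters used.

Diameters are the **maximum Feret diameter** (maximum caliper width over
all in-plane directions) of the 2D cross-section through the site center
in each plane — our operationalization of the "maximum extension of the
diameter"; a slab-projection mode (`slab_halfwidth_mm`) is available but
single-slice is the default. The Feret value is computed over the convex
hull of the *pixel squares* (each mask pixel contributes its four
corners): bare pixel centers systematically undershoot the region
footprint by up to a pixel per end, while the square support keeps the
error within about one pixel diagonal in either direction. No sub-pixel
contour fitting is attempted, for determinism. Feret values are asserted
to match a brute-force pairwise boundary-corner-distance oracle exactly,
and recovery of known ellipse axes is asserted within `sqrt(2) * spacing`
on noiseless phantoms.

## Conversion factors and inference

For each subject/side/site/plane the two factors are
`IAC(CBCT)/IAN(MRI)` and `IAC(MRI)/IAN(MRI)`. Summaries are the
arithmetic mean and sample SD (denominator n−1) of the per-observation
ratios over all subjects and sides — the **mean of ratios**, never the
ratio of mean diameters; the two differ materially (diameter pairs 4/1
and 2/2 give a mean factor of 2.5 but a ratio of means of 1.5, a
regression test in the suite). For inference, observations are first
averaged over each subject's left and right sides, leaving one paired
observation per participant; the per-subject difference of the two
factor types is tested against zero with a one-sample Wilcoxon
signed-rank test, two-sided, decision at p ≤ 0.05.

Signed-rank details: zeros are dropped before ranking by default (the
classic procedure and the default of standard statistical software); the
Pratt variant (zeros ranked, then discarded from the statistic, normal
approximation with adjusted moments) is available via
`zero_handling = "pratt"`. Without ties and with at most 25 differences
the exact null distribution is used; otherwise a normal approximation
with mid-ranks, tie correction and continuity correction. Exact
p-values are verified against full 2^n enumeration for n ≤ 12, and the
test's null rejection rate is checked by simulation (1000 replicates at
the study's n = 19) to lie near the nominal 5%. An all-zero difference
vector is reported as degenerate with p = 1 and no rejection rather than
an error.

Which n underlies a published SD ("over all subjects and sides" for
means vs one-per-participant for the test) is ambiguous in verbal
descriptions; both conventions are computed and labeled
(`summarize_factors()` vs `side_average()`).

## The phantom generator

One subject side is a 14 × 18 mm coronal field over a mesiodistal extent
of `n_slices × 0.75` mm (default 10.5 mm), holding an elliptical canal
tube (default semiaxes 1.95 × 2.65 mm, i.e. 3.9 mm buccolingual and
5.3 mm superoinferior canal diameters, matching published CBCT canal
morphometry) with a cortical ring (default 1.2 mm thick — kept above one
MRI voxel diagonal so the ring rasterizes closed), and a circular nerve
tube (default radius 1.3 mm) inside it, optionally undulating
buccolingually. The tube is closed by cortical end caps so the canal
interior is a bounded region in both modalities. MRI (0.75 mm isotropic)
renders a dark ring and a Gaussian-blurred hyperintense nerve top-hat;
CBCT (0.16 mm) renders a bright ring, a flat interior and **no** nerve
contrast. Noise is additive Gaussian (default SD 5 on contrasts of
60–120): the pipeline thresholds intensities, it does not model noise
physics, so Rician corrections would add nothing testable. Right sides
mirror the buccolingual axis through one code path.

Cohorts draw subject-level anatomy from Gaussian distributions
(canal semiaxis SDs 0.42/0.52 mm from published 3.9 ± 0.85 and
5.3 ± 1.03 mm diameters; nerve radius 1.3 ± 0.25 mm, kept below 85% of
the smaller canal semiaxis so the nerve fits; per-side asymmetry jitter
0.1 mm; nerve-course undulation amplitude 0.3 ± 0.15 mm so the two
molar sites genuinely differ). A per-side absent probability of 2/38
reproduces the published design scale of 36 evaluated nerves from 19
subjects in expectation, and retention-type labels follow the published
frequency table; they are carried as opaque stratification categories
only.

Ground truth is analytic: per-slice ellipse/disk descriptors, landmark
coordinates, and per-plane true Feret diameters computed from finely
sampled boundary points of the analytic cross-sections. The
`truth_occupancy()` oracle integrates the nerve disk over analytically
constructed segments on a 1200² quadrature grid (boundary-cell error
bound ~16/n_grid, reported with the result), using the closed-form chord
of the midline through the ellipse — fully independent of the raster
pipeline it checks.

What the phantom does **not** emulate: tooth roots and real trabecular
texture, metal and motion artifacts, partial-volume and bias fields,
oblique canal courses relative to the scan axes, and reader variability.
Passing tests therefore demonstrate correctness of the geometry,
scoring, measurement and inference machinery under known truth — not
clinical performance on patient scans. One visible consequence: because
the phantom canal runs exactly mesiodistally, axial and sagittal
cross-sections of the straight tube are dominated by the tube length, so
their in-plane Feret diameters (and hence axial/sagittal conversion
factors near 1) are not numerically comparable to clinical values, while
the coronal plane maps directly onto familiar canal/nerve diameters.
A second consequence: at 0.75 mm MRI voxels the measured canal diameter
carries a positive bias of up to about one voxel relative to 0.16 mm
CBCT, so on phantoms with identical cross-modality anatomy the paired
factor comparison detects this resolution bias rather than an anatomical
difference.

## Reproducibility and problem sizes

All randomness flows from explicit integer seeds (`phantom_params$seed`,
cohort seed, pipeline config seed); volume seeds for cohort sides are
drawn once from the cohort stream, and a synthetic pipeline run is
bit-identical under a fixed configuration — the provenance block records
a config hash and package version, deliberately no timestamp, so written
CSVs hash equal across reruns. The validation suite uses problem sizes
chosen to exercise each property well inside a desktop budget: 200
random slices for tiling, ten instances for exact classifier equality,
quadrature at 0.05 and 0.025 mm/pixel (tolerances 0.02 and 0.01),
twenty noiseless phantoms for diameter recovery, ratio recovery at
n = 36 observations with 5% diameter noise, 1000-replicate null
calibration at n = 19, and a full 19-subject end-to-end run executed
twice for bit-identity.

## Known limitations

- Landmarks are taken as given (phantom truth or JSON); no automatic
  landmark detection.
- Occupancy is scored on a single reference slice; a multi-slice mode
  exists in the scoring path but is off by default.
- File ingestion is NIfTI-only; DICOM series must be converted upstream.
- The segmentation is intentionally simple (interval region growing);
  it stands in for interactive contour tools and is not a clinical
  segmentation method.
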