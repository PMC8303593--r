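# iansegmap

Localizing the inferior alveolar nerve (IAN) inside the inferior alveolar
canal (IAC) on coronal reference images, and relating canal and nerve
calibers across imaging modalities.

CBCT shows the canal's osseous boundaries but cannot display the nerve;
3D-DESS MRI shows the nerve as a hyperintense tubular signal inside those
boundaries. Surgeons planning third-molar extractions therefore want to
know *where inside the canal* the nerve usually sits, and how canal
measurements made on one modality translate to nerve measurements on the
other. `iansegmap` implements that analysis as a tested, reusable R
pipeline:

- **Six-segment partition.** On the coronal reference slice, a horizontal
  baseline is placed through the alveolar crest of the buccal cortical
  plate and a parallel midline through the midpoint of the IAN. The
  midline's chord across the canal mask is cut into equal thirds by two
  perpendiculars, tiling the canal into segments 1–6 (upper/lower ×
  buccal/middle/lingual), pixel-exactly.
- **Occupancy scoring.** Each segment is "visible" when at least half of
  its area contains hyperintense nerve signal (inclusive at exactly one
  half). Cohort records aggregate into marginal percentages
  (*P(segment s visible)*) and conditional co-occurrence percentages
  (*P(segment j | segment i)*), pooled and stratified by retention type.
- **Morphometry.** Canal (CBCT and MRI) and nerve (MRI only) are
  segmented by seeded region growing; the maximum Feret diameter
  (maximum caliper width) of the structure's cross-section through the
  site center is measured in the axial, sagittal and coronal planes.
- **Conversion factors.** Per observation and plane,
  `IAC(CBCT)/IAN(MRI)` and `IAC(MRI)/IAN(MRI)` diameter ratios are
  summarized as mean ± SD of ratios over all subjects and sides; for
  inference, factors are first averaged over each subject's two sides and
  the per-subject difference of the two factor types is tested with a
  one-sample Wilcoxon signed-rank test (exact null distribution in the
  tie-free case, decision at p ≤ 0.05).
- **Synthetic phantoms.** Because clinical scans of this kind are not
  publicly available, a phantom generator renders paired CBCT-like
  (0.16 mm voxels, bright cortical ring) and MRI-like (0.75 mm voxels,
  dark ring, hyperintense nerve) volumes with fully known ground truth,
  so every stage is validated against analytic oracles: exact brute-force
  partition classification, fine-grid quadrature occupancy, pairwise
  boundary-distance Feret values, and full 2^n signed-rank enumeration.

## Worked example

```r
library(iansegmap)

cfg    <- pipeline_config(n_subjects = 5, seed = 42)
report <- run_pipeline(cfg)
print(report)
#> <study_report>
#>   sides evaluated: 9, occupancy records: 18, failures: 0
#>   M3 marginal %: 0.0 22.2 0.0 33.3 88.9 11.1 (n = 9)
#>   M2 marginal %: 0.0 0.0 0.0 55.6 66.7 11.1 (n = 9)
#>   Wilcoxon comparisons (CBCT vs MRI factor):
#>     M2_axial     p = 0.0625
#>     M2_sagittal  p = 0.0625
#>     M2_coronal   p = 0.3125
#>     M3_axial     p = 0.0625
#>     M3_sagittal  p = 0.0625
#>     M3_coronal   p = 0.3125

print(report$occupancy_tables$M3$pooled)
#> <cooccurrence_table> site M3, n = 9
#>                  seg1 seg2 seg3  seg4  seg5 seg6
#> Generally Yes       0 22.2    0  33.3  88.9 11.1
#> If Segment 1 Yes    -    -    -     -     -    -
#> If Segment 2 Yes    0    -    0  50.0 100.0  0.0
#> If Segment 3 Yes    -    -    -     -     -    -
#> If Segment 4 Yes    0 33.3    0     - 100.0 33.3
#> If Segment 5 Yes    0 25.0    0  37.5     - 12.5
#> If Segment 6 Yes    0  0.0    0 100.0 100.0    -
```

Five subjects yielded nine evaluable sides (one side was absent), each
scored at the third-molar (M3) and second-molar (M2) reference slices.
The "Generally Yes" row gives the probability of finding nerve signal in
each segment — the lower middle segment (5) is occupied most often, as
expected for a nerve running along the canal floor. The conditional rows
read "if segment *i* holds nerve signal, segment *j* does too in x% of
records". The Wilcoxon block compares the CBCT-based and MRI-based
conversion factors per plane; at n = 9 sides (5 subjects) the exact test
has little resolution, and a study-scale run (19 subjects) is used for
the real analysis.

`write_report(report, "out/")` writes the tidy CSV set (occupancy
records, co-occurrence tables in the published layout, diameters,
conversion summaries) plus a full-precision `report.json`. Volumes,
landmarks and manifests round-trip through NIfTI/JSON/CSV
(`export_cohort()`, `read_volume()`, files-mode `run_pipeline()`).

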