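# MARbench

Quantitative, vendor-neutral benchmarking of CT **metal artifact
reduction (MAR)** algorithms with a cylindrical single-insert phantom —
for medical physicists and imaging scientists who need numbers, not
impressions, on what a MAR implementation does to CT-number accuracy and
geometry.

Metallic implants produce streaks and CT-number (CTN) bias that propagate
across the field of view; MAR algorithms suppress them with undisclosed,
vendor-specific processing. MARbench characterizes that processing from
the outside using a phantom of known geometry: an 11.9 cm resin cylinder
with a central 28.0 mm channel holding interchangeable inserts — a
12.7 mm core of solid water (the control), aluminum, titanium, or 316
stainless steel in a solid-water housing — scanned with and without MAR.

## Metrics

For a scan pair (non-MAR, MAR) and the solid-water control of the same
session:

* **Circular profile deviation** — CTN sampled on circles of radius
  1.27, 2.80 and 3.80 cm about the insert centre, over five consecutive
  slices; reported as mean |ΔCTN| against the control's per-radius mean.
  Circles see streaks in every direction; lines do not.
* **Geometric accuracy** — the core segmented at 50% of its maximum CTN,
  reduced to the area-equivalent diameter *d* = 2√(A/π), compared with the
  physical 12.7 mm (error in mm and %).
* **Bad-voxel / M-error analysis** — inside a 15.0–45.0 mm annular mask, a
  voxel is *bad* if |ΔCTN| > 40 HU versus the expected solid-water value;
  the composite index

      M_error = (% bad voxels / 100) × mean |ΔCTN| of bad voxels

  combines artifact extent and intensity, and
  ΔM_error = M_error(non-MAR) − M_error(MAR) measures the improvement MAR
  delivers.
* **Difference maps and histograms** — ΔCTN = CTN(non-MAR) − CTN(MAR)
  maps with 3rd–97th percentile display clipping, and cumulative
  histograms of annular deviations in 5 HU bins.

Real data enter through `loadDicomSeries` (DICOM CT, Explicit VR Little
Endian, rescale slope/intercept) or the portable NIfTI container
(`saveVolume` / `loadVolume`). Because scanner reconstructions are rarely
redistributable, the package also ships a parallel-beam polychromatic CT
simulator (two-energy beam hardening, Poisson noise, photon-starvation
floor, filtered back-projection) plus a reference sinogram-inpainting MAR,
so the entire metric suite runs end to end on synthetic ground truth.

## Worked example

```r
library(MARbench)

cfg <- simConfig(nSlices = 3L, noiseSeed = 7L)   # 256 x 256, 180 views
set <- makeScanSet(cfg)                          # 4 inserts, non-MAR + MAR
bl  <- computeBaseline(controlPair(set), radialConfig(nSlices = 3L))

circularDeviation(scanPairs(set)$stainless_steel, bl,
                  radialConfig(nSlices = 3L))
#>     scanner        material    arm radius_mm mean_abs_dctn_hu
#> 1 simulator stainless_steel nonMAR      12.7           25.632
#> 2 simulator stainless_steel nonMAR      28.0            9.635
#> 3 simulator stainless_steel nonMAR      38.0           12.883
#> 4 simulator stainless_steel    MAR      12.7           15.898
#> 5 simulator stainless_steel    MAR      28.0           15.238
#> 6 simulator stainless_steel    MAR      38.0           21.197

deltaMError(scanPairs(set)$stainless_steel, bl)
#> MErrorResult (|dCTN| > 40 HU, 3 slices)
#>   nonMAR  bad 22.26 +/- 0.13 %, mean|dCTN|_bad 59.4 HU, M_error 13.23
#>   MAR     bad 11.57 +/- 0.12 %, mean|dCTN|_bad 49.6 HU, M_error 5.74
#>   delta M_error: 7.49

diameterReport(scanPairs(set)$titanium, nSlicesAnalyzed = 3L)
#> DiameterResult (d_true = 12.70 mm, 3 slices)
#>   mean diameter: 12.62 mm
#>   diameter error: 0.08 +/- 0.00 mm
#>   percent error: 0.66 +/- 0.00 %
```

Reading: without MAR, steel deviations concentrate near the insert
(25.6 HU at 1.27 cm vs 12.9 HU at 3.80 cm) and 22% of annulus voxels are
bad; the reference inpainting MAR halves the composite index
(ΔM_error = 7.49 > 0) while introducing some mid-range bias of its own —
the classic MAR trade-off the metrics are built to expose. The titanium
core's diameter is recovered to 0.08 mm (0.66%).

`renderReport(set, "out/")` writes all metric tables as CSV, difference-map
and unwrapped-profile images, and a JSON manifest of configuration and
seeds. A thin command-line front end with `fixtures` / `analyze` verbs is
installed at `inst/cli/marbench.R`.

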