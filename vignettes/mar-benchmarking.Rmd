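---
title: "Phantom-based benchmarking of CT metal artifact reduction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based benchmarking of CT metal artifact reduction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MARbench)
```

## The measurement problem

Metallic implants corrupt CT images with streaking, shadowing and
CT-number (CTN) bias radiating from the metal. Commercial metal artifact
reduction (MAR) algorithms correct this to varying degrees, but they are
proprietary black boxes, so their performance must be characterized from
the outside: scan a known phantom with and without MAR, and quantify how
far each reconstruction departs from what the phantom should look like.

MARbench implements a complete quantitative suite for a cylindrical
single-insert phantom: an 11.9 cm resin body with a central 28.0 mm
channel that accepts interchangeable inserts, each a 12.7 mm material core
(solid water, aluminum, titanium, or 316 stainless steel) in a solid-water
housing. The solid-water insert is the control: every deviation metric is
defined against CT numbers measured with it, which absorbs scanner-specific
offsets (including the resin body reconstructing near +90 HU rather
than 0).

Four complementary metric families are provided:

* **Circular profiles** (`sampleCircle`, `circularDeviation`): CT numbers
  sampled on circles of 12.7, 28.0 and 38.0 mm radius around the insert
  centre, over five (configurable) consecutive slices. The statistic is
  the mean of per-sample absolute deviations from the control's mean at
  the same radius. Averaging *after* the absolute value is deliberate:
  streaks alternate bright and dark around the circle, and a mean taken
  first would cancel them — the stated weakness of line profiles that
  circular sampling exists to fix.
* **Geometric accuracy** (`segmentMetalMask`, `diameterReport`): the
  reconstructed core is segmented at 50% of the maximum CTN inside the
  channel region of interest, converted to an area-equivalent diameter
  \(d = 2\sqrt{A/\pi}\), and compared with the known 12.7 mm.
* **Annular bad-voxel analysis** (`badVoxelStats`, `deltaMError`): inside
  a donut mask (15.0–45.0 mm radii, excluding the insert channel and
  staying within the body), a voxel is *bad* when its CTN deviates
  strictly beyond 40 HU from the expected solid-water value. The composite
  index
  \(M_{error} = \frac{\%\,bad}{100}\times \overline{|\Delta CTN|}_{bad}\)
  grows with both the extent and the severity of artifacts;
  \(\Delta M_{error} = M_{error}^{non\text{-}MAR} - M_{error}^{MAR}\)
  measures the improvement MAR delivers.
* **Distributional views** (`deltaMap`, `cumulativeHist`): difference maps
  (non-MAR minus MAR) with 3rd–97th percentile display clipping, and
  cumulative histograms of annular deviations in 5 HU bins.

## Baseline conventions

Two points are genuinely underdetermined in this kind of protocol and are
therefore explicit configuration:

* **Per-radius vs global baseline.** The default compares each circle with
  the control's mean at the *same radius*, which removes radial structure
  (cupping, the resin/housing boundary) from the deviation signal;
  `baselineMode = "global"` substitutes the single overall control mean.
* **Per-arm baselines.** Non-MAR and MAR reconstructions are each
  referenced to the control scan of the *same* arm. A MAR algorithm that
  smooths the control would otherwise masquerade as artifact signal in
  every metal scan. A fixed numeric baseline can be supplied instead of a
  `BaselineReference` wherever one is accepted.

Similarly, the histogram default is *signed* deviations — the negative and
positive tails distinguish CTN under- from overestimation — with
`signed = FALSE` restoring absolute-value binning; and the 50%-of-max
segmentation threshold is computed per slice (a global-across-slices
variant would differ only when the core's peak value drifts across
slices).

For the diameter table, per-slice absolute errors are averaged
(`mean |d_i - 12.7|`) rather than taking `|mean(d_i) - 12.7|`; the
per-slice convention is what gives the reported SD columns meaning. The
two agree whenever all slices err on the same side.

## The simulator

Scanner reconstructions of this phantom are not generally redistributable,
so the package carries a synthetic data generator faithful enough to
exercise every metric end to end:

* **Geometry.** Concentric disks (body, housing, core) rasterized at voxel
  centres on a square grid (default 256 voxels at 0.5 mm — a 128 mm field
  of view), replicated across slices; ground truth assigns each voxel its
  material's nominal CTN (resin +90, solid water 0, aluminum +1200,
  titanium +8000, steel +12000 — order-of-magnitude conventions, not
  physical claims).
* **Acquisition.** Parallel-beam line integrals at 180 views over 180°, at
  two effective energies with spectrum weights 0.35/0.65. The detected
  intensity \(I = w_{lo}e^{-p_{lo}} + w_{hi}e^{-p_{hi}}\) beam-hardens
  exactly as a polychromatic beam does, because each material's low-energy
  attenuation exceeds its high-energy attenuation (strongly so for the
  metals, emulating the photoelectric contribution).
* **Noise and starvation.** Detected counts are Poisson with mean
  `photonsPerRay * I` and are clamped below at `photonFloor` before the
  log — near-total attenuation behind metal saturates at the floor,
  which is what turns isolated rays into the bright/dark streak pairs the
  circular profiles must detect.
* **Reconstruction.** Ram–Lak (discrete-kernel) filtered back-projection,
  then mapping to HU against the spectrum-weighted water attenuation, so a
  water-equivalent object reconstructs to 0 HU by construction.
* **Reference MAR.** A generic sinogram-inpainting correction: voxels at
  or above 2500 HU form the metal mask, its forward projection defines the
  metal trace, each projection profile is linearly interpolated across its
  trace interval, the volume is re-reconstructed, and the original metal
  voxels are re-inserted unchanged. This is the textbook
  interpolation-based MAR, provided as a transparent stand-in for the
  vendor black boxes so that "MAR improves the index" properties are
  testable; it imitates no specific vendor.

### Numerical choices that matter

* **Photon budget.** The default `photonsPerRay = 1e7` (with floor 10)
  yields roughly 13 HU of annular noise on the control at the default
  geometry, so the control's bad-voxel fraction stays well below 0.5% —
  the regime of a low-noise QA acquisition. At 2e5 photons the annular
  noise (≈36 HU) would swamp the 40 HU classification threshold and every
  scan, control included, would read as heavily artifacted.
* **Angular sampling.** 180 views undersample a 256-wide grid (the
  parallel-beam sampling requirement is ≈ π/2 × width), leaving a
  deterministic aliasing ripple of up to ~40 HU in isolated voxels. This
  is acceptable — and realistic-looking — for the artifact metrics, but
  reconstruction-consistency checks (agreement with ground truth within
  ±15 HU everywhere) are run at 360 views where the ripple collapses to a
  few HU.
* **Determinism.** One master seed; the per-material seed is
  `noiseSeed + 1000*index` (recorded in the scan set's seed log) and the
  per-slice seed adds the slice index. Identical configurations reproduce
  volumes bit for bit.
* **Degenerate inputs.** A constant difference map has no 3rd–97th
  percentile range; the display range widens to ±1 HU with a warning
  (stored values are never touched). A volume with no voxel at or above
  the metal threshold makes the reference MAR a warning no-op. Exact
  threshold ties are resolved by stated conventions: a deviation of
  exactly 40 HU is *not* bad (strict inequality); a voxel centre exactly
  on an annulus boundary is inside (closed boundaries); equal metal areas
  pick the lower slice index.
* **Percentiles** use linear interpolation between order statistics
  (`stats::quantile` type 7), which makes the 3rd–97th range of the
  integers 1…100 exactly (3.97, 97.03).

### What the simulator does and does not establish

The generator produces streaks, beam-hardening bias and noise with the
right phenomenology and ordering (bias magnitude grows from aluminum
through titanium to steel), but it is not a scanner model: no fan-beam or
helical geometry, no scatter, no detector cross-talk, and no attempt to
reproduce any vendor's MAR behaviour. Green tests therefore demonstrate
that the *metrics* are correct and discriminating — not that any
particular scanner would achieve particular values. Published
vendor-comparison numbers require the proprietary reconstructions
themselves, which only the real scanners can supply; with scanner DICOM
series in hand, `loadDicomSeries` + `makeScanPair` feed the identical
metric pipeline.

One consequence of the defaults worth knowing: the aluminum insert
(nominal +1200 HU) reconstructs below the 2500 HU metal-trace threshold,
so the reference MAR is an exact no-op for it and its
\(\Delta M_{error}\) is 0 — aluminum is essentially "not metal" to
threshold-based MAR, for the simulator as for clinical practice.

## Worked example

```{r example, eval = FALSE}
cfg <- simConfig(nSlices = 3L, noiseSeed = 7L)
set <- makeScanSet(cfg)
bl  <- computeBaseline(controlPair(set), radialConfig(nSlices = 3L))

circularDeviation(scanPairs(set)$stainless_steel, bl,
                  radialConfig(nSlices = 3L))
deltaMError(scanPairs(set)$stainless_steel, bl)
diameterReport(scanPairs(set)$titanium, nSlicesAnalyzed = 3L)

renderReport(set, "marbench_report")
```

`renderReport` writes the four CSV tables, per-insert difference-map and
unwrapped-profile images, and a JSON manifest of the configuration and
seeds; reruns with the same configuration are byte-identical on the CSVs.
The problem sizes used throughout the test suite (128–256 voxel grids,
2–5 slices, 120–360 views) were chosen as the smallest on which every
property is stable.

## Known limitations

* Parallel-beam, slice-replicated 2-D simulation; no axial structure
  beyond independent noise.
* The DICOM reader supports Explicit VR Little Endian CT series with
  linear rescale only — the QA-series case — and rejects anisotropic
  in-plane spacing rather than resampling.
* Volumes from different scanners are analyzed on their native grids;
  no registration or resampling is performed.
* No statistical inference between arms is provided; the benchmark is
  descriptive by design.
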