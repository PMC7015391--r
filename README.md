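# sma: automated muscle architecture measurement from B-mode ultrasound

`sma` measures the three standard architecture parameters of pennate
muscle — **pennation angle**, **fascicle length** and **muscle
thickness** — fully automatically from longitudinal B-mode ultrasound
scans. It is aimed at researchers and clinicians who routinely digitise
these quantities by hand and want a reproducible, operator-independent
alternative that runs on single images or whole folders of scans.

## Method

A scan is processed in four stages:

1. **Field-of-view detection.** The ultrasound image proper is separated
   from the surrounding information frame (text, settings, scale bar) by
   smoothing, median filtering and local-median thresholding; the
   largest bright region's bounding box is the field of view. Manual
   rectangles are supported when automatic cropping is unsuitable.
2. **Aponeurosis segmentation.** After heavy speckle suppression (CLAHE
   + non-local means), bright elongated bands are enhanced with a
   Hessian-eigenvalue *tubeness* filter at scale σₐ (default 10 px). In
   the frequency domain, the power spectrum is thresholded and a
   directional mask removes energy in the expected fascicle directions;
   the band edges of the inverse-transformed image are detected with a
   Canny detector, chained into near-horizontal lines, screened by a
   simple contrast threshold, and re-localized to sub-pixel accuracy.
   The muscle-facing edges become the superficial and deep aponeurosis
   paths, each with a total-least-squares fitted line.
3. **Dominant fascicle orientation.** Inside `n` overlapping regions of
   interest between the aponeuroses (default 3, each 60% of the field
   width and 90% of the gap height), the texture is lightly denoised,
   spectrum-thresholded, ridge-enhanced, and the gradient structure
   tensor — components smoothed by a Gaussian window of standard
   deviation σ (default 4 px) and pooled over the ROI — yields the
   dominant feature angle; its coherency (0–1) grades ROI quality. Per
   ROI angles are aggregated by the greatest, mean or median value.
4. **Architecture parameters.** With β the fascicle inclination
   (positive rising toward the left) and α the deep aponeurosis
   inclination (positive descending toward the left), pennation is
   θ = β + α; fascicle length is the straight chord through the deep
   aponeurosis at angle β up to the superficial aponeurosis
   (extrapolating the fitted line, and flagging it, when the chord
   leaves the field of view; for parallel horizontal aponeuroses this is
   the textbook t/sin θ); thickness is the mean per-column distance
   between the aponeuroses. Pixel values convert to millimetres when a
   scale is supplied.

A synthetic **phantom generator** renders B-mode-like scans (bright
aponeurosis bands, oblique fascicle striations, multiplicative speckle,
optional information frame with a tick-marked scale bar) with exact
analytic ground truth, so the whole pipeline is testable without any
real scan. A **Bland–Altman** helper quantifies agreement between
measurement series.

## Worked example

```r
library(sma)

spec <- phantom_spec(fascicle_angle_deg = 20, thickness_px = 140,
                     speckle_sigma = 0.15, frame = TRUE,
                     scale_mm_per_px = 0.08, seed = 11)
ph  <- generate_phantom(spec)
res <- analyse_image(ph$image, sma_config(crop = "auto", mm_per_px = 0.08))
res
#> Muscle architecture analysis
#>   pennation angle : 19.88 deg  (aponeurosis extrapolated)
#>   fascicle length : 412.4 px (33.00 mm)
#>   muscle thickness: 141.4 px (11.31 mm)
#>   fascicle angle 20.02 deg, deep aponeurosis -0.14 deg (median of 3 ROIs)
```

The phantom's analytic truth is a pennation of 20.00°, a fascicle length
of 409.3 px and a thickness of 140.0 px, so the automated measurements
land within 0.15°, 0.8% and 1% respectively. The "extrapolated" note
records that the composite fascicle left the field of view laterally and
the superficial aponeurosis was extended along its fitted line, exactly
as the ground-truth chord is.

## Command line

```sh
Rscript inst/cli/sma.R analyse scan.png --scale-px 50 --scale-mm 4
Rscript inst/cli/sma.R batch scans/ --ext tif --crop auto --aggregate median
Rscript inst/cli/sma.R analyse scan.png --sigma-test     # σ = 0..7 sweep table
Rscript inst/cli/sma.R phantom --spec spec.json --out phantom.png
Rscript inst/cli/sma.R agree a.csv b.csv --column pennation_deg
```

Batch mode writes `results.csv` (one row per scan), a multi-page
`overlays.tif` with the detected geometry drawn on each scan, and a
`run_manifest.json` capturing every parameter; failures are logged per
file without aborting the batch.

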