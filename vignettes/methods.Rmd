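---
title: "Methods: automated muscle architecture measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated muscle architecture measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sma)
```

## The measurement problem

Longitudinal B-mode scans of pennate muscle show two bright,
near-horizontal connective-tissue sheets (the superficial and deep
aponeuroses) with oblique fascicle striations between them. Three
parameters summarise the architecture: the pennation angle between
fascicles and the deep aponeurosis, the fascicle length between the two
insertions, and the muscle thickness. Manual digitisation of these
quantities is slow and operator-dependent; this package automates it.
The central difficulty is that scans contain many echogenic structures
(fat, vessels, septa, frame annotations) besides the objects of
interest, so each stage pairs a spatial-domain enhancement step with a
frequency-domain directional filter that isolates structures by their
orientation.

## Conventions

Images are numeric matrices in [0, 1], row = depth (y grows downward),
column = lateral position, with the proximal side of the limb on the
left (scans acquired the other way round are flipped first, which is an
exact mirror operation). All public angles are degrees from the
horizontal. Fascicle inclinations β are positive when the striations
rise toward the left; aponeurosis inclinations α are positive when the
line descends toward the left. Under this pair of conventions the
pennation angle is the plain sum θ = β + α, and the package asserts on
every analysis that this sum equals the dot-product angle between the
two direction vectors. Rectangles are 0-based, top-left-origin,
half-open.

## Stage 1: field of view

The information frame is removed by a 5×5 box blur plus a median filter
(radius 3), which erase text-sized structures, followed by binarization
against a local median (window 1/8 of the image height) plus a small
offset, or against an absolute brightness floor (0.15). The floor
matters for frameless images: there the local median tracks the signal
itself everywhere and the median test alone would binarize to noise.
The components are consolidated by morphological closing and the
bounding box of the largest one is the field of view; a box under 20%
of the image area raises an error advising manual cropping, because a
frame or annotation never dominates a genuine scan. The minimum-area
rule is applied to the bounding box rather than the pixel count because
a thresholded speckle field need not be dense.

## Stage 2: aponeuroses

The field of view is denoised with the heavy preset (CLAHE, clip limit
1.2, then non-local means with patch 5, search 11 and smoothing tied to
3× the post-equalisation noise estimate — CLAHE amplifies speckle along
with contrast, so the smoothing must be calibrated after it). Ridges
are enhanced by the Hessian tubeness filter: with Gaussian-derivative
second derivatives at scale σₐ, the response is σₐ²·max(−λ_min, 0),
which is large along bright elongated bands and small for blobs and
flats. σₐ defaults to 10 px; 8 is preferable when contrast allows and
higher values help weakly contrasted aponeuroses at the price of edge
distortion (the recovered angles change by under 1° between σₐ = 8 and
14 on well-contrasted phantoms).

The tubeness map is transformed with the FFT; bins below a fraction of
the maximum log-magnitude are zeroed (the automatic fraction is
proportional to mean image brightness, constant 1.0, clipped to
[0.05, 0.9] — the constant was calibrated on phantoms) and a hard-edged
angular wedge removes bins whose feature orientation lies in the
expected fascicle range (10–80° rising-left; a cosine taper is
available). Masking is specified in feature angles; the 90° rotation
between a feature and its spectral energy is internal. The DC bin
always survives both filters.

Canny edges (Gaussian σ = 1.4, hysteresis thresholds at the 0.5/0.85
quantiles of the non-negligible gradient magnitudes) of the
inverse-transformed image are chained into candidate lines: edge pixels
are labelled after a lateral dilation that bridges gaps up to 10 px and
keeps stair-stepped oblique chains connected, reduced to one point per
column, and kept when they span ≥ 50% of the width with a fitted
inclination under 45°. "Parallelism" is deliberately not enforced
between the two lines, because real aponeuroses converge.

Two registration details matter for accuracy. First, frequency-domain
filtering of a band produces low-contrast ghost ridges parallel to it;
candidates are therefore screened by a simple contrast threshold — a
genuine aponeurosis edge has a bright band immediately above or below
it (≥ 50% of the brightest candidate's flanking brightness), ghosts lie
in dark tissue. The topmost band-adjacent candidate becomes the
superficial aponeurosis, the bottommost the deep one; intermediate
septa are discarded. Second, the Canny edge of the tubeness ridge is
displaced outward by an amount that grows with σₐ, so each column is
re-localized on the denoised image as the sub-pixel extremum of the
vertical gradient with the expected sign (falling for the lower edge of
the superficial band, rising for the upper edge of the deep band),
searching a window of 0.8·σₐ around the candidate (shifted across the
band when the registered line is the band's far edge). Columns without
a clear transition are dropped. The muscle-facing edges define the
paths, so thickness measures the inter-aponeurosis distance. When fewer
than two lines with sufficient contrast register, the stage raises an
error inviting the user to crop manually or raise the tubeness σ —
precisely the situation produced by a deep aponeurosis imaged with
insufficient contrast.

Each path carries a total-least-squares line (first principal axis of
the point scatter). Inside the detected support, evaluation returns the
detected point; outside, the fitted line — this extrapolation is what
allows a composite fascicle to run beyond the field of view.

## Stage 3: fascicle orientation

Orientation is measured on unfiltered duplicates of the field of view
inside `n_rois` overlapping rectangles (default 3) with left edges at
i·(W − w)/(n − 1), width 60% of the shared aponeurosis support and
height 90% of the local inter-aponeurosis gap, anchored at the deep
aponeurosis and inset by a 6 px safety margin. Overlapping ROIs smooth
out local texture failures; anchoring at the deep aponeurosis reflects
the better mechanical alignment of deep fascicle segments with the line
of pull.

Each ROI is denoised with the light preset (3×3 median plus gentle
non-local means), spectrum-thresholded as above, and ridge-enhanced
with tubeness at the fascicle scale (2 px; fascicles are an order of
magnitude thinner than aponeuroses). Gradients are computed with a
Gaussian-derivative kernel of scale 1 px. This kernel is
quasi-isotropic — its frequency response depends on |f| only — which is
essential: plain central differences bias oblique angles by more than a
degree at stripe periods near 8 px, and a 1° orientation error at a 10°
pennation propagates to a ~10% fascicle-length error. The structure
tensor components Ix², Iy², IxIy are smoothed by a Gaussian window of
standard deviation σ (default 4, chosen to scale with fascicle
thickness; σ = 0 disables the window), the boundary ring affected by
padding is trimmed, and the components are pooled over the ROI
interior. The dominant feature angle is ½·atan2(2⟨IxIy⟩, ⟨Iy²⟩ −
⟨Ix²⟩), converted once to the rising-left-positive convention, and the
coherency is (λ₁ − λ₂)/(λ₁ + λ₂) of the pooled tensor.

One design choice deserves emphasis: the frequency-domain enhancement
reconstructs a near-perfect grating from whatever bins survive the
threshold, so coherency computed on the *enhanced* ROI is close to 1
regardless of tissue quality and cannot serve as a quality index. The
angle is therefore measured on the enhanced texture, while the reported
coherency comes from the raw ROI texture. On white noise this raw
coherency sits well below 0.1, so uninterpretable ROIs are excluded by
the coherency floor (0.05) before the per-ROI angles are aggregated by
the greatest, mean or median (default median, the most outlier-robust
of the three; the greatest is useful in image series where the deepest
fascicle segments are the steadiest).

A σ-sweep utility recomputes the measurement at σ = 0..7 and attaches a
warning flag that fires when the angle increases strictly monotonically
across σ = 1..7 — the classic signature of insufficient fascicle
resolution. Two caveats are documented rather than hidden. With
tensor components smoothed *linearly and then pooled*, the pooled angle
is nearly σ-invariant by construction (the smoothing commutes with the
average up to boundary effects), so the sweep varies little on any
texture and the monotone signature is rare; on white noise the
measurement typically collapses to a single surviving frequency pair
and the sweep is flat. The flag therefore implements the stated
criterion exactly, while the coherency floor is the mechanism that
actually rejects noise ROIs in practice.

## Stage 4: architecture

The composite fascicle is anchored at the midpoint of the deep
aponeurosis's detected extent (configurable); the intersection with the
superficial aponeurosis uses the detected edge inside its support and
the fitted line outside it, setting the `extrapolated` flag. Thickness
is the mean per-column vertical distance over the shared support —
vertical rather than perpendicular distance matches manual practice of
digitising the gap at fixed image sites, and the two differ by under 1%
for inclinations under 8°. The chord inequality (fascicle length ≥
thickness) and the sum-vs-vector pennation identity are asserted on
every analysis. The analysis contains no random number draws anywhere,
so repeated runs are bit-identical.

## The phantom generator

Synthetic scans provide exact ground truth: two bright bands with a
flat-top (superellipse) profile at configurable inclinations, a
rectified-sinusoid stripe texture between their muscle-facing edges
(bright ridges, so tubeness responds as it does to fascicles),
multiplicative speckle pixel·(1 + N(0, σ_s)) clipped to [0, 1], and
optionally a dark frame with text-like glyph clutter and a tick-marked
scale bar (ticks every 4 mm at the ground-truth scale). `thickness_px`
is defined as the vertical distance between the muscle-facing band
edges at mid-width — the quantity the pipeline measures — and the
ground-truth fascicle length is the analytic chord from the deep edge
at mid-width to the superficial edge line. Generation is seeded and
restores the caller's RNG state.

The defaults define the validation conditions: 512×400 px images,
superficial band at 60 px, band thickness 8 px, stripe period 14 px,
speckle σ_s 0.15, and a validation grid crossing fascicle angles
{10°, 20°, 30°} with gaps {80, 140, 200} px and speckle {0, 0.15, 0.3}.
Speckle of 0.3 is the documented upper limit at which all tolerances in
the test suite hold. What the phantoms deliberately do not emulate —
point-spread anisotropy, attenuation with depth, refraction, curved
fascicle paths, inhomogeneous grey levels along an aponeurosis — bounds
what passing tests show: recovery on phantoms demonstrates the geometry
and the filtering logic, not robustness to every artefact of real
tissue, which is why the tunable parameters (tubeness σ, ROI layout,
spectrum threshold, window σ) remain exposed exactly as a sonographer
would adjust them.

## Numerical choices and degenerate inputs

Convolutions use replicate padding; derivative kernels are corrected to
zero response on constants. FFT thresholding operates on
log1p-magnitudes. Sub-pixel edge refinement uses a parabolic fit
clamped to ±0.5 px. Constant ROIs return an invalid result (coherency
0) rather than an angle; a fascicle parallel to the superficial
aponeurosis and pennation below 0.5° are errors, not numbers. The
σ-sweep includes σ = 0 (no window smoothing). Errors are typed
conditions (`sma_fov_not_found`, `sma_apo_not_found`,
`sma_roi_too_small`, `sma_no_fascicle_orientation`, `sma_validation`,
`sma_io`) so batch drivers can isolate per-file failures, which the
batch runner does: one failed scan is logged and skipped.

## Problem sizes used in validation

The test suite and the acceptance script run the full pipeline on the
27-phantom grid at the default 512×400 px size (about two seconds per
scan), 20 random 64×64 gratings for the orientation oracle, and
closed-form geometry checks; the whole validation completes in a few
minutes on a single core.

## Known limitations

Fascicle paths are modelled as straight lines; curvature in contracted
muscle is not captured (for resting muscle the error is negligible, and
taking the aponeurosis orientations into account keeps it small during
contraction). Only two aponeuroses are modelled; bright structures
below the muscle require manual cropping. Thickness averages over the
full shared support of the two paths. Video must be pre-extracted to
image files; DICOM is not parsed. The Bland–Altman helper quantifies
agreement but does not model repeated-measure variance components.
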