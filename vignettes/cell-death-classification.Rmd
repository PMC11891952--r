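---
title: "Classifying viable, apoptotic and necrotic cells from two-channel micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying viable, apoptotic and necrotic cells from two-channel micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorcount)
```

## The assay and the classification model

Cell-death assays that pair a viability dye with an apoptosis marker encode
each cell's fate in its two-channel fluorescence pattern. With
6-carboxyfluorescein diacetate (6-CFDA) and Annexin V-Cy3 (AnnCy3):

* **viable** cells retain esterase activity and an intact membrane — green
  (6-CF) signal only;
* **apoptotic** cells still convert 6-CFDA but expose phosphatidylserine on
  the outer membrane leaflet — green **and** red, co-localised;
* **necrotic** cells have lost membrane integrity — the green signal leaks
  away while AnnCy3 binds both leaflets, typically accumulating in punctate
  intracellular foci — red only.

`fluorcount` turns this dye logic into set arithmetic on binary masks. With
`G` and `R` the processed green and red masks of one field of view:

```
Merge    = G AND R          # double-stained: apoptotic
Viable   = G - dilate(Merge)
Necrotic = R - dilate(Merge)
count on Viable, Necrotic, erode(dilate(Merge))
total    = viable + necrotic + apoptotic
```

The single dilation of `Merge` before subtraction deliberately over-covers
apoptotic cells, so that the thin halo a double-stained cell leaves behind
in one channel does not survive subtraction as a spurious "cell"; the merge
mask is eroded back to its original extent before it is itself counted. Any
fragments that do survive are removed by the circularity gate (below) —
subtraction debris is thin and elongated, with circularity far below any
plausible cell.

## Per-channel preprocessing

Each channel passes through a fixed stage order
(`process_channel()`):

1. **Rolling-ball background subtraction** (`subtract_background()`), radius
   50 px for green and 30 px for red. The background is the envelope of a
   ball rolled beneath the intensity surface — a grayscale opening with a
   ball structuring element. For radii above 16 px the classic
   shrink/enlarge speed-up is applied (min-block reduction by 4x or 8x,
   opening on the reduced image, bilinear enlargement clamped below the
   data). Below that the opening is exact, which is what the test oracles
   exercise.
2. **Richardson–Lucy deconvolution** (`deconvolve()`) with a
   diffraction-limited Airy PSF (`generate_psf()`), at most 10 iterations,
   stopping early when the relative L2 change between successive estimates
   falls below 0.010. The Wiener/Tikhonov damping term defaults to 0 (off),
   and the x/y low-pass diameter defaults to 1.0 px — a single-pixel filter,
   i.e. no filtering. These defaults reproduce the validated processing
   settings. We chose Richardson–Lucy as the non-negativity-constrained
   iterative scheme because the iteration/termination contract, not the
   exact update rule, is what the validated configuration fixes; the choice
   is documented here and in the function help.
3. **Smoothing**: two passes of a 3x3 mean filter. Border pixels average
   their in-bounds neighbours only, so flat backgrounds stay flat and the
   thresholder is not fed artificially darkened borders.
4. **Auto-thresholding** on a 256-bin histogram (`histogram256()`), with the
   algorithm fixed by channel and mode: the green channel uses the
   iterative-intermeans "Default" algorithm for control samples (mode C) and
   Otsu for treated samples (mode TR); the red channel uses the Triangle
   method in both modes. A manual per-channel threshold can override the
   automatic choice — the documented escape hatch for images with poor
   signal-to-noise ratio.
5. **Watershed separation** (`watershed_split()`) of touching cells on the
   Euclidean distance transform: green in both modes, red in mode C only.
   In treated samples the red signal sits in punctate foci that do not
   optically fuse neighbouring cells, so no watershed is applied there —
   splitting a foci cluster would fragment single necrotic cells.

### Numerical conventions

Some primitives admit more than one textbook convention. The package fixes
one of each and states it:

* **Connectivity**: foreground 8-connected, background 4-connected,
  everywhere (labelling, hole filling, watershed lines).
* **Histogram scaling**: 8-bit images bin directly; deeper images are
  min–max scaled into 256 bins and the chosen bin is mapped back to source
  intensity units (the midpoint of the threshold bin). Min–max scaling,
  rather than a fixed 0–65535 range, is what makes thresholding sparse
  16-bit fluorescence data behave sensibly.
* **Intermeans start and ties**: the iteration starts at the midpoint of
  the occupied range (this makes the algorithm translation-equivariant,
  which the property tests check); Otsu ties break to the lowest qualifying
  bin; a flat histogram under Triangle returns the lowest occupied bin.
* **Thresholding polarity**: foreground is strictly above threshold; both
  dyes are bright on dark.
* **Watershed plateaus**: regional maxima of the distance map within a
  tolerance of 0.5 of each other are merged before flooding, so a digital
  disk with a small plateau at its centre is not split. Dividing lines are
  removed one-sidedly (the higher-labelled basin recedes), which guarantees
  split objects are not 8-connected while objects with a single maximum
  pass through bit-identical.
* **Perimeter**: the convex outline through the pixel-corner points. This
  is exact for axis-aligned rectangles (a 10x10 square has perimeter 40, a
  1x10 line 22) and tracks the true circumference of rasterised disks to
  within a few percent, so circularity `4*pi*area/perimeter^2` behaves
  across the whole gate range. It overestimates the circularity of strongly
  concave particles; for this pipeline that is conservative, because the
  circularity gate is a *lower* bound used to reject debris, and the one
  concave shape the pipeline routinely produces — subtraction rings around
  apoptotic cells — still falls well below the 0.3 gate. Circularity is
  clipped at 1.
* **Deconvolution**: FFT convolution with replicated borders on canvases
  padded to 7-smooth sizes; the result is clipped to the input bit range;
  the iteration count is exposed for inspection and logging.

## Gates and the two modes

Counting is gated particle analysis (`analyze_particles()`): connected
components are measured, then filtered by area (px², uncalibrated, as
appropriate for a 10x air objective), circularity, and contact with the
image border (edge exclusion on; interior holes filled before measurement).
The validated gate sets are the mode defaults in `pipeline_config()`:

| image class | mode C | mode TR |
|---|---|---|
| Merge (apoptotic) | 0.2–1; 100–inf | 0.1–1; 50–inf |
| AnnCy3 only (necrotic) | 0.3–1; 100–inf | 0.3–1; 100–inf |
| 6-CF only (viable) | 0.2–1; 100–inf | 0.6–1; 100–inf |

Mode C is meant for control/healthy (green-dominant) samples, mode TR for
treated/dying (red-dominant) ones; the choice is explicit, never guessed
from the data. The documented "include more/less signal" adjustment —
moving a size gate between 100 and 50 px² — is a plain `gates` argument
edit, not a code change.

Accepted particles are numbered consecutively in raster order and coloured
in the overlay; rejected particles are drawn white and unnumbered, so a
user can see at a glance what was excluded and why a gate might need
adjusting.

## Optics, the PSF and pixel calibration

`generate_psf()` samples the in-focus Airy intensity pattern
`I(r) = (2 J1(v)/v)^2`, `v = 2*pi*NA*r*dx/lambda`, normalised to unit sum;
`rayleigh_resolution_px()` returns `0.61*lambda/(NA*dx)`. The validated
configuration is a 10x/0.3 NA air objective with 488 nm (green) and 561 nm
(red) excitation.

The pixel spacing `dx` is deliberately a **user-supplied calibration**. The
two reference resolution figures quoted for this configuration (32.53 px at
488 nm, 36.53 px at 561 nm) are not mutually consistent with any single
pixel spacing under the standard Rayleigh formula (their ratio differs from
the wavelength ratio), so no spacing is hard-coded; the default of 25 nm in
`optics_params()` is labelled a calibration placeholder and should be
replaced with the metadata of your own acquisition. Processing is entirely
2-D: single-plane channels are the input, and the 3-D-then-project route is
represented by `zproject_average()`. The `lowpass_z` setting is accepted
and ignored for configuration compatibility.

Within this package's own tests and acceptance runs, the deconvolution PSF
is built with a 300 nm spacing and a 31 px kernel. That is a statement
about the *synthetic* data: the generator renders scenes essentially
unblurred, so the physically appropriate kernel is compact. A PSF must
describe the blur actually present in the data it deconvolves, not the blur
of some other instrument.

## The synthetic-scene generator

Because the original micrographs are not publicly deposited, validation
beyond the printed tables runs on `generate_scene()`: seeded scenes of
flat-top disks (2-px Gaussian edge feathering) on a dim background with
low-frequency shading and Gaussian noise, rendered at 16 bits, 512x512 by
default. Class patterns follow the dye logic: viable cells appear in green
only, apoptotic cells as co-localised green and red disks, necrotic cells
as clusters of overlapping Gaussian foci (red only). Optional fused viable
pairs (centre distance `r1 + r2 - 4` px) exercise the watershed. Each cell
draws from its own seeded RNG substream, so adding a cell never moves
previously placed ones and scenes are bit-reproducible.

Default levels — background 800, signal 12000, noise SD 150, radii
10–16 px, 5 viable / 2 apoptotic / 3 necrotic cells per field — emulate a
clean spinning-disk acquisition at 10x with a signal-to-background ratio of
about 15. These are the study conditions of the recovery tests: on 20
seeded well-separated scenes the pipeline recovers every per-class count
exactly, and on 20 scenes with touching pairs the per-class totals agree
within 5%. What such scenes do **not** emulate: optical blur (unless you
convolve with the PSF yourself), irregular cell morphology, intensity
heterogeneity within a cell, autofluorescence, or bleed-through. Passing
recovery tests on them demonstrates the correctness of the mask arithmetic,
thresholds, watershed and gating under controlled conditions — not
performance on difficult real data, which is what the printed
manual-vs-automated comparison addresses.

Scene sizes in the test suite (512x512 for the recovery batches, 256x256
and smaller for unit tests) were chosen as the smallest fields that hold
the default cell complement at realistic density.

## Agreement statistics

`icc_two_way()` computes the intraclass correlation of a subjects-by-raters
table under the **two-way random-effects, absolute-agreement,
average-measures** model,

`ICC(A,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n)`,

with 95% confidence bounds from the standard F-based single-measure
construction stepped up via Spearman–Brown, and the p-value from
`F = MSR/MSE`. The reference analysis does not name its ICC flavour; this
one was adopted because recomputing the mean squares by hand on the
published six-image count table reproduces all three reported coefficients
(0.993 apoptotic, 0.998 necrotic, 1.000 viable) at 3-decimal rounding,
whereas single-measure forms do not. Comparisons against printed 3-decimal
values use half-up rounding (`round_half_up()`). The absolute-agreement
form penalises a systematic shift between raters — the property that makes
it the right validation statistic for "does the automated count equal the
manual one", not merely "does it correlate".

A degenerate table with zero total variance is defined to have ICC 1 with a
collapsed confidence interval, documented in the function help.

```{r icc}
reproduce_validation_icc()
```

## Worked example

```{r example}
sc <- generate_scene(scene_spec(seed = 3))
cfg <- pipeline_config("TR",
  optics_green = optics_params(488, 0.3, pixel_spacing = 300, psf_size = 31),
  optics_red = optics_params(561, 0.3, pixel_spacing = 300, psf_size = 31)
)
run <- classify(sc$stack, cfg)
run
score_against_truth(run$counts, sc$truth)
glance(run)
```

## Known limitations

* Counting accuracy inherits every convention above; the package does not
  attempt bit-exact replication of any GUI program's rolling-ball or
  watershed output, only the documented semantics.
* The convex-outline perimeter overestimates circularity for concave
  shapes; gates calibrated elsewhere with a crack-length or chain-code
  convention may need loosening.
* Only the 10x/0.3 NA configuration is validated; gates are in raw px² and
  do not rescale with magnification.
* Mode selection (C vs TR) is the user's call, mirroring the intended
  workflow: red-dominant fields → TR, green-dominant → C, and when in
  doubt, compare the overlay masks each mode produces.
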