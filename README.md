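# fluorcount

Automated counting and classification of **viable, apoptotic and necrotic
cells** in two-channel fluorescence micrographs of samples stained with a
green viability dye (6-carboxyfluorescein, 6-CF) and red Annexin V-Cy3
(AnnCy3). Intended for anyone quantifying cell-death assays — photodynamic
therapy, cytotoxicity screens, drug development — who currently counts
cells by hand in the green, red and merged channels.

The dye logic is: viable cells fluoresce green only; apoptotic cells green
and red, co-localised (Annexin V binds externalised phosphatidylserine
while the membrane is still intact); necrotic cells red only, with the
signal accumulated in punctate foci. `fluorcount` implements the full
post-processing chain that turns a raw three-plane stack (green, red,
transmitted light) into per-class counts:

1. rolling-ball background subtraction (radius 50 px green / 30 px red);
2. Richardson–Lucy deconvolution with a diffraction-limited Airy PSF
   (≤ 10 iterations, 0.010 relative-change termination);
3. two passes of 3×3 mean smoothing;
4. mode-dependent auto-thresholding — iterative intermeans ("Default",
   control mode C) or Otsu (treated mode TR) for green, Triangle for red;
5. watershed separation of touching cells (green always; red in mode C);
6. mask set arithmetic,

   ```
   Merge    = G AND R            # apoptotic
   Viable   = G − dilate(Merge)  # green only
   Necrotic = R − dilate(Merge)  # red only
   Total    = viable + necrotic + apoptotic
   ```

7. gated particle counting (size and circularity intervals per class and
   mode, edge exclusion, hole inclusion) with coloured-and-numbered
   overlay masks for everything counted, white for everything rejected.

A seeded synthetic-scene generator with per-cell ground truth
(`generate_scene()`) and an intraclass-correlation module for
manual-vs-automated validation (`icc_two_way()`) round out the package.

## Worked example

Simulate a 512×512 field with 5 viable, 2 apoptotic and 3 necrotic cells,
classify it in treated mode, and score against the known ground truth:

```r
library(fluorcount)

sc <- generate_scene(scene_spec(seed = 3))
cfg <- pipeline_config("TR",
  optics_green = optics_params(488, 0.3, pixel_spacing = 300, psf_size = 31),
  optics_red   = optics_params(561, 0.3, pixel_spacing = 300, psf_size = 31)
)
run <- classify(sc$stack, cfg)
run
#> <classification run>
#>   mode TR | thresholds: green 5987.6 (otsu), red 697.7 (triangle)
#>   viable 5 | apoptotic 2 | necrotic 3 | total 10

score_against_truth(run$counts, sc$truth)
#> # A tibble: 4 × 5
#>   class      true predicted abs_error rel_error
#>   <chr>     <int>     <int>     <int>     <dbl>
#> 1 viable        5         5         0         0
#> 2 apoptotic     2         2         0         0
#> 3 necrotic      3         3         0         0
#> 4 total        10        10         0         0
```

The run object carries the deconvolved planes, all intermediate masks, the
per-particle records, overlays (`autoplot(run$particles$viable)`), and a
summary table whose rows are labelled `6-CF subt Merge`, `AnnCy3 subt
Merge` and `Merge`; `write_outputs(run, "outdir")` saves all of it
(TIFF/PNG/CSV/JSON). `tidy(run)` and `glance(run)` return the results as
tibbles. The green/red thresholds shown above are the Otsu and Triangle
cuts in 16-bit intensity units; counts are cells after gating.

Agreement between two count series (e.g. manual vs automated, six images):

```r
tidy(icc_two_way(paired_counts(c(5, 2, 11, 59, 19, 51), c(5, 1, 9, 50, 19, 51))))
#> # A tibble: 1 × 7
#>     icc ci_low ci_high   p_value model                                  n     k
#>   0.993  0.958   0.999 0.0000127 two-way random, absolute agreement...  6     2
```

A command-line wrapper ships at `inst/cli/fluorcount.R` with subcommands
`classify`, `simulate`, `validate-icc` and `psf`; see `?run_cli`.

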