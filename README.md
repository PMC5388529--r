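# apicobasal

Quantification of fluorescent protein localization along the apical–basal
(A–B) axis of pseudostratified epithelia, for cell and developmental
biologists working with multichannel confocal stacks of tissues such as the
*Drosophila* wing imaginal disc.

Epithelial cells are polarized: the septate/tight-junction belt separates an
apical from a basolateral membrane compartment, and many questions (where
does a morphogen travel? where does a mislocalized protein end up?) reduce
to "how much of protein X sits in each compartment?". This package turns
raw image stacks — or synthetic stacks with known ground truth — into
aligned, background-corrected average intensity profiles and per-compartment
localization fractions, with the statistics needed to compare conditions.

## What it computes

Given channels for a junctional marker (e.g. Dlg), a GFP/YFP-tagged target,
and optionally a nanobody-based GFP trap ("GrabFP"), the pipeline:

1. **Reslices** a 3-D (z, y, x) stack into an orthogonal cross-section,
   carrying the anisotropic voxel spacing (e.g. the 0.17 µm z-step).
2. **Extracts profiles** over a rectangular ROI (default 114 × 16 µm): at
   each axial position, the mean intensity across the ROI width.
3. **Aligns** per-disc profiles by the junctional marker peak (global
   maximum after optional Gaussian smoothing; plateau centroid on ties) and
   **subtracts** the luminal background (minimum over a luminal window),
   then averages with pointwise SD and SEM, trimmed to the disc-proper
   region (default −10 to +60 µm around the junction).
4. **Corrects** the target for binding-induced fluorescence enhancement.
   Nanobody binding makes eGFP brighter by a factor F = 1.475 at
   saturation, so observed fluorescence overstates trapped protein. With
   relGrabFP(x) the trap profile normalized to its maximum,

   ```
   linear (default):  corrected(x) = observed(x) − observed(x) · relGrabFP(x) · (F−1)/F
   divisive:          corrected(x) = observed(x) / (1 + (F−1) · relGrabFP(x))
   ```

   Both leave untrapped regions untouched and divide by F at saturation;
   they disagree by at most (F−1)²/(4F) ≈ 3.8 % in between.
5. **Partitions** the axis at the aligned junction peak ± 1.0 µm into
   apical / junctional / basolateral compartments and integrates
   (trapezoid) to localization fractions.
6. **Compares** conditions with two-sided Welch t-tests per position and
   per compartment fraction (BH-adjusted q-values reported alongside), with
   Tukey-fence outlier exclusion for boxplot-style group summaries.

A titration module analyzes the in vitro calibration that yields F
(plateau detection, fold change at saturation, imaging-linearity check), a
morphometry module computes polygon (shoelace) areas and relative areas,
and a seeded synthetic-scene generator provides ground-truth-known
cross-sections, profile bundles and titrations for validation.

## Worked example

```r
library(apicobasal)

cfg <- list(
  scene = list(target_mix = c(0.35, 0, 0.65, 0),   # apical/junct/baso/uniform
               trap_compartment = "apical", bound_fraction_max = 1,
               noise_sd = 2),
  control_scene = list(target_mix = c(0, 0, 1, 0), trap_compartment = "none",
                       noise_sd = 2),
  roi = list(length_um = 114, width_um = 16),
  n_discs = 8, seed = 1, alpha = 0.05)
report <- runPipeline(cfg)
report
#> apicobasal pipeline report
#>   experimental: n = 8 discs; fractions apical 0.097, junctional 0.019, basolateral 0.885
#>   control: n = 8 discs; fractions apical 0.001, junctional 0.014, basolateral 0.985
#>   comparison: 3/3 compartment fractions significant at alpha = 0.05
```

The experimental scene models a basolateral protein partially mislocalized
by an apically anchored GFP trap: after enhancement correction, ~10 % of
the target now sits apically versus ~0 % in the control, and the Welch test
on per-disc fractions flags the shift. Titration analysis of a synthetic
saturation series recovers the enhancement factor:

```r
ts <- generateTitration(trueF = 1.475, gfpNM = 54, replicates = 5,
                        noiseCV = 0.05, seed = 1)
fc <- foldChangeAtSaturation(ts, detectPlateau(ts, relTol = 0.05))
round(c(fold = fc$fold, percent = fc$percentIncrease), 3)
#>    fold percent
#>   1.418  41.838
```

A single 5-replicate experiment at 5 % well-to-well noise scatters around
the true 47.5 %; averaging independent seeded experiments (as
`scripts/acceptance.R` does) converges on it.

## Command line

A thin CLI over the same functions ships in `inst/scripts/apicobasal-cli.R`
with verbs `simulate`, `profile`, `titrate` and `areas`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/apicobasal-cli.R", package="apicobasal"))')" \
  titrate --in titration.csv
```

See the vignette (`vignettes/quantifying-ab-localization.Rmd`) for the
model, its assumptions, and the design decisions behind each stage.
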