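---
title: "Quantifying protein localization along the apical-basal axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein localization along the apical-basal axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apicobasal)
```

# The measurement problem

Pseudostratified epithelia such as the *Drosophila* wing disc proper (DP)
are tall, polarized cell sheets: a septate-junction belt (marked by
Discs-large, Dlg) separates a short apical membrane domain facing the
lumen from a long basolateral domain. Many experiments — in particular
nanobody-based mislocalization of GFP-tagged proteins with membrane- or
matrix-anchored GFP traps ("GrabFP") — ask how the *distribution* of a
protein along this apical-basal (A-B) axis changes between conditions.

The raw data are multichannel confocal stacks acquired at high z-resolution
(0.17 µm sections) with the tissue mounted apical-side down, so the A-B
axis runs along z. The quantity of interest is a one-dimensional average
intensity profile per channel, and from it the fraction of signal in the
apical, junctional and basolateral compartments.

This vignette describes the model each stage implements, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was open.

# From stack to profile

**Reslice.** `reslice()` cuts an orthogonal 2-D section from a 3-D
(z, y, x) stack at a fixed index, carrying the two remaining voxel
spacings. For the standard acquisition geometry, a y-reslice yields a
section whose rows are the former z axis (spacing 0.17 µm) — the A-B axis
of the cells.

**Profile extraction.** `extractProfile()` implements rectangular-ROI line
profiling: at each position along the ROI's long axis the value is the
unweighted mean across the ROI width. The default ROI is 114 µm long and
16 µm wide. Two numerical choices:

* Anisotropic sections are resampled to square pixels at the *finest*
  in-plane spacing by separable linear interpolation before profiling, so
  every profile lives on a uniform µm grid (required for landmark
  alignment later). Linear interpolation is exact for locally linear
  signals and never overshoots.
* Fractional-pixel ROI edges are snapped to the nearest pixel with a
  warning. This keeps the width average unweighted, matching the behavior
  of interactive profiling tools; partial-pixel weighting would change
  results by less than one part in the ROI width but complicate
  reproduction.

ROI placement is an input (config/CLI); automatic anatomical placement
(e.g. "dorsal compartment, parallel to the D/V boundary") is out of scope
because it would require landmarks this package does not segment.

# Alignment, background and averaging

Sections from different discs cannot be averaged directly: absolute depth
varies. The junctional Dlg peak is the landmark. `detectJunctionPeak()`
takes the global maximum of the (optionally Gaussian-smoothed) marker
profile; exact ties (a sampled plateau) resolve to the plateau centroid,
which is why peak positions are continuous rather than grid-bound. The
smoothing sigma (default 0.5 µm in the pipeline) should be of the order of
the peak width; a matched filter is optimal for a Gaussian peak in white
noise. At signal-to-noise 5 the information-theoretic limit on peak
localization for these settings is ~0.07 µm, so sub-pixel accuracy is
achievable but single-draw guarantees are not — accuracy statements in the
tests are therefore medians and upper quantiles over seeded draws.

`subtractLuminalBackground()` subtracts the *minimum* intensity over a
luminal window and clamps at zero. The lumen is the natural background
reference because no membrane protein should reside there; the minimum
(rather than the mean) makes the subtraction robust to stray luminal
signal. The default window is the first 5 µm of the profile, configurable
because luminal extent varies with mounting.

`alignAndAverage()` shifts each profile so its peak maps to x = 0
(sub-pixel shifts allowed), resamples onto a common grid (spacing of the
first profile, phased so x = 0 is a grid point — this makes re-alignment
of an aligned set an exact no-op), and averages. Both SD and SEM are
retained; profile plots conventionally show SEM, group summaries SD, and
reports state which is used. Positions covered by fewer than two discs
carry NA dispersion. The average is trimmed to the disc-proper region
(default −10 µm apical to +60 µm basal of the junction) to exclude the
peripodial layer; the bounds are anatomical judgments, hence config
parameters rather than constants.

# Enhancement correction

Anti-GFP nanobody binding increases eGFP fluorescence. The in vitro
titration (below) puts the saturation enhancement at F = 1.475. Observed
fluorescence in trap-expressing tissue therefore overstates the trapped
fraction. With relGrabFP(x) the trap channel's background-subtracted
profile normalized to its own maximum — a proxy for local fractional
occupancy — `correctProfile()` offers two inversions:

* **linear** (default): corrected = observed − observed · relGrabFP · (F−1)/F.
  This is the unique correction linear in relGrabFP that leaves
  trap-free positions untouched and divides by exactly F at saturation.
* **divisive**: corrected = observed / (1 + (F−1) · relGrabFP). This
  inverts the forward enhancement model
  observed = true · (1 + (F−1) · b) *exactly* when relGrabFP equals the
  true bound fraction b.

The two agree at relGrabFP ∈ {0, 1} and disagree by at most
(F−1)²/(4F) ≈ 3.8 % (attained at half occupancy);
`correctionModeDisagreement()` reports the realized maximum. The linear
form is the default because occupancy is only proxied, not measured — a
correction linear in the proxy degrades gracefully when the proxy is
imperfect — and the exact divisive inversion is one flag away. relGrabFP
is computed from the *set-average* trap profile, not per disc: the
correction targets average profiles, and the set average is the lower-noise
occupancy estimate.

Assumptions worth stating: enhancement is instantaneous and multiplicative;
trap fluorescence is proportional to trap concentration; occupancy is
proportional to normalized trap signal (true when target is locally in
excess of neither trap nor fluorophore saturation).

# Compartments and statistics

The junctional band is the aligned peak ± 1.0 µm; apical is everything
above (negative x), basolateral everything below. `compartmentFractions()`
integrates the piecewise-linear profile per compartment (trapezoid rule,
with analytic splitting at band edges so boundaries need not sit on the
grid) and normalizes. Fractions are invariant under positive rescaling,
so they are comparable across imaging sessions with different gains.

`compareProfiles()` applies two-sided Welch (unequal-variance) t-tests per
grid position and per compartment fraction across discs. Per-position
p-values are reported raw — the headline significance flag follows the
raw-alpha convention — with Benjamini–Hochberg q-values alongside, because
neighboring positions are strongly correlated and a hard FDR correction
across ~400 positions would be conservative in a way the raw convention is
not; both are in the output, the choice is the reader's. Degenerate
zero-variance comparisons report p at the machine floor with an explicit
flag rather than NaN. `excludeOutliers()` implements Tukey fences with
type-7 (linear-interpolation) quartiles; the quartile method is fixed and
documented because the fences depend on it.

For titration wells the significance test is the *equal-variance* Student
t-test (replicate wells of one plate share an error model), unlike the
Welch tests used for biological replicates; both variants are implemented
and labelled.

# The in vitro titration

`generateTitration()` and the analysis functions model the calibration
experiment: a fixed concentration of purified eGFP (54 nM), an increasing
ladder of nanobody (5–216 nM, five replicate wells each, plus binder-free
baseline wells), mean well fluorescence per well. Occupancy follows a
tight-binding model, min(1, binder/eGFP): the observed plateau at a 2:1
binder:eGFP ratio implies near-stoichiometric binding, so an explicit Kd
isotherm is not fitted (and would not be identifiable from this design).

`detectPlateau()` formalizes "no further increase": the largest terminal
run of concentrations whose mean fluorescences are mutually within a
relative tolerance (default 0.02; the plateau call in the original
experiment was by inspection, so the rule is ours and configurable).
`foldChangeAtSaturation()` pools *all* replicate points at plateau
concentrations, divides by baseline, and reports mean, median and
dispersion. `linearityCheck()` regresses measured fluorescence on known
fluorophore concentrations (defaults 43.5–108.8 nM) and flags
proportionality when the intercept is within its standard error of zero
and R² ≥ 0.98 — the check that imaging conditions are in the linear range
of the detector.

Baseline definition: binder-free wells when present, else the
lowest-binder wells; configurable, since plate layouts differ.

# The synthetic-scene generator

`sceneParams()` + `generateCrossSection()`/`generateProfileBundle()` build
cross-sections with known ground truth. The geometry emulates a wing-disc
DP cross-section read apical-to-basal: a luminal low-signal region over the
first 10 µm of the sampled axis, the junction at 20 µm, a basolateral
membrane extending 45 µm further (columnar DP cells are some 30–60 µm
tall), sampled at the 0.17 µm z-step over a 114 µm axis. Signal amplitudes
are ~100 intensity units over an offset of 5 (so background subtraction
has work to do). The junctional marker is a sharp Gaussian peak
(sigma 0.6 µm) over a weaker lateral-membrane pool, giving the unique
global maximum the alignment stage requires. Targets are weighted mixtures
of apical, junctional, basolateral and uniform components; traps occupy
one compartment (or the basal matrix, "ecm"). The forward enhancement
model is observed = true · (1 + (F−1) · boundFraction(x)) with F = 1.475.

Noise is additive Gaussian with optional Poisson shot noise. The noise
model of real confocal acquisitions is not published for this setting;
Gaussian + shot is the standard approximation and is flagged as an
assumption. Seeds are mandatory, and identical parameters plus seed give
bit-identical output.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: optical point-spread blurring, depth-dependent
attenuation, tissue curvature (real A-B axes bend; the ROI assumes a
straight axis), peripodial-layer signal, cell-to-cell heterogeneity within
a disc, and chromatic shifts between channels. Recovery results on
synthetic scenes validate the *computation*, not the acquisition.

# Problem sizes and determinism

The shipped tests and the acceptance script run entirely on synthetic
scenes: profile grids of 200–670 samples, 2–8 discs per condition, 100–200
seeded titration experiments, 500 peak-recovery draws, 1000 null
simulations for the Welch type-I check. These sizes give stable statistics
(binomial or CLT error well inside the asserted tolerances) while keeping
a full run in seconds. Every stochastic step draws from an explicit seed;
pipeline reports record package version, config hash and all seeds.

# Known limitations

* ROI placement and disc-proper trim bounds are user judgments; results
  inherit their subjectivity.
* relGrabFP is an occupancy *proxy*; where trap is locally saturated by
  target the correction under-corrects (bounded by the mode-disagreement
  analysis above).
* The tight-binding titration model has no Kd; it is adequate at the
  nanomolar affinities of anti-GFP nanobodies but not generally.
* The gradient-range metric (`gradientRange()`: distance from the profile
  maximum to the first sustained drop below a threshold fraction, default
  0.1, two-sample persistence) is a formalization of a descriptive
  practice; absolute ranges depend on the threshold and should only be
  compared at a fixed one.
* Welch tests treat positions independently; no spatial model is fitted.
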