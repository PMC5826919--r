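---
title: "Quantifying membrane-protein localisation heterogeneity in coccoid cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-protein localisation heterogeneity in coccoid cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cocciq)
```

Many bacterial membrane proteins are not spread uniformly over the
cytoplasmic membrane: phospholipid-synthesis enzymes, flotillin-like raft
markers and some respiratory proteins form discrete puncta and concentrate
at the division septum, while others (such as components of the general
secretion machinery) appear homogeneous. In a ~1 µm coccus imaged by
widefield fluorescence microscopy at its mid-plane, the membrane appears as
a ring a few pixels thick, and "punctate vs homogeneous" becomes a question
about how intensity varies *around* that ring. This vignette describes the
models and numerical choices behind the three readouts this package
provides: the angular CV heterogeneity factor, donor-photobleaching FRET
efficiencies, and the Manders M1 colocalisation workflow, together with the
synthetic-data generator used to validate all of them.

## The synthetic coccoid-cell generator

Every analysis here is validated against images with known ground truth,
produced by `render_cell()`, `render_field()`, `simulate_bleach_trace()` and
`render_coloc_pair()`.

**Cell model.** A cell is a 2-D mid-plane pattern: a membrane ring of
radius `radius_px` with a Gaussian radial cross-section (`ring_sigma_px`,
default 1.5 px), multiplied along the angle by a modulation that is 1 for a
homogeneous ring or carries `n_puncta` Gaussian bumps (angular sd
`puncta_ang_sd`, default 0.15 rad) whose peaks are `puncta_contrast` times
the ring baseline. A septal pattern is a straight chord band through the
centre; `ring_plus_septum` sums both; `cytoplasm_level` adds a uniform
interior component. The 2-D mid-plane choice matches what the angular CV
statistic consumes — no 3-D shell projection is attempted. `uniform_mix`
blends the angular modulation towards a uniform ring, emulating the
collapse of punctate patterns seen when a fusion is over-expressed. The
default radius of 8 px corresponds to a 1 µm cell at a nominal 65 nm/px;
both are configurable and neither is inferred from any particular
instrument.

**Imaging model.** The pattern, evaluated analytically at pixel centres, is
convolved with an isotropic Gaussian PSF (`psf_sigma_px`, default 1.3 px),
then passed through a standard widefield camera model:
`Poisson(photon_scale · ideal) / photon_scale` shot noise, additive Gaussian
read noise (`read_noise_sd` counts), rounding, and clipping to the bit
depth. Setting `photon_scale = Inf` and `read_noise_sd = 0` gives noise-free
renders for exact tests. The PSF kernel is separable, symmetric, truncated
at 4σ and normalised to sum 1, so total intensity is conserved away from the
frame edge and blurring commutes exactly with quarter-turn rotations of the
image — a property the rotation tests rely on (see below). Identical seeds
give bit-identical renders.

**Bleaching model.** A bleach trace is
`A·exp(−t/τ) + B + noise`, clamped at zero. The defaults emulate a 6 min
continuous acquisition at a 0.5 s frame interval, hence 720 frames; the
frame interval is a declared convention, not a measurement.

**Colocalisation fields.** Two channels of equal-intensity uniform discs
(radius 4 px): a fraction of the green foci coincide exactly with red foci,
the rest of each channel's foci are placed disjointly with a minimum
separation, so the ideal-image M1 equals `round(overlap · n_foci) / n_foci`
by construction (exact up to disc pixelation). An optional smooth diagonal
background gradient exercises the rolling-ball stage.

**What the generator does not emulate.** Real micrographs have cell-to-cell
brightness variation, out-of-focus light from neighbouring Z planes,
overlapping and dividing cells, drift, and PSFs that are neither Gaussian
nor spatially uniform. Passing tests on this generator therefore
demonstrate correctness of the *computation* — the transforms, fits and
coefficients — under a realistic noise model, not robustness to every
artefact of real data.

## The CV heterogeneity factor

`polar_transform()` resamples the image at `n_angle_bins` angles (default
360) and `max_radius_px + 1` radii by bilinear interpolation, exactly as an
image-coordinate polar unwrapping plug-in would; `angular_profile()`
averages a radial band to give mean fluorescence per angle; and
`cv_factor()` reports

\[ \mathrm{CV} = 100 \cdot \sigma / \mu \]

with σ and μ the standard deviation and mean of the fluorescence-by-angle
distribution.

**Why 100·σ/μ.** The scale factor is arbitrary and configurable
(`scale_factor`). The quantity itself is the percent coefficient of
variation: dividing by μ removes overall brightness, so only the *shape* of
the angular distribution matters. Published uses of this statistic typeset
the ratio in more than one orientation; values in the tens for punctate
cells are only produced by σ/μ × 100, which is what this package computes.

**Population vs sample σ.** The population (n-denominator) standard
deviation is the default; with 360 bins the sample version differs by under
0.2%, and `sd_type = "sample"` switches it.

**Cytoplasm removal.** With non-deconvolved images, cytoplasmic signal
flattens the profile. Excluding a central disc containing 20% of the cell
area sets `r_min = r_max·√0.2 ≈ 0.447·r_max`. It is off by default (and
unnecessary for deconvolved-like, low-cytoplasm renders); whether the
profile should average all radii or only the membrane annulus is left to
`r_min_px`/`r_max_px`, since both conventions are in use.

**Degenerate inputs.** Profiles whose mean falls below `mu_floor` are
rejected rather than returning an unstable ratio; a constant image gives
CV = 0.

**Numerical behaviour of the invariance tests.** Three properties pin the
statistic down:

- *Intensity-scale invariance* is exact up to floating-point rounding
  (σ and μ scale together).
- *Rotation invariance* is tested at quarter-turn rotations, where an
  analytically rendered pattern rotated by 90° is an exact rearrangement of
  the pixel grid and symmetric separable blur commutes with the rotation,
  so the polar image shifts cyclically to machine precision (< 1e−6). At
  arbitrary angles a cartesian pixel grid cannot represent the rotated
  image exactly and bilinear interpolation bounds the agreement at the
  percent level — that is a property of sampled images, not of the
  statistic, whose profile-level cyclic-shift invariance is exact.
- *Size near-invariance* (CV difference < 1 CV unit between 8 px and 12 px
  cells with the same pattern) holds when the angular features are resolved
  at both sizes; it is tested on unblurred renders with puncta of angular
  sd 0.3 rad. With a fixed-width PSF, smaller cells are genuinely smoothed
  more in angle — a physical resolution effect, not an artefact of the
  statistic.

**Oracle equivalence.** The polar-transform profile is cross-checked
against an independent estimator: assign every pixel in the annulus to an
angle bin by its arctangent and average. The two agree within 2% RMS
(mean-normalised) when each oracle bin holds tens of pixels and features
are wider than a pixel arc — the tests use radius-20 cells, 24 bins and
resolved puncta. At finer bins or smaller cells, the per-pixel oracle's
whole-pixel bin assignment quantises the profile and the comparison
degrades; that sampling noise belongs to the oracle, not the transform.

**Group comparison.** `cv_group_compare()` is the classic pooled-variance
two-tailed unpaired Student's t-test with the conventional star mapping
(\*P<0.05 through \*\*\*\*P<0.0001). The emulated study conditions use 20
cells per group.

## Donor-photobleaching FRET

`fit_decay()` fits `I(t) = A·exp(−t/τ) + B` by least squares. The model has
an offset because fixed cells on slides retain non-bleaching background; a
rate-only (no-offset) variant is available via `offset = FALSE`. The fit is
computed by *profiling*: for fixed τ the model is linear in (A, B), so
those are solved in closed form and τ is found by 1-D minimisation of the
profiled residual sum of squares over log τ, bracketed by a log-linear
regression on the baseline-subtracted early frames, followed by a
Levenberg–Marquardt polish that is kept only when it improves the fit. This
is exact on noise-free traces over the whole admissible range
(τ from a few frames up to several times the trace length, where a direct
3-parameter optimiser can stall) and honest about failure: constant or
non-decreasing traces come back with `converged = FALSE` and a diagnostic,
never a silent number. Frames at the quantisation floor are trimmed from
the tail.

`fret_efficiency()` aggregates each arm's converged per-cell time constants
as an arithmetic mean — one τ_PB per construct — before applying
E = 1 − τ_PB/τ′_PB; the alternative (per-acceptor-cell efficiencies, then
averaged) is available via `aggregate = "per_cell"`. Negative efficiencies
are reported unclipped: they simply mean the donor bleached faster with the
acceptor present. Uncertainty is a seeded percentile bootstrap over cells
within arms (default 1000 resamples), since no analytic error model is
assumed for per-cell τ dispersion.

`subcellular_fret()` crosses division state with ROI (septum, periphery,
whole cell) and computes one efficiency per compartment; compartments with
no data are flagged absent, and a compartment missing its donor-only arm
yields an error row without blocking the others.

## Manders colocalisation

`rolling_ball_subtract()` estimates background as the grayscale
morphological opening of the image with a non-flat ball (spherical-cap)
structuring element — literally the surface traced by a ball of the given
radius rolled under the intensity landscape — and subtracts it, flooring at
zero. The exact opening is used rather than the classic shrink-paraboloid
approximation: it is unambiguous, testable against a direct double-loop
oracle, and differs negligibly when the ball is much larger than the
features, as with the conventional 50 px radius over ~8 px cells. The
kernel is compiled (offsets outermost, contiguous column passes), so the
exact operator is also fast enough for routine use.

`auto_threshold()` is the isodata (iterative intermeans) rule on a 256-bin
histogram: the threshold is the fixed point of
t ← (mean below t + mean above t)/2. Which auto-threshold variant a given
GUI plugin applies is rarely documented; isodata is declared here and the
function is the single seam where an alternative could be plugged in.

`manders_m1()` computes the intensity-weighted M1: within the selection
(the green/FITC reference channel's above-threshold pixels), the fraction
of green intensity in pixels where the red channel exceeds *its own*
isodata threshold. This reconstructs the usual "M1 above threshold"
behaviour of colocalisation plugins; the channel roles are explicit
arguments, so the opposite assignment is one call away.
`coloc_pipeline()` applies background subtraction → selection → M1 per
field and summarises mean ± sd over replicate fields (three per condition
in the emulated design). Pearson's coefficient, M2 and randomisation tests
are out of scope.

## Pipeline, seeds and determinism

`pipeline_config()` resolves a full nested configuration (overridable
programmatically or from YAML) and every run writes the resolved
configuration next to its outputs, so a run is reproducible from that file
alone. All randomness derives from one top-level seed through named
sub-streams (`seed_for_stage()`), so each stage is independently
reproducible and `run_reproduce()` is byte-identical across reruns with the
same seed. Problem sizes of the default study — 20 cells per CV group,
64 px single-cell frames, 20 traces of 720 frames per FRET arm, three
160 px colocalisation fields per overlap condition — were chosen to match
the emulated experimental design while keeping a full reproduction run in
the tens of seconds.

## Known limitations

- The generator's 2-D mid-plane geometry cannot express genuinely 3-D
  structures (puncta distributed over the full cell surface appear only as
  their mid-plane section); Z-stacks and super-resolution reconstructions
  are out of scope.
- Cell centres and radii are inputs (ground truth or manual annotation)
  refined by `estimate_centre()`; there is no segmentation of dense fields,
  and dividing vs non-dividing classification is an annotation, not a
  computation.
- The CV statistic deliberately ignores *how many* puncta there are; two
  patterns with different punctum counts but similar angular variance score
  alike.
- FRET efficiencies assume mono-exponential bleaching; multi-component
  decays will bias τ towards whichever component dominates the fitted
  window.
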