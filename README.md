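# cocciq

Quantitative image analysis of membrane-protein localisation in coccoid
bacteria such as *Staphylococcus aureus*, for microscopists who need to say —
with a statistic rather than an arrow on a micrograph — whether a fluorescent
membrane fusion is distributed homogeneously around the cell, concentrated in
discrete puncta, or enriched at the division septum, and whether two such
proteins colocalise or interact.

The package implements three quantitative readouts, each exercised end to end
on a synthetic coccoid-cell image generator with known ground truth, so the
whole workflow is testable without any experimental data:

1. **CV heterogeneity factor.** A cell image is resampled into polar
   coordinates about the cell centre; the mean fluorescence per angular bin
   gives an angular intensity profile I(θ), and heterogeneity is scored as

       CV = 100 · σ(I) / μ(I)

   the (percent) coefficient of variation of fluorescence by angle. A
   homogeneous membrane ring scores near 0; discrete puncta score high.
   Cytoplasmic signal can be excluded by removing a central disc holding 20%
   of the cell area (r_min = r_max·√0.2). Groups of cells (conventionally
   n = 20 per group) are compared with a two-tailed unpaired pooled-variance
   Student's t-test.

2. **Donor-photobleaching FRET efficiency.** Energy transfer to an acceptor
   slows the donor's photobleaching. ROI mean intensities over a continuous
   acquisition (default 720 frames) are fitted with I(t) = A·e^(−t/τ) + B,
   and the interaction is quantified as

       E = 1 − τ_PB / τ′_PB

   where τ_PB is the donor-only time constant and τ′_PB the time constant
   with the acceptor present. Negative estimates are reported as-is. The
   analysis also runs per subcellular compartment (dividing vs non-dividing
   cells; septum vs periphery ROIs).

3. **Manders M1 colocalisation.** After rolling-ball background subtraction
   (grayscale opening with a ball element, radius 50 px) and isodata
   auto-thresholding of the reference (green) channel,

       M1 = Σ green[i ∈ sel, red > thr] / Σ green[i ∈ sel]

   is the intensity-weighted fraction of green signal lying in pixels where
   the red channel is above its own threshold, summarised over replicate
   fields.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data; `Rscript analysis/01_generate_synthetic_data.R` writes the dataset
(TIFF images, bleach traces, annotations) under `results/synthetic/`, and
`analysis/02` to `04` run the three analyses. For instance the CV stage:

```sh
$ Rscript analysis/02_cv_heterogeneity.R
Per-group CV factors:
        group cv.mean cv.sd
1 homogeneous    1.36  0.15
2    punctate   36.03  4.93

Group comparison (pooled-variance Student's t):
   group_a     group_b n_a n_b mean_a sd_a mean_b   sd_b     t df         p stars
1 punctate homogeneous  20  20  36.03 4.93  1.364 0.1487 31.44 38 8.283e-29  ****
```

Twenty synthetic cells with six-fold punctate membrane signal (contrast 3)
score a mean CV of 36 against 1.4 for homogeneous rings of the same
brightness — the punctate cohort is discriminated at p < 10⁻²⁸. The FRET
stage recovers E = 19.9% for the arm simulated with a true efficiency of
20% and −0.02% for the non-interacting arm; the colocalisation stage
recovers mean M1 of 0.743 and 0.202 for fields generated at overlaps 0.75
and 0.20.

`analysis/05_reproduce_report.R` reruns everything in one command and
reports each qualitative finding as pass/fail; rerunning it with the same
seed reproduces every result table byte for byte.

## Layout

- `R/`, `src/` — the package: synthetic generators, image I/O, polar CV,
  FRET, colocalisation, pipeline stages (compiled morphology kernel under
  `src/`).
- `analysis/` — numbered narrative drivers over the package.
- `tests/testthat/` — unit, property and end-to-end acceptance tests with
  independent brute-force oracles.
- `vignettes/` — the methods vignette describing the models, parameters and
  numerical choices.
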