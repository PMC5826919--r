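Package: cocciq
Title: Quantitative Analysis of Membrane-Protein Localisation in Coccoid Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative fluorescence-microscopy analysis of membrane-protein
    localisation in coccoid bacteria such as Staphylococcus aureus. Implements
    the polar-transform coefficient-of-variation (CV) statistic for scoring
    heterogeneity of membrane fluorescence around the cell periphery, donor
    photobleaching FRET efficiency estimation from mono-exponential decay fits
    of ROI intensity traces, and a thresholded Manders M1 colocalisation
    workflow with rolling-ball background subtraction. A synthetic coccoid-cell
    image generator (membrane ring, puncta, septum; PSF blur; Poisson and
    camera noise; photobleaching stacks; two-channel fields with controlled
    overlap) provides ground truth so the whole pipeline is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    minpack.lm,
    withr,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
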