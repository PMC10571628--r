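Package: ifwtools
Title: Interstitial Free-Water Mapping from Multi-Shell Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates interstitial free water (iFW) in cortical gray matter
    from multi-shell diffusion MRI. Fits a two-compartment (tissue tensor plus
    isotropic free water) signal model per voxel, compensates the fitted
    free-water fraction for T2 relaxation differences between cerebrospinal
    fluid and tissue, subtracts an externally supplied CSF fractional-volume
    map, and aggregates the resulting iFW map over an eight-lobe cortical
    parcellation. Includes synthetic multi-shell phantoms and longitudinal
    cohort simulators with known ground truth, and the longitudinal
    group-comparison statistics used with such ROI tables: linear mixed-effects
    models with group-by-time interactions, Tukey post hoc contrasts on
    estimated marginal means and slopes, Benjamini-Hochberg FDR correction,
    per-subject rate-of-change slopes, Spearman correlations and Fisher z
    comparison of correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    minpack.lm,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
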