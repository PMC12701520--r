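Package: lateq
Title: Hippocampal-Volume Quartile Enrichment for Suspected LATE Co-Pathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies cognitively impaired individuals on the Alzheimer's
    disease continuum by suspected limbic-predominant age-related TDP-43
    encephalopathy (LATE) co-pathology, using a quartile cut-off on the
    age- and intracranial-volume-adjusted hippocampal volume of the more
    atrophic hemisphere. Provides a seeded synthetic cohort generator with
    longitudinal cognition, medial temporal lobe subregion volumes, mesh
    thickness maps and an autopsy arm; LATE-suggestive imaging features
    (hippocampal asymmetry index, ERC/PHC thickness ratio, Gaussian-mixture
    Tau-MaX tau-PET burden, amyloid positivity); graph-generic mass-univariate
    inference with threshold-free cluster enhancement (TFCE) and max-statistic
    permutation FWER control plus per-vertex linear mixed-effects maps with
    FDR correction; cognitive-domain mixed models with slope contrasts; SILA
    biomarker trajectory modelling with tau-onset anchoring and
    impairment-onset estimation; and autopsy enrichment validation via exact
    conditional odds ratios and ROC/Youden analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    mclust,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
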