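Package: fecalsig
Title: Host and Microbiome Signatures from Fecal DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint analysis of host-derived and microbial DNA in stool.
    Implements methylation-marker deconvolution of fecal human DNA into
    cell-type-of-origin fractions from targeted bisulfite amplicon reads,
    Poisson-based droplet digital PCR absolute quantification of human DNA,
    metagenomic human-read fraction and species-profile handling,
    clinical harmonization with host-inflammation summary metrics
    (neutrophil-to-lymphocyte and neutrophil-to-epithelial DNA ratios),
    compositional microbiome ecology (robust Aitchison ordination, richness,
    six-category expanded/lost species classification), mixed-effects
    modelling of fecal calprotectin, and gradient-boosted classification of
    disease phenotypes from microbiome features. A synthetic cohort
    generator emulates the statistical structure of inflammatory bowel
    disease case-control cohorts so that every stage is testable without
    access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    lme4,
    lmerTest,
    xgboost,
    pROC,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
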