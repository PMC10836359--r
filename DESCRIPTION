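Package: qmprof
Title: Quantitative Microbiome Profiling for Preclinical Rheumatoid Arthritis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse gut microbiome profiles across preclinical stages of
    rheumatoid arthritis in first-degree-relative cohorts. Implements the four-stage
    cohort classifier (control, high genetic risk, autoimmunity, symptomatic) built
    from serology, shared-epitope genotype and clinically suspect arthralgia scores;
    quantitative microbiome profiling (QMP) via 16S copy-number correction and
    rarefaction to even sampling depth scaled to flow-cytometric microbial loads;
    community ecology (Shannon diversity, Bray-Curtis ordination, PERMANOVA);
    Dirichlet-multinomial mixture enterotyping with BIC model selection; centred
    log-ratio Monte-Carlo differential abundance with Benjamini-Hochberg correction;
    subgroup permutation tests on median taxon abundances; and a synthetic-cohort
    generator so the full pipeline is reproducible without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
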