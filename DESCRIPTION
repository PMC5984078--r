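Package: dtimeta
Title: Two-Stage Multi-Site Meta-Analysis of Diffusion MRI ROI Measures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coordinated two-stage analysis of region-of-interest (ROI)
    diffusion tensor imaging measures across many scanning sites: per-site
    covariate-adjusted case-control Cohen's d effect sizes, clinical
    moderator regressions, subgroup contrasts and dispersion comparisons,
    pooled by random-effects inverse-variance meta-analysis with
    DerSimonian-Laird or REML between-site variance, Cochran's Q and I2
    heterogeneity, and Bonferroni family-wise control. Includes a calibrated
    multi-site synthetic cohort generator for parameter-recovery and error
    control studies, ROI summaries of white-matter skeleton voxel data with
    a core/periphery decomposition, and a manifest-driven pipeline with a
    CSV interchange format for site summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    jsonlite
Config/testthat/edition: 3
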