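Package: oralcna
Title: Copy-Number Aberration Burden Analysis for Oral Potentially
    Malignant Disorders and Carcinomas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An array-CGH copy-number analysis workflow for oral
    potentially malignant disorders (OPMDs) and oral squamous cell
    carcinomas (OSCCs): probe-level log2-ratio preprocessing (replicate
    averaging, derivative log-ratio spread QC, MAD winsorization), exact
    penalized least-squares segmentation, gain/loss calling with
    focal/broad classification at cytoband and arm resolution, a
    simplified GISTIC-style permutation test for recurrent aberrations,
    aggregation of multi-biopsy samples into patient-by-subsite
    statistical units with total burden scores (TFG, TBG, TFL, TBL), and
    the full association-testing machinery (Fisher exact 2x2 with odds
    ratios, Breslow-Day homogeneity, Mann-Whitney, Cohen's kappa,
    Benjamini-Hochberg and discrete false-discovery-rate q-values for
    families of 2x2 tables). A synthetic-cohort generator with known
    ground truth replaces the study-scale raw arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
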