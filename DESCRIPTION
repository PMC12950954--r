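Package: fragsens
Title: Fragment-Based Drug Sensitiser Screening and Co-Administration
    Dose-Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering non-toxic chemical fragments ("binary
    drugs") that sensitise cancer cells to a chemotherapeutic. Implements
    Tanimoto-coefficient fingerprint screening of Rule-of-3 fragment
    libraries against inhibitor and natural-metabolite reference panels,
    exact maximum common substructure (MCS) evidence via the modular
    product graph and a connected maximum-clique search, and analysis of
    co-administration viability plates: normalisation to untreated
    control, sensitiser enhancement, dose-sparing by log-dose
    interpolation, hormesis (biphasic response) detection and one-way
    ANOVA with Tukey correction. A synthetic-data module generates
    fragment libraries and Hill-model dose-response matrices with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineOB,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
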