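Package: coresist
Title: Co-Resistance Analysis of Cell-Line Drug-Response Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pharmacogenomic co-resistance analysis of cell-line
    by drug response panels. Discretizes continuous drug-response scores
    (log IC50 or activity area) into sensitive/resistant calls with the
    waterfall method, quantifies and ranks co-occurring resistance between
    drug pairs, builds alteration and expression association profiles for
    co-resistance cases, matches case-specific upregulated genes against
    annotated gene sets (e.g. EMT and cancer stem cell programs), and
    provides dose-response analytics: four-parameter logistic fits, ICx
    inversion, fold-change resistance and Chou-Talalay combination indices.
    Includes a synthetic-data generator that emulates GDSC-shaped inputs
    with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
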