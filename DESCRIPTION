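Package: npdrugspace
Title: Drug-Likeness and Drug-Similarity Scoring for Natural-Product Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Triage of natural-product libraries by drug-likeness and
    drug-similarity. Implements the quantitative estimate of drug-likeness
    (QED), the relative drug likelihood (RDL), Lipinski rule-of-five
    violation counts, and a weighted ADMET endpoint score, together with
    chemical-space analyses (drug-range scaling, PCA, PERMANOVA,
    quantitative Jaccard similarity to the drug cloud) and structural
    similarity (atom-pair fingerprint and maximum-common-substructure
    Tanimoto). Component indices are combined into a z-standardised summed
    drug index with tail-quadrant classification. A synthetic-data
    generator emulates drug, natural-product and toxin compound sets so the
    whole pipeline is testable without subscription databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
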