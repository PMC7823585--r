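Package: panclass
Title: Tumor-Agnostic Two-Class Molecular Classification from
    Centroid-Based Subtyping with Permutation Confidence
Version: 0.1.0
Authors@R:
    person("panclass", "developers", email = "panclass@example.org",
           role = c("aut", "cre"))
Description: A multi-stage pipeline for repurposing a tissue-specific
    nearest-centroid expression signature (PAM50-style) in a pan-cancer
    setting.  Samples are called against subtype centroids with a
    permutation-based confidence filter, low-certainty samples are
    discarded, and confidently assigned samples are collapsed into two
    tumor-agnostic classes (C1 = luminal A; C2 = luminal B, Her2-enriched
    or basal-like).  Downstream machinery characterizes the classes:
    TMM/CPM count normalization, single-sample gene-set enrichment
    (rank-based random-walk scores), per-cohort moderated differential
    expression with cross-cohort consistency counting, gene-signature
    scoring with paired tumor-normal differences, Cox survival models
    benchmarked against a random-gene-signature null (V-score),
    class-by-immune-infiltrate interaction models, and per-drug lnIC50
    class models with diagnostic gates.  A synthetic multi-cohort
    RNA-seq generator makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
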