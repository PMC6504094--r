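Package: mirdrug
Title: Associating miRNA Expression with Drug Sensitivity in Cell Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A censoring-aware pipeline for associating microRNA expression
    with drug sensitivity (IC50) across cancer cell line panels. Per-drug
    IC50 profiles are classified by their degree of right-censoring at the
    maximum tested concentration and routed to one of three association
    tests (Spearman correlation, a two-step screen-and-confirm analysis, or
    a Mann-Whitney test). Significance is assessed with Storey q-values per
    analysis branch; significant associations are checked for molecular
    subtype confounding by multivariate regression; co-expression among
    miRNAs hitting the same drug is quantified; and a quartile-group global
    test screens gene sets for pathways tracking each miRNA. A synthetic
    panel generator with planted associations, confounders and pathway
    signals makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
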