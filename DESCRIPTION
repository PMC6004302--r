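Package: paleoarc
Title: Quantitative Paleoecology of Arcellinida Assemblages in Lake
    Sediment Cores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative paleolimnological analysis of
    Arcellinida (testate lobose amoebae) assemblage records from lake
    sediment cores: count-significance screening, Shannon diversity with
    health-band classification, the difflugiid/centropyxid stress ratio,
    geochemical covariate screening (censoring rules, aluminum
    normalization, redox-tracer ratios, redundancy reduction),
    Bray-Curtis and Euclidean resemblance matrices, stratigraphically
    constrained cluster analysis (CONISS) with broken-stick zone
    selection, one-way ANOSIM and Mantel-type matrix rank-correlation
    permutation tests, non-metric multidimensional scaling, age-depth
    modelling from lead-210/ash-layer tie points with hiatus support,
    and a Dirichlet-multinomial synthetic-core generator for end-to-end
    validation. Ships the printed 30-sample Frame Lake (Yellowknife,
    NWT) core dataset as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
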