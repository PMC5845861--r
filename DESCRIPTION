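Package: clsqtl
Title: Chronological Life Span Quantification and QTL Mapping in Yeast
    Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies yeast chronological life span (CLS) as Survival
    Integrals from high-throughput outgrowth kinetics, and maps the
    genetic basis of CLS variation in haploid biparental crosses by
    Individual Segregant Analysis (single-marker LOD scans with
    permutation-derived genome-wide thresholds) and Bulk Segregant
    Analysis (G statistic with tricube smoothing and false discovery rate
    control). Includes broad- and narrow-sense heritability estimation,
    transgressive segregation summaries, condition correlation and
    clustering, and a meiosis and plate-reader simulator (Haldane map
    function, additive per-condition QTL effects, logistic outgrowth)
    for end-to-end validation of the analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
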