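Package: admixld
Title: Power Theory and Linkage Disequilibrium in Admixed-Population GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates admixed cohorts under the Pritchard-Stephens-Donnelly
    (PSD) admixture model and under a forward Wright-Fisher model with exact
    local-ancestry tracking; fits standard-GWAS (Armitage trend test) and
    local-ancestry-aware (Tractor-style) regressions; evaluates closed-form
    predictions for standard errors, Wald-statistic power ordering, and the
    independence of ancestry-specific estimates; combines ancestry-specific
    estimates by fixed-effects meta-analysis; and measures
    local-ancestry-adjusted linkage disequilibrium to test the extended-PSD
    assumption that within-continental LD is confined to local ancestry
    segments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), vcfR, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
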