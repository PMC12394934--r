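Package: cupep
Title: Profiling of Copper-Binding Peptide Populations from Protein Hydrolysates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for peptide populations enriched by
    Cu(II) immobilized-metal affinity chromatography (IMAC) from food
    protein hydrolysates. Provides in-silico protease digestion with
    missed cleavages, a seeded logistic model of IMAC retention with a
    calibration routine, per-peptide physicochemical properties
    (Kyte-Doolittle GRAVY, isoelectric point by bisection,
    Henderson-Hasselbalch net charge, monoisotopic mass), global and
    position-specific amino-acid frequency profiling, sliding-window
    motif catalogues compared by normalized Hamming distance,
    between-condition Mann-Whitney U and Kolmogorov-Smirnov
    comparisons, and plate-assay arithmetic (degree of hydrolysis,
    chelation percent, luminescence area under the curve).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
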