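Package: dropcult
Title: Growth Kinetics and Carbohydrate Utilization from Droplet
    Microfluidic Culture
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing massively parallel droplet
    culture experiments on complex microbial communities, in which single
    cells are encapsulated in picoliter droplets and taxon growth is read
    out by 16S rRNA amplicon sequencing plus total 16S qPCR.  Provides
    Poisson occupancy mathematics for loading design, estimation of
    absolute sequence-variant abundances from count tables and qPCR
    totals, multi-start robust fitting of a modified Gompertz growth
    model, calibration of growth/no-growth thresholds by ROC analysis and
    Youden's J, and ecology statistics for carbohydrate utilization
    screens (primary degraders, specialist/generalist classification,
    permutation tests, prebiotic-combination coverage, Mantel tests).  A
    synthetic-data generator produces droplet experiments with known
    ground truth so every stage of the pipeline can be validated end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
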