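Package: rohscan
Title: Runs of Homozygosity, Genomic Inbreeding and ROH Islands for SNP-Array Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of runs of homozygosity (ROH) in biallelic SNP-array
    genotypes with the consecutive-runs method, quality control of PLINK text
    PED/MAP panels, ROH-based (F_ROH) and excess-homozygosity (F_HOM) genomic
    inbreeding coefficients, per-marker incidence of common runs, ROH-island
    calling with population-sharing classification, and a one-way breed-effect
    model on per-sample island SNP proportions. Includes a multi-breed
    genotype simulator that plants identical-by-descent segments with known
    true autozygosity, used as the ground-truth oracle for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
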