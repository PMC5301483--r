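Package: zdose
Title: Gene-Dose qPCR Analysis of Sex-Chromosome Homology and Molecular Sexing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative quantitative-PCR gene-dosage analysis of
    sex chromosomes. Converts raw triplicate quantification-cycle (Cq)
    measurements into reference-normalized relative gene doses and
    female:male dose-ratio statistics with bootstrap confidence intervals,
    classifies genes as Z-specific or autosomal, calls species-level ZZ/ZW
    sex-determination systems, assigns sex to individuals from either
    Z-gene dosage or 18S rRNA copy-number assays, and brackets the origin
    age of a sex-chromosome system on a dated phylogeny by parsimony
    ancestral-state reconstruction. Includes a seeded synthetic Cq data
    generator emulating a softshell-turtle (Trionychidae) study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: ape, jsonlite, yaml, stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), phangorn, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
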