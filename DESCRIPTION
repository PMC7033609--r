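Package: SMNcnv
Title: Copy-Number Analysis of the SMN Region from MLPA Dosage Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multiplex ligation-dependent probe amplification (MLPA)
    copy-number analysis of the SMN1/SMN2 segmental-duplication region on
    chromosome 5q13. Implements two-stage dosage-quotient normalization and
    integer copy-number calling for the P021 probe mix, genotype-group
    classification and cohort summaries, exhaustive pedigree-based phasing of
    copy-number totals with informativeness classification and de novo
    copy-number event detection, Hardy-Weinberg estimation of per-allele
    copy-count frequencies with silent-carrier (2:0) risk computation, and
    tie-corrected nonparametric cohort comparisons. Includes a forward
    simulator of population haplotype pools, pedigrees and noisy MLPA peak
    data for validation without access to patient material.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0), knitr, rmarkdown, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
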