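Package: chtriage
Title: Triage of Incidental Findings from Hereditary Cancer Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based triage of incidental findings from germline
    next-generation-sequencing multi-gene panel (NGS-MGP) testing on peripheral
    blood leukocytes. Screens patients for suspicious results (multiple
    pathogenic variants, low allele fractions, TP53 findings in non-Chompret
    families), grades per-tissue allele-fraction evidence including detection of
    blood contamination in direct skin biopsies, and classifies each finding as
    full germline, likely germline, mosaic, clonal hematopoiesis (confirmed or
    likely), or related to a hematologic malignancy, with an auditable evidence
    trail. Ships a 24-patient reference cohort, cohort-level summaries, and a
    synthetic-cohort generator with binomial read-depth noise for validating
    recovery of known etiologies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
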