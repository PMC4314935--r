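Package: glygain
Title: Detection of N-Glycosylation Sequon Gains in the Human Lineage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens experimentally verified human N-glycosylation sites
    (Asn-X-Ser/Thr sequons) against mammalian ortholog alignments to find
    sites gained along the human lineage, assigns the gain to a clade on the
    nested human-lineage ladder (humans through Euarchonta), applies
    ancestral-conservation and curation filters, and performs likelihood-ratio
    tests over parsed codeml model fits. Includes a synthetic
    ortholog-alignment generator with planted sequon gains and losses so the
    whole screen is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
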