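Package: dimatlas
Title: Deep Indel Mutagenesis Atlas of Amyloid Nucleation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing deep indel mutagenesis (DIM)
    atlases of amyloid nucleation, modelled on a selection-and-sequencing assay
    for the amyloid beta peptide (Abeta42). Enumerates complete variant
    libraries (substitutions, insertions, single and multi-residue deletions,
    truncations) with canonicalization of degenerate coding variants; simulates
    selection-assay sequencing data with replicate structure; quantifies
    variants from paired-end amplicon reads; estimates nucleation scores with
    replicate error models and FDR classification; and reproduces downstream
    atlas analyses (region frequencies, deletion hotspot detection, alternative
    aliphatic cores, truncation series, ROC against disease labels, weighted
    correlation, and growth-rate fitting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
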