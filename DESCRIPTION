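Package: plsedit
Title: PPR-RNA Recognition, Off-Target Scanning and C-to-U Editing-Site
    Calling for PLS-Type Editing Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying C-to-U RNA editing directed by PLS-type
    pentatricopeptide repeat (PPR) proteins in a bacterial expression system.
    Implements the amino-acid based PPR-RNA recognition code for P-, L- and
    S-type repeats, juxtaposes repeat arrays with candidate target windows and
    scores the match, scans transcriptome sequences on both strands for
    candidate editable cytidines (including one-nucleotide register shifts and
    editing-site nomenclature labels), calls editing sites from RNA/DNA/control
    base-count tables with purity, replicate-concordance and control filters,
    summarises off-target windows as position frequency matrices with
    conservation shading, quantifies editing from Sanger peak heights, and
    generates fully synthetic inputs with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
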