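Package: dinogss
Title: Genome Survey and Transcriptome Sequence Analysis for Dinoflagellates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for low-coverage genome survey sequence (GSS) and EST analysis
    of dinoflagellates. Detects the canonical 22-nt spliced leader (SL) at EST 5'
    ends and chains of decayed relict SL copies downstream of it, discovers tandem
    repeat arrays in clone-end reads and estimates the genome fraction of each
    repeat family, classifies read sets by repetitiveness via greedy overlap
    clustering, annotates simple repeats and low-complexity tracts, tabulates stop
    codon usage and scans polyA-upstream windows for overrepresented motifs, and
    predicts restriction-digest fragment ladders. A synthetic-data module generates
    EST, CDS and clone-end read sets with planted ground truth so every stage can
    be tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
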