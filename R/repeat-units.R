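#' Reference tandem-repeat units of the *A. ostenfeldii* genome survey
#'
#' The four short repeat units (79-97 bp) whose tandem arrays dominate the
#' published *Alexandrium ostenfeldii* clone-end survey, with the genome
#' percentage estimated for each family. These are the default planted
#' families of [generate_gss_reads()] and convenient fixtures for the tandem
#' array detectors.
#'
#' @return A tibble with columns `family`, `unit` (the unit sequence),
#'   `unit_length` and `genome_pct` (estimated percent of total genomic
#'   sample occupied by the family's arrays).
#' @examples
#' aost_repeat_units()
#' @export
aost_repeat_units <- function() {
  tibble::tibble(
    family = paste0("repeat_", 1:4),
    unit = c(
      paste0("AATAGCGCTTGAGGTGCGCGCGCGTTTCTTCCGAATGCCCAAGACGGTT",
             "TTGGCGTTTTCAGTGGCGGAGCCTCGCGGCGCCCCGAAGCCCGGAGCG"),
      paste0("CCGCTCAGCCGCCTGAGCGAGCAATTCCTCGAGCGAGTCCTCCATGGTA",
             "TGTCCACAAAGTGGCTACGCCCTCTTTGGC"),
      paste0("GTCCGGAGCCAGAAGCAAGAGAAGCAAT",
             "TGAAATTGACCGCAAGAGTGCCCTTTTACTGGCTCCGGCCTAAAGCTTGTCGCGAGCGAG"),
      paste0("TGAAATTGACCGCAATAGTGCCCTTTTTGTGGCTCCGGCCTAAAGCGTGTCGCGAGCGAG",
             "GTCCGGAGCCAGAAGCAGGAGAAGCAAT")
    ),
    unit_length = c(97L, 79L, 88L, 88L),
    genome_pct = c(14.79, 11.15, 3.75, 28.11)
  )
}
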