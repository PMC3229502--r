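# shared fixtures: all sequence fixtures are built in code at test time

rec <- function(ids, seqs, source = "synthetic") {
  tibble::tibble(id = ids, seq = seqs, source = source, length = nchar(seqs))
}

rand_dna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# one concrete resolution of the default SL consensus (D -> A)
resolved_sl <- function(cfg = sl_config()) chartr("D", "A", cfg$sl_consensus)

# substitute the bases at `pos` (1-based) deterministically (A<->C, G<->T)
swap_at <- function(s, pos) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  v[pos] <- chartr("ACGT", "CATG", v[pos])
  paste(v, collapse = "")
}

table2_counts <- function() {
  tibble::tibble(
    set = rep(c("A. ostenfeldii", "A. minutum"), each = 3),
    codon = rep(c("TAA", "TAG", "TGA"), 2),
    n = c(7L, 16L, 74L, 13L, 25L, 127L)
  )
}

# the published 24-row abundance table: TC counts, EST counts, printed %
table1_rows <- function() {
  tibble::tibble(
    n_tcs = c(31L, 37L, 21L, 5L, 2L, 15L, 7L, 7L, 2L, 8L, 2L, 3L,
              4L, 1L, 1L, 2L, 5L, 3L, 6L, 1L, 3L, 1L, 1L, 4L),
    n_ests = c(355L, 265L, 249L, 185L, 185L, 81L, 43L, 29L, 25L, 22L, 21L, 19L,
               16L, 15L, 15L, 15L, 14L, 14L, 14L, 13L, 13L, 12L, 12L, 12L),
    printed_pct = c(2.89, 2.16, 2.03, 1.51, 1.51, 0.66, 0.35, 0.24, 0.20, 0.18,
                    0.17, 0.15, 0.13, 0.12, 0.12, 0.12, 0.11, 0.11, 0.11, 0.11,
                    0.11, 0.10, 0.10, 0.10)
  )
}
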