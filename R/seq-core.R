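# Sequence records, FASTA I/O and the elementary comparisons every stage
# uses. A record set is a tibble with columns `id`, `seq` and `source`
# (one of "est", "gss", "cds", "synthetic"); coordinates are 0-based,
# half-open throughout the package.

#' Read a FASTA file into a record tibble
#'
#' Sequences are uppercased, `U` is mapped to `T` (SL work is often quoted in
#' the RNA alphabet), and the alphabet is restricted to `A`, `C`, `G`, `T`,
#' `N`. Record order is preserved.
#'
#' @param path Path to a (possibly line-wrapped) multi-record FASTA file.
#' @param source Source label attached to every record: one of `"est"`,
#'   `"gss"`, `"cds"`, `"synthetic"`.
#' @return A tibble with columns `id`, `seq`, `source`, `length`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, source = c("est", "gss", "cds", "synthetic")) {
  source <- rlang::arg_match(source)
  if (!file.exists(path)) {
    rlang::abort(sprintf("FASTA file '%s' does not exist.", path))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    rlang::abort(sprintf("Duplicate FASTA id(s): %s.",
                         paste0("'", dup, "'", collapse = ", ")))
  }
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    rlang::abort(sprintf("Empty sequence for record '%s'.", ids[!nzchar(seqs)][1]))
  }
  seqs <- unname(purrr::map2_chr(seqs, ids, normalize_seq))
  tibble::tibble(id = ids, seq = seqs, source = source, length = nchar(seqs))
}

#' Write a record tibble to FASTA
#'
#' @param records Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  .check_records(records)
  set <- Biostrings::DNAStringSet(rlang::set_names(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' GC content of a sequence
#'
#' `N` bases are excluded from both numerator and denominator. Vectorised
#' over `seq`.
#'
#' @param seq Character vector of DNA strings.
#' @return Fraction(s) in `[0, 1]`; `NA` (with a warning) for all-`N` input.
#' @examples
#' gc_content("GGCC")
#' @export
gc_content <- function(seq) {
  out <- vapply(seq, function(s) {
    .assert_seq(s)
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- sum(v != "N")
    if (n == 0) return(NA_real_)
    sum(v %in% c("G", "C")) / n
  }, numeric(1), USE.NAMES = FALSE)
  if (anyNA(out)) warning("GC content undefined for all-N sequence(s); returning NA.")
  out
}

#' Ungapped identity between two equal-length sequences
#'
#' Fraction of positions with identical bases; `N` matches nothing (a
#' position with `N` on either side counts as a mismatch).
#'
#' @param a,b DNA strings of equal, positive length.
#' @return Fraction in `[0, 1]`.
#' @examples
#' ungapped_identity("GATTACA", "GATTATA")
#' @export
ungapped_identity <- function(a, b) {
  .assert_seq(a, "a"); .assert_seq(b, "b")
  if (nchar(a) != nchar(b)) {
    rlang::abort(sprintf("Sequences must have equal length (%d vs %d).",
                         nchar(a), nchar(b)))
  }
  va <- .chr2int(a); vb <- .chr2int(b)
  mean(va == vb & va != .N_INT & vb != .N_INT)
}

# IUPAC lookup: 15 codes x 4 bases logical match matrix
.iupac_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      codes <- Biostrings::IUPAC_CODE_MAP
      m <<- t(vapply(names(codes), function(cd) {
        DNA_BASES %in% strsplit(codes[[cd]], "", fixed = TRUE)[[1]]
      }, logical(4)))
      colnames(m) <<- DNA_BASES
    }
    m
  }
})

#' Identity of a sequence window against an IUPAC pattern
#'
#' A position matches when the window base is in the expansion of the
#' pattern's IUPAC code at that position (e.g. `D` = A/G/T). `N` in the
#' window never matches.
#'
#' @param pattern IUPAC string (codes `A`..`N`, ambiguity codes allowed).
#' @param seq_window Plain DNA string of the same length.
#' @return Fraction in `[0, 1]`.
#' @examples
#' iupac_identity("DCC", "ACC")
#' @export
iupac_identity <- function(pattern, seq_window) {
  .assert_seq(pattern, "pattern"); .assert_seq(seq_window, "seq_window")
  if (nchar(pattern) != nchar(seq_window)) {
    rlang::abort("`pattern` and `seq_window` must have equal length.")
  }
  pv <- strsplit(pattern, "", fixed = TRUE)[[1]]
  sv <- strsplit(seq_window, "", fixed = TRUE)[[1]]
  M <- .iupac_matrix()
  if (any(!pv %in% rownames(M))) {
    rlang::abort(sprintf("Unknown IUPAC code(s): %s.",
                         paste0("'", setdiff(unique(pv), rownames(M)), "'", collapse = ", ")))
  }
  hits <- vapply(seq_along(pv), function(i) {
    sv[i] %in% DNA_BASES && M[pv[i], sv[i]]
  }, logical(1))
  mean(hits)
}

#' Locate the start of the 3'-terminal polyA run
#'
#' Finds the 0-based start of the 3'-terminal A-run of at least `min_run`
#' bases. If the pure terminal A-run is long enough its start is returned;
#' otherwise up to `max_mismatch` non-A bases are tolerated inside the
#' terminal region and the leftmost qualifying start (which must itself be
#' an `A`) is returned.
#'
#' @param seq mRNA-sense DNA string.
#' @param min_run Minimum run length (default 10).
#' @param max_mismatch Maximum tolerated non-A bases inside the run.
#' @return 0-based start position, or `NA_integer_` when no run qualifies.
#' @examples
#' find_polya_start(paste0("GATTACC", strrep("A", 20)))
#' @export
find_polya_start <- function(seq, min_run = 10, max_mismatch = 1) {
  .assert_seq(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  isA <- v == "A"
  # pure terminal run
  run <- 0L
  while (run < n && isA[n - run]) run <- run + 1L
  if (run >= min_run) return(n - run)
  # allow mismatches: leftmost A-start whose suffix has <= max_mismatch non-A
  nonA_tail <- rev(cumsum(rev(!isA)))  # non-A count in suffix starting at i
  ok <- isA & nonA_tail <= max_mismatch & (n - seq_len(n) + 1L) >= min_run
  if (!any(ok)) return(NA_integer_)
  which(ok)[1] - 1L
}
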