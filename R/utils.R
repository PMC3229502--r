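# Internal helpers shared across modules. Sequences are plain uppercase
# character scalars over {A,C,G,T,N}; hot loops work on integer vectors
# from utf8ToInt() to avoid repeated strsplit().

`%||%` <- rlang::`%||%`

DNA_BASES <- c("A", "C", "G", "T")

.chr2int <- function(s) utf8ToInt(s)
.int2chr <- function(x) intToUtf8(x)
.N_INT <- utf8ToInt("N")

# round half up to `digits` decimals (R's round() is round-half-even; the
# printed survey tables use conventional rounding)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

.assert_seq <- function(seq, arg = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    rlang::abort(sprintf("`%s` must be a single non-empty string.", arg))
  }
  invisible(seq)
}

# uppercase, U -> T, validate alphabet
normalize_seq <- function(seq, id = NULL, allow_iupac = FALSE) {
  s <- chartr("u", "T", toupper(seq))
  s <- chartr("U", "T", s)
  allowed <- if (allow_iupac) names(Biostrings::IUPAC_CODE_MAP) else c(DNA_BASES, "N")
  bad <- setdiff(unique(strsplit(s, "", fixed = TRUE)[[1]]), allowed)
  if (length(bad) > 0) {
    where <- if (is.null(id)) "" else sprintf(" in record '%s'", id)
    rlang::abort(sprintf("Invalid character(s) %s%s.",
                         paste0("'", bad, "'", collapse = ", "), where))
  }
  s
}

#' Reverse complement of a DNA string
#'
#' @param seq A single DNA string over `A`, `C`, `G`, `T`, `N`.
#' @return The reverse complement as a string; `N` maps to `N`.
#' @examples
#' revcomp("GATTACA")
#' @export
revcomp <- function(seq) {
  .assert_seq(seq)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

# random DNA string with the given base probabilities (A,C,G,T order)
.random_seq <- function(n, probs = rep(0.25, 4)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = probs), collapse = "")
}

# substitute `k` random positions of `s` with a different base
.mutate_seq <- function(s, k) {
  if (k <= 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(v), min(k, length(v)))
  for (p in pos) v[p] <- sample(setdiff(DNA_BASES, v[p]), 1L)
  paste(v, collapse = "")
}

# per-base substitution with rate `rate`
.noisy_copy <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  for (p in hit) v[p] <- sample(setdiff(DNA_BASES, v[p]), 1L)
  paste(v, collapse = "")
}

.check_records <- function(records, arg = "records") {
  if (!is.data.frame(records) || !all(c("id", "seq") %in% names(records))) {
    rlang::abort(sprintf("`%s` must be a data frame with columns `id` and `seq`.", arg))
  }
  if (anyDuplicated(records$id)) {
    dup <- unique(records$id[duplicated(records$id)])
    rlang::abort(sprintf("Duplicate record id(s): %s.",
                         paste0("'", dup, "'", collapse = ", ")))
  }
  invisible(records)
}
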