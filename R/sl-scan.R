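# Spliced-leader (SL) detection at EST 5' ends and the downstream scan for
# chained relict (truncated) SL copies. Dinoflagellate mRNAs carry an
# invariant 22-nt trans-spliced leader; each round of mRNA recycling
# (reverse transcription and genomic reintegration followed by renewed
# trans-splicing) leaves behind a relict copy truncated after nucleotide 7
# at the AG splice-acceptor site, so a cascade of decaying 15-nt relicts
# directly downstream of the canonical SL records the number of cycles.

#' SL scan configuration
#'
#' @param sl_consensus 22-nt IUPAC consensus of the canonical spliced
#'   leader. The default is the conserved dinoflagellate SL (5' ambiguity
#'   code `D`, ending `CAAG`).
#' @param canonical_min_identity Minimum identity for a canonical SL call.
#' @param relict_floor Lowest identity at which a downstream relict copy is
#'   still accepted; relicts are searched from 100% down to this floor.
#' @param max_offset Bases of slack allowed between consecutive copies
#'   (small insertions/deletions between relicts).
#' @return An object of class `sl_config`.
#' @export
sl_config <- function(sl_consensus = "DCCGTAGCCATTTTGGCTCAAG",
                      canonical_min_identity = 0.90,
                      relict_floor = 0.50,
                      max_offset = 3) {
  sl_consensus <- normalize_seq(sl_consensus, allow_iupac = TRUE)
  if (nchar(sl_consensus) != 22) {
    rlang::abort("`sl_consensus` must be exactly 22 nt long.")
  }
  if (!(relict_floor > 0 && relict_floor <= 1)) {
    rlang::abort("`relict_floor` must be in (0, 1].")
  }
  structure(
    list(
      sl_consensus = sl_consensus,
      relict_motif = substr(sl_consensus, 8, 22),
      canonical_min_identity = canonical_min_identity,
      relict_floor = relict_floor,
      max_offset = as.integer(max_offset)
    ),
    class = "sl_config"
  )
}

# base char -> index 1..5 (A C G T other) lookup for fast window scoring
.base_index <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      tab <<- rep(5L, 127L)
      tab[utf8ToInt("A")] <<- 1L; tab[utf8ToInt("C")] <<- 2L
      tab[utf8ToInt("G")] <<- 3L; tab[utf8ToInt("T")] <<- 4L
    }
    tab
  }
})

# closure scoring int-index windows against an IUPAC pattern
.pattern_matcher <- function(pattern) {
  pv <- strsplit(pattern, "", fixed = TRUE)[[1]]
  M <- .iupac_matrix()
  allowed <- cbind(M[pv, , drop = FALSE], FALSE)  # 5th col: N/other never matches
  k <- length(pv)
  rows <- seq_len(k)
  function(idx_window) mean(allowed[cbind(rows, idx_window)])
}

.seq_index <- function(seq) .base_index()[.chr2int(seq)]

#' Find the canonical spliced leader near an EST 5' end
#'
#' Scores every 22-nt window lying fully within the first 60 bases of each
#' record against the SL consensus and reports the best-scoring window at or
#' above `canonical_min_identity` (ties broken leftmost).
#'
#' @param records Record tibble (see [read_fasta()]), mRNA-sense ESTs.
#' @param cfg An [sl_config()].
#' @param search_5prime Length of the 5' region searched (default 60).
#' @return A tibble with one row per record that has a match: `id`,
#'   `sl_start` (0-based), `sl_end` (exclusive), `sl_identity`.
#' @export
find_canonical_sl <- function(records, cfg = sl_config(), search_5prime = 60) {
  .check_records(records)
  score <- .pattern_matcher(cfg$sl_consensus)
  hits <- purrr::map(seq_len(nrow(records)), function(i) {
    s <- records$seq[i]
    L <- nchar(s)
    if (L < 22) return(NULL)
    idx <- .seq_index(s)
    starts <- 0:(min(search_5prime, L) - 22L)
    ident <- vapply(starts, function(p) score(idx[(p + 1):(p + 22)]), numeric(1))
    best <- which.max(ident)  # which.max is leftmost on ties
    if (ident[best] < cfg$canonical_min_identity) return(NULL)
    tibble::tibble(id = records$id[i], sl_start = starts[best],
                   sl_end = starts[best] + 22L, sl_identity = ident[best])
  })
  dplyr::bind_rows(hits)
}

#' Deduplicate SL-bearing ESTs and trim to the SL start
#'
#' Each record is truncated to start at its canonical SL; records whose
#' trimmed sequence is a (near-)prefix of a longer record -- at least
#' `min_identity` over the full overlap, i.e. the shorter length -- are
#' collapsed onto the longest representative (ties broken by id).
#'
#' @param records Record tibble.
#' @param matches Output of [find_canonical_sl()] for these records.
#' @param min_identity Collapse threshold over the full overlap.
#' @return Tibble of unique trimmed records (`id`, `seq`, `source`,
#'   `length`, `n_members`), longest first; the number of uniques is also
#'   attached as attribute `n_unique`.
#' @export
dedupe_and_trim <- function(records, matches, min_identity = 0.95) {
  .check_records(records)
  if (!all(matches$id %in% records$id)) {
    rlang::abort("All `matches` ids must be present in `records`.")
  }
  trimmed <- records |>
    dplyr::inner_join(matches, by = "id") |>
    dplyr::mutate(seq = substr(.data$seq, .data$sl_start + 1L, nchar(.data$seq)),
                  length = nchar(.data$seq)) |>
    dplyr::arrange(dplyr::desc(.data$length), .data$id)
  n <- nrow(trimmed)
  rep_of <- integer(n)  # index of representative, 0 = is itself a representative
  reps <- integer(0)
  for (i in seq_len(n)) {
    assigned <- FALSE
    for (r in reps) {
      ov <- trimmed$length[i]  # i is no longer than r
      if (ungapped_identity(substr(trimmed$seq[r], 1, ov), trimmed$seq[i]) >= min_identity) {
        rep_of[i] <- r
        assigned <- TRUE
        break
      }
    }
    if (!assigned) reps <- c(reps, i)
  }
  out <- trimmed[reps, c("id", "seq", "source", "length")]
  out$n_members <- vapply(reps, function(r) sum(rep_of == r) + 1L, integer(1))
  attr(out, "n_unique") <- length(reps)
  out
}

# chain scan for a single trimmed record (int-index vector)
.scan_chain_one <- function(idx, cfg, score) {
  L <- length(idx)
  k <- 0L
  ids <- numeric(0)
  starts <- integer(0)
  e <- 22L  # 0-based end of the canonical SL
  repeat {
    offs <- 0:cfg$max_offset
    offs <- offs[e + offs + 15L <= L]
    if (length(offs) == 0) break
    ident <- vapply(offs, function(o) score(idx[(e + o + 1):(e + o + 15)]), numeric(1))
    best <- which.max(ident)
    if (ident[best] < cfg$relict_floor) break
    k <- k + 1L
    ids <- c(ids, ident[best])
    starts <- c(starts, e + offs[best])
    e <- e + offs[best] + 15L
  }
  list(k = k, identities = ids, starts = starts)
}

#' Scan downstream of the SL for chained relict copies
#'
#' Greedy 5' to 3' chaining: from the end of the previous copy (initially
#' the canonical SL end), start offsets `0..max_offset` are examined; at
#' each offset a 15-nt window is scored against the relict motif and the
#' highest-identity window at or above `relict_floor` is accepted (ties to
#' the smallest offset); the scan repeats from the accepted copy's end
#' until no window qualifies.
#'
#' @param records Trimmed record tibble; every sequence must begin with its
#'   canonical SL (see [dedupe_and_trim()]).
#' @param cfg An [sl_config()].
#' @return A tibble with one row per record: `id`, `k` (number of relict
#'   copies), `identities` (list column of per-copy identities, 5' to 3'),
#'   `starts` (list column of 0-based copy starts) and `flag`
#'   (`"too_short"` for records shorter than 22 + 15 nt, else `NA`).
#' @export
scan_relict_chain <- function(records, cfg = sl_config()) {
  .check_records(records)
  score <- .pattern_matcher(cfg$relict_motif)
  res <- purrr::map(records$seq, function(s) {
    if (nchar(s) < 37) {
      return(list(k = 0L, identities = numeric(0), starts = integer(0),
                  flag = "too_short"))
    }
    c(.scan_chain_one(.seq_index(s), cfg, score), list(flag = NA_character_))
  })
  tibble::tibble(
    id = records$id,
    k = vapply(res, `[[`, integer(1), "k"),
    identities = purrr::map(res, "identities"),
    starts = purrr::map(res, "starts"),
    flag = vapply(res, `[[`, character(1), "flag")
  )
}

#' Summarise relict chain counts and per-rank identity ranges
#'
#' @param chains Output of [scan_relict_chain()].
#' @return An object of class `sl_chain_summary`: a list with `histogram`
#'   (`k`, `n`, `fraction` of the SL-containing set), `ranks` (per relict
#'   rank: `n`, `min_identity`, `max_identity`) and `n_records`. Use
#'   [generics::tidy()] / [generics::glance()] or `autoplot()` on it.
#' @export
classify_chain_counts <- function(chains) {
  n_tot <- nrow(chains)
  if (n_tot == 0) rlang::abort("`chains` is empty.")
  histogram <- chains |>
    dplyr::count(.data$k, name = "n") |>
    dplyr::mutate(fraction = .data$n / n_tot) |>
    dplyr::arrange(.data$k)
  with_copies <- if ("identities" %in% names(chains)) {
    dplyr::filter(chains, .data$k > 0)
  } else chains[0, ]
  per_rank <- if (nrow(with_copies) == 0) {
    tibble::tibble(rank = integer(0), n = integer(0),
                   min_identity = numeric(0), max_identity = numeric(0),
                   mean_identity = numeric(0))
  } else {
    with_copies |>
      dplyr::mutate(identity = .data$identities) |>
      tidyr::unnest_longer("identity", indices_to = "rank") |>
      dplyr::group_by(.data$rank) |>
      dplyr::summarise(n = dplyr::n(),
                       min_identity = min(.data$identity),
                       max_identity = max(.data$identity),
                       mean_identity = mean(.data$identity),
                       .groups = "drop")
  }
  structure(list(histogram = histogram, ranks = per_rank, n_records = n_tot),
            class = "sl_chain_summary")
}

#' @export
print.sl_chain_summary <- function(x, ...) {
  cat(sprintf("Relict SL chain summary over %d SL-bearing records\n", x$n_records))
  print(x$histogram)
  if (nrow(x$ranks) > 0) {
    cat("Per-rank identities:\n")
    print(x$ranks)
  }
  invisible(x)
}
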