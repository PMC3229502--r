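# Tandem repeat array discovery in clone-end reads and contigs. Arrays of
# short (tens-of-bp) units are detected by self-comparison at all candidate
# lags, a unit consensus is extracted by per-column majority vote, divergent
# copies are flagged, and each family's share of the genomic sample is
# estimated as n_units x unit_length x n_reads summed over contigs.

# lag match vector: TRUE where seq[i] == seq[i+p], N never matches
.lag_matches <- function(idx, p) {
  L <- length(idx)
  a <- idx[1:(L - p)]
  b <- idx[(p + 1):L]
  a == b & a != 5L & b != 5L
}

#' Detect the tandem period of a sequence
#'
#' Self-comparison at every lag `min_p..max_p`: the lag `p` maximising the
#' mean ungapped identity between the sequence and itself shifted by `p`
#' (over the full overlap) is reported, provided that identity reaches
#' `min_identity`; ties go to the smallest lag.
#'
#' @param seq DNA string of length at least `2 * min_p`.
#' @param min_p,max_p Candidate unit lengths in bp.
#' @param min_identity Qualifying mean lag identity (default 0.85).
#' @return The unit length as an integer, or `NA_integer_` when no lag
#'   qualifies.
#' @examples
#' detect_period(strrep("GATTACAGATC", 6), min_p = 5, max_p = 20)
#' @export
detect_period <- function(seq, min_p = 20, max_p = 300, min_identity = 0.85) {
  .assert_seq(seq)
  L <- nchar(seq)
  if (L < 2 * min_p) rlang::abort("`seq` must be at least `2 * min_p` long.")
  idx <- .seq_index(seq)
  ps <- min_p:min(max_p, floor(L / 2))
  ident <- vapply(ps, function(p) mean(.lag_matches(idx, p)), numeric(1))
  best <- which.max(ident)
  if (ident[best] < min_identity) return(NA_integer_)
  as.integer(ps[best])
}

#' Extract the unit consensus and per-copy identities of a tandem array
#'
#' The span is partitioned into `p`-length frames; the phase is chosen to
#' maximise the number of complete units (among such phases, the one with
#' the highest mean copy-vs-consensus identity; remaining ties to the
#' smallest phase). The consensus is the per-column majority over all
#' copies (ties broken alphabetically) and each complete copy's identity
#' against the consensus is reported.
#'
#' @param seq DNA string holding the array.
#' @param p Unit length, typically from [detect_period()].
#' @return A list with `consensus`, `per_unit_identity`, `n_units`
#'   (complete units), `phase` (0-based offset of the first complete unit).
#' @export
extract_unit_consensus <- function(seq, p) {
  .assert_seq(seq)
  p <- as.integer(p)
  L <- nchar(seq)
  if (L < 2L * p) rlang::abort("Fewer than 2 complete units in `seq`.")
  idx <- .seq_index(seq)
  phases <- 0:(L %% p)
  cand <- purrr::map(phases, function(phi) {
    k <- (L - phi) %/% p
    starts <- phi + p * (0:(k - 1))
    mat <- matrix(idx[rep(starts, each = p) + rep(1:p, times = k)],
                  nrow = k, ncol = p, byrow = TRUE)
    counts <- matrix(vapply(1:4, function(b) colSums(mat == b), numeric(p)),
                     nrow = p, ncol = 4)
    cons_idx <- max.col(counts, ties.method = "first")  # first = alphabetical
    cmp <- mat == matrix(cons_idx, k, p, byrow = TRUE)
    ident <- rowMeans(cmp)
    list(phase = phi, k = k, cons_idx = cons_idx, ident = ident,
         mean_ident = mean(ident))
  })
  means <- vapply(cand, `[[`, numeric(1), "mean_ident")
  best <- cand[[which.max(means)]]  # leftmost on ties
  list(
    consensus = paste(DNA_BASES[best$cons_idx], collapse = ""),
    per_unit_identity = best$ident,
    n_units = best$k,
    phase = best$phase
  )
}

# candidate (p, start, end) regions from windowed lag identity;
# coordinates 1-based inclusive over the read
.array_candidates <- function(idx, min_p, max_p, min_identity) {
  L <- length(idx)
  out <- list()
  for (p in min_p:min(max_p, floor(L / 2))) {
    m <- .lag_matches(idx, p)
    nm <- length(m)
    if (nm < p) next
    cs <- cumsum(c(0, m))
    w <- (cs[(p + 1):(nm + 1)] - cs[1:(nm - p + 1)]) / p  # mean over [i, i+p-1]
    ok <- w >= min_identity
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      out[[length(out) + 1L]] <- c(p = p, start = starts[j], end = ends[j] + 2L * p - 1L)
    }
  }
  if (length(out) == 0) return(NULL)
  as.data.frame(do.call(rbind, out))
}

#' Annotate tandem arrays in a read set
#'
#' For every record, maximal tandem-array regions are located by windowed
#' lag self-identity, the unit consensus is extracted, and edge copies
#' whose identity to the consensus falls below `divergent_floor` are
#' trimmed. Overlapping candidate periods are resolved in favour of the
#' longest span (preferring the smallest period among near-equal spans, so
#' a true period is not reported as its own multiple).
#'
#' @param records Record tibble (clone-end reads or contigs).
#' @param min_p,max_p Candidate unit lengths in bp.
#' @param min_identity Qualifying windowed lag identity.
#' @param divergent_floor Minimum copy-vs-consensus identity retained in an
#'   array (default 0.85, admitting the survey's 88-98% divergent copies).
#' @param exclude_simple_units Drop arrays whose unit consensus is itself a
#'   tiling of a 1-6 bp unit (default `TRUE`): such regions are
#'   microsatellite-like simple repeats, a separate census category, and
#'   would otherwise be reported at an aliased long period.
#' @return A tibble of arrays sorted by record and start: `id`, `start`,
#'   `end` (0-based half-open span of the complete units), `unit_length`,
#'   `n_units`, `unit_consensus`, `mean_identity`, `min_identity`,
#'   `per_unit_identity` (list column).
#' @export
annotate_arrays <- function(records, min_p = 20, max_p = 300,
                            min_identity = 0.85, divergent_floor = 0.85,
                            exclude_simple_units = TRUE) {
  .check_records(records)
  # a unit that is itself near-periodic at lag 1-6 is a simple repeat
  is_simple_unit <- function(u) {
    iu <- .seq_index(u)
    any(vapply(1:min(6L, nchar(u) - 1L),
               function(lag) mean(.lag_matches(iu, lag)) >= 0.8, logical(1)))
  }
  res <- purrr::map(seq_len(nrow(records)), function(i) {
    s <- records$seq[i]
    L <- nchar(s)
    if (L < 2 * min_p) return(NULL)
    idx <- .seq_index(s)
    cand <- .array_candidates(idx, min_p, max_p, min_identity)
    if (is.null(cand)) return(NULL)
    cand$span <- cand$end - cand$start + 1L
    # prefer the smallest period among overlapping near-equal spans
    keep <- rep(TRUE, nrow(cand))
    for (a in seq_len(nrow(cand))) {
      for (b in seq_len(nrow(cand))) {
        if (a == b || !keep[a] || !keep[b]) next
        ov <- min(cand$end[a], cand$end[b]) - max(cand$start[a], cand$start[b]) + 1L
        if (ov <= 0) next
        if (cand$p[a] < cand$p[b] && cand$span[a] >= cand$span[b] - cand$p[b]) {
          keep[b] <- FALSE
        }
      }
    }
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[order(-cand$span, cand$p), , drop = FALSE]
    chosen <- list()
    occupied <- rep(FALSE, L)
    for (j in seq_len(nrow(cand))) {
      rng <- cand$start[j]:cand$end[j]
      if (any(occupied[rng])) next
      occupied[rng] <- TRUE
      chosen[[length(chosen) + 1L]] <- cand[j, ]
    }
    rows <- purrr::map(chosen, function(cn) {
      sub <- substr(s, cn$start, cn$end)
      p <- cn$p
      if (nchar(sub) < 2 * p) return(NULL)
      un <- extract_unit_consensus(sub, p)
      if (exclude_simple_units && is_simple_unit(un$consensus)) return(NULL)
      ident <- un$per_unit_identity
      lo <- 1L; hi <- length(ident)
      while (lo <= hi && ident[lo] < divergent_floor) lo <- lo + 1L
      while (hi >= lo && ident[hi] < divergent_floor) hi <- hi - 1L
      if (hi - lo + 1L < 2L) return(NULL)
      ident <- ident[lo:hi]
      # 0-based half-open span of the retained complete units
      start0 <- (cn$start - 1L) + un$phase + (lo - 1L) * p
      end0 <- start0 + (hi - lo + 1L) * p
      tibble::tibble(
        id = records$id[i], start = start0, end = end0,
        unit_length = as.integer(p), n_units = hi - lo + 1L,
        unit_consensus = un$consensus,
        mean_identity = mean(ident), min_identity = min(ident),
        per_unit_identity = list(ident)
      )
    })
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) return(out)
  dplyr::arrange(out, .data$id, .data$start)
}

# circular full-overlap identity between two units: max over rotations and
# strands of the identity of the shorter unit against the doubled longer
.unit_match_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  na <- nchar(a)
  av <- .chr2int(a)
  best <- 0
  for (bb in c(b, revcomp(b))) {
    dv <- .chr2int(paste0(bb, bb))
    for (k in 0:(nchar(b) - 1L)) {
      ident <- mean(av == dv[(k + 1):(k + na)])
      if (ident > best) best <- ident
    }
  }
  best
}

#' Group detected arrays into repeat families
#'
#' Array unit consensi are assigned to families by circular full-length
#' comparison: a unit joins a family when its identity to the family's
#' representative unit, maximised over circular rotations and both strands
#' of the shorter against the longer, reaches `min_identity`. When
#' `ref_units` is supplied (e.g. [aost_repeat_units()]) those units seed
#' the families; unassigned units found de novo open new families in order
#' of total array span.
#'
#' @param arrays Output of [annotate_arrays()].
#' @param ref_units Optional tibble with columns `family` and `unit`.
#' @param min_identity Family-merge identity threshold (default 0.90).
#' @return `arrays` with a `family` column; the family table (`family`,
#'   `unit`, `unit_length`, `n_arrays`) is attached as attribute
#'   `"families"`.
#' @export
assign_repeat_families <- function(arrays, ref_units = NULL, min_identity = 0.90) {
  if (nrow(arrays) == 0) {
    arrays$family <- character(0)
    attr(arrays, "families") <- tibble::tibble(
      family = character(0), unit = character(0),
      unit_length = integer(0), n_arrays = integer(0))
    return(arrays)
  }
  fam_names <- character(0)
  fam_units <- character(0)
  if (!is.null(ref_units)) {
    fam_names <- ref_units$family
    fam_units <- ref_units$unit
  }
  n_seed <- length(fam_names)
  ord <- order(-(arrays$end - arrays$start), arrays$id)
  fam <- character(nrow(arrays))
  for (i in ord) {
    u <- arrays$unit_consensus[i]
    hit <- NA_integer_
    if (length(fam_units) > 0) {
      ident <- vapply(fam_units, .unit_match_identity, numeric(1), a = u)
      j <- which.max(ident)
      if (ident[j] >= min_identity) hit <- j
    }
    if (is.na(hit)) {
      fam_names <- c(fam_names, paste0("family_", length(fam_names) - n_seed + 1L))
      fam_units <- c(fam_units, u)
      hit <- length(fam_names)
    }
    fam[i] <- fam_names[hit]
  }
  arrays$family <- fam
  used <- fam_names %in% fam
  attr(arrays, "families") <- tibble::tibble(
    family = fam_names[used], unit = fam_units[used],
    unit_length = nchar(fam_units[used]),
    n_arrays = as.integer(table(factor(fam, levels = fam_names[used]))))
  arrays
}

#' Estimate each repeat family's fraction of the sequenced sample
#'
#' Implements the survey's accounting: for each contig (or read) the number
#' of complete repeat units is multiplied by the unit length and by the
#' number of reads in the contig, summed within a family and expressed as a
#' percentage of the total sample bp. Fractional trailing units count as
#' `floor(n)` complete units (they are already excluded upstream by
#' [annotate_arrays()]).
#'
#' @param arrays Array tibble with `n_units` and `unit_length`, optionally
#'   `family` and `n_reads` (reads per contig; default 1, i.e. per-read
#'   accounting).
#' @param total_bp Total bp of the sample; must be positive.
#' @return A tibble per family: `n_arrays`, `repeat_bp` and
#'   `fraction_pct` (percent of `total_bp`).
#' @export
estimate_family_fraction <- function(arrays, total_bp) {
  if (!is.numeric(total_bp) || length(total_bp) != 1 || total_bp <= 0) {
    rlang::abort("`total_bp` must be a single positive number.")
  }
  if (nrow(arrays) == 0) {
    return(tibble::tibble(family = character(0), n_arrays = integer(0),
                          repeat_bp = numeric(0), fraction_pct = numeric(0)))
  }
  if (!"family" %in% names(arrays)) arrays$family <- "all"
  if (!"n_reads" %in% names(arrays)) arrays$n_reads <- 1L
  arrays |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      n_arrays = dplyr::n(),
      repeat_bp = sum(floor(.data$n_units) * .data$unit_length * .data$n_reads),
      .groups = "drop") |>
    dplyr::mutate(fraction_pct = 100 * .data$repeat_bp / total_bp) |>
    dplyr::arrange(dplyr::desc(.data$fraction_pct))
}

# longest window with mismatch fraction <= 1 - min_identity at one offset;
# returns c(len, ident, start_a, start_b) or NULL
.best_window_at_offset <- function(av, bv, o, min_len, min_identity) {
  na <- length(av); nb <- length(bv)
  ia <- max(1L, 1L + o); ib <- max(1L, 1L - o)
  len <- min(na - ia, nb - ib) + 1L
  if (len < min_len) return(NULL)
  mm <- cumsum(c(0L, av[ia:(ia + len - 1)] != bv[ib:(ib + len - 1)]))
  best <- NULL
  for (w in len:min_len) {
    i <- seq_len(len - w + 1L)
    bad <- mm[i + w] - mm[i]
    ok <- which(bad <= (1 - min_identity) * w)
    if (length(ok) > 0) {
      j <- ok[which.min(bad[ok])]
      best <- c(len = w, ident = 1 - bad[j] / w,
                start_a = ia + j - 2L, start_b = ib + j - 2L)  # 0-based
      break
    }
  }
  best
}

#' Longest shared ungapped segment between two repeat units
#'
#' Slides one unit along the other on both strands and reports the longest
#' ungapped window of at least `min_len` bases whose identity reaches
#' `min_identity` (among equal-length windows, the highest identity; among
#' offsets, the longest window wins, ties to higher identity).
#'
#' @param unit_a,unit_b Unit sequences.
#' @param min_len Minimum reported window length (at least 20).
#' @param min_identity Minimum window identity (default 0.80).
#' @return A one-row tibble `start_a`, `end_a`, `start_b`, `end_b`
#'   (0-based half-open, on `unit_b`'s plus strand coordinates), `strand`,
#'   `length`, `identity`; or `NULL` when no window qualifies.
#' @export
shared_segment <- function(unit_a, unit_b, min_len = 40, min_identity = 0.80) {
  .assert_seq(unit_a, "unit_a"); .assert_seq(unit_b, "unit_b")
  if (min_len < 20) rlang::abort("`min_len` must be at least 20.")
  av <- .chr2int(unit_a)
  best <- NULL
  for (strand in c("+", "-")) {
    b <- if (strand == "+") unit_b else revcomp(unit_b)
    bv <- .chr2int(b)
    for (o in (-(length(bv) - min_len)):(length(av) - min_len)) {
      w <- .best_window_at_offset(av, bv, o, min_len, min_identity)
      if (is.null(w)) next
      if (is.null(best) || w["len"] > best$length ||
          (w["len"] == best$length && w["ident"] > best$identity)) {
        sb <- w[["start_b"]]
        if (strand == "-") sb <- length(bv) - (sb + w[["len"]])
        best <- tibble::tibble(
          start_a = as.integer(w[["start_a"]]),
          end_a = as.integer(w[["start_a"]] + w[["len"]]),
          start_b = as.integer(sb), end_b = as.integer(sb + w[["len"]]),
          strand = strand, length = as.integer(w[["len"]]),
          identity = w[["ident"]])
      }
    }
  }
  best
}

# all (possibly overlapping) 0-based start positions of `pat` in `seq`
.find_all <- function(seq, pat) {
  L <- nchar(seq); m <- nchar(pat)
  if (m > L) return(integer(0))
  v <- .chr2int(seq); pv <- .chr2int(pat)
  hit <- rep(TRUE, L - m + 1L)
  for (j in seq_len(m)) hit <- hit & v[j:(L - m + j)] == pv[j]
  which(hit) - 1L
}

#' In-silico restriction digest
#'
#' Cuts the sequence at every occurrence of the recognition site on either
#' strand. The cut position is taken at the site start (only the fragment
#' ladder periodicity matters for tandem-array verification, not the
#' enzyme's true cut offset); fragments partition the sequence.
#'
#' @param seq DNA string.
#' @param recognition_site Site over `A`,`C`,`G`,`T`, length at least 4.
#' @return Sorted integer vector of fragment lengths summing to
#'   `nchar(seq)`.
#' @examples
#' in_silico_digest(strrep("CCGCTTTTAAGG", 5), "CCGC")
#' @export
in_silico_digest <- function(seq, recognition_site) {
  .assert_seq(seq); .assert_seq(recognition_site, "recognition_site")
  site <- normalize_seq(recognition_site)
  if (nchar(site) < 4) rlang::abort("`recognition_site` must be at least 4 bp.")
  cuts <- sort(unique(c(.find_all(seq, site), .find_all(seq, revcomp(site)))))
  cuts <- cuts[cuts > 0]
  sort(diff(c(0L, cuts, nchar(seq))))
}
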