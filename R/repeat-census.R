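# Repetitiveness census of a clone-end read set: greedy overlap clustering
# (standing in for assembly, whose only role in a survey is to identify
# non-unique sequence stretches), simple-repeat and low-complexity
# annotation, the pie-vs-actual percentage accounting, and genome-size
# arithmetic from DNA content.

#' Overlap clustering parameters
#'
#' @param min_overlap Minimum ungapped overlap in bp (>= 20).
#' @param min_identity Minimum overlap identity (0.5-1).
#' @param max_mismatches Maximum absolute mismatches in the overlap
#'   (`Inf` = unlimited).
#' @return A list of class `cluster_params`. Presets: genomic survey reads
#'   use 100 bp / 0.90; EST clustering uses 40 bp / 0.95 / 30 mismatches.
#' @export
cluster_params <- function(min_overlap = 100, min_identity = 0.90,
                           max_mismatches = Inf) {
  if (min_overlap < 20) rlang::abort("`min_overlap` must be >= 20.")
  if (min_identity < 0.5 || min_identity > 1) {
    rlang::abort("`min_identity` must be in [0.5, 1].")
  }
  structure(list(min_overlap = as.integer(min_overlap),
                 min_identity = min_identity,
                 max_mismatches = max_mismatches),
            class = "cluster_params")
}

# ungapped overlap check of int vectors a, b at offset o (a[i] ~ b[i - o])
.overlap_ok <- function(av, bv, o, params) {
  ia <- max(1L, 1L + o); ib <- max(1L, 1L - o)
  len <- min(length(av) - ia, length(bv) - ib) + 1L
  if (len < params$min_overlap) return(FALSE)
  sa <- av[ia:(ia + len - 1L)]; sb <- bv[ib:(ib + len - 1L)]
  matches <- sum(sa == sb & sa != 5L)
  matches / len >= params$min_identity && (len - matches) <= params$max_mismatches
}

# seed k-mers: tibble(kmer, i, pos), first occurrence per (read, kmer)
.seed_kmers <- function(seqs, k) {
  rows <- purrr::imap(seqs, function(s, i) {
    L <- nchar(s)
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    tibble::tibble(kmer = substring(s, starts, starts + k - 1L),
                   i = i, pos = starts)
  })
  dplyr::bind_rows(rows) |> dplyr::distinct(.data$kmer, .data$i, .keep_all = TRUE)
}

#' Greedy overlap clustering of reads
#'
#' Reads sharing an ungapped overlap meeting the [cluster_params()] with
#' any member of a cluster (either orientation, any offset) join that
#' cluster; the process repeats from the longest unclustered read until
#' stable. Candidate overlaps are seeded by exact `seed_k`-mer matches and
#' verified over the full implied overlap. Clustering is deterministic:
#' cluster numbers follow seed order (longest read first, ties by id) and
#' membership is invariant to input order.
#'
#' @param reads Record tibble.
#' @param params A [cluster_params()].
#' @param seed_k Exact-match seed length (default 16; must not exceed
#'   `min_overlap`).
#' @return A tibble `id`, `cluster` (integer), `cluster_size`, in the
#'   input's row order.
#' @export
greedy_overlap_cluster <- function(reads, params = cluster_params(), seed_k = 16) {
  .check_records(reads)
  n <- nrow(reads)
  if (n == 0) rlang::abort("`reads` is empty.")
  seed_k <- as.integer(seed_k)
  if (seed_k > params$min_overlap) rlang::abort("`seed_k` must be <= `min_overlap`.")
  fwd <- purrr::map(reads$seq, .seq_index)
  rc <- purrr::map(reads$seq, function(s) .seq_index(revcomp(s)))

  kf <- .seed_kmers(reads$seq, seed_k)
  kr <- .seed_kmers(vapply(reads$seq, revcomp, character(1), USE.NAMES = FALSE),
                    seed_k)
  same <- dplyr::inner_join(kf, kf, by = "kmer", relationship = "many-to-many") |>
    dplyr::filter(.data$i.x < .data$i.y) |>
    dplyr::transmute(i = .data$i.x, j = .data$i.y,
                     offset = .data$pos.x - .data$pos.y, strand = "+")
  # fwd(i) vs rc(j) at this diagonal; kept directional (i may exceed j)
  opp <- dplyr::inner_join(kf, kr, by = "kmer", relationship = "many-to-many") |>
    dplyr::filter(.data$i.x != .data$i.y) |>
    dplyr::transmute(i = .data$i.x, j = .data$i.y,
                     offset = .data$pos.x - .data$pos.y, strand = "-")
  cand <- dplyr::distinct(dplyr::bind_rows(same, opp))

  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(cand) > 0) {
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (find(i) == find(j)) next
      bv <- if (cand$strand[r] == "+") fwd[[j]] else rc[[j]]
      if (.overlap_ok(fwd[[i]], bv, cand$offset[r], params)) {
        parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  ord <- order(-nchar(reads$seq), reads$id)
  cluster <- integer(n)
  nxt <- 0L
  for (i in ord) {
    root <- comp[i]
    if (cluster[i] == 0L) {
      nxt <- nxt + 1L
      cluster[comp == root] <- nxt
    }
  }
  sizes <- tabulate(cluster)
  tibble::tibble(id = reads$id, cluster = cluster, cluster_size = sizes[cluster])
}

#' Classify reads by cluster repetitiveness
#'
#' Singletons are `unique`; reads in clusters of at least 2 are
#' `repetitive`; clusters of more than 20 reads are `highly_repetitive`
#' (which subsumes repetitive).
#'
#' @param clusters Output of [greedy_overlap_cluster()].
#' @param highly_threshold Reads above which a cluster is highly
#'   repetitive (default 20, i.e. `> 20 reads`).
#' @return `clusters` with an added `category` column.
#' @export
classify_repetitiveness <- function(clusters, highly_threshold = 20) {
  dplyr::mutate(clusters, category = dplyr::case_when(
    .data$cluster_size > highly_threshold ~ "highly_repetitive",
    .data$cluster_size >= 2 ~ "repetitive",
    TRUE ~ "unique"
  ))
}

# primitive period of a short unit (e.g. "ATAT" -> "AT")
.primitive_unit <- function(u) {
  n <- nchar(u)
  for (d in seq_len(n - 1)) {
    if (n %% d == 0 && strrep(substr(u, 1, d), n %/% d) == u) {
      return(substr(u, 1, d))
    }
  }
  u
}

# lexicographically minimal rotation
.min_rotation <- function(u) {
  n <- nchar(u)
  if (n == 1) return(u)
  rots <- substring(strrep(u, 2), 1:n, n:(2 * n - 1))
  sort(rots)[1]
}

#' Find simple (microsatellite-like) repeats
#'
#' Maximal runs of a 1-6 bp unit repeated in tandem, covering at least
#' `min_span` bp with at least `min_purity` of positions matching the unit
#' phase. Overlapping calls at different unit lengths resolve to the longer
#' span (ties to the shorter unit), and the unit is reported as the
#' lexicographically minimal rotation of its primitive period.
#'
#' @param seq DNA string.
#' @param max_unit Largest unit length considered (default 6).
#' @param min_span Minimum repeat span in bp (default 12).
#' @param min_purity Minimum fraction of in-phase matching positions.
#' @return A tibble `start`, `end` (0-based half-open), `unit`, `length`.
#' @examples
#' find_simple_repeats(paste0("GTACGTAC", strrep("CACG", 6), "TTGCA"))
#' @export
find_simple_repeats <- function(seq, max_unit = 6, min_span = 12, min_purity = 0.9) {
  .assert_seq(seq)
  L <- nchar(seq)
  idx <- .seq_index(seq)
  cand <- list()
  for (u in seq_len(min(max_unit, L - 1))) {
    m <- .lag_matches(idx, u)
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    if (length(runs) == 0) next
    taken <- rep(FALSE, length(r$lengths))
    for (ri in runs) {
      if (taken[ri]) next
      s0 <- starts[ri]; e0 <- ends[ri]; true_n <- r$lengths[ri]
      j <- ri
      repeat {  # greedily absorb later runs while purity holds
        if (j + 2 > length(r$lengths)) break
        gap <- r$lengths[j + 1]
        nxt <- r$lengths[j + 2]
        if ((true_n + nxt) / (ends[j + 2] - s0 + 1L) >= min_purity) {
          true_n <- true_n + nxt
          e0 <- ends[j + 2]
          taken[j + 2] <- TRUE
          j <- j + 2
        } else break
      }
      span <- e0 - s0 + 1L + u
      if (span >= min_span && true_n / (e0 - s0 + 1L) >= min_purity) {
        cand[[length(cand) + 1L]] <- list(u = u, start = s0, end = s0 + span - 1L)
      }
    }
  }
  if (length(cand) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          unit = character(0), length = integer(0)))
  }
  df <- dplyr::bind_rows(lapply(cand, tibble::as_tibble))
  df$span <- df$end - df$start + 1L
  df <- df[order(-df$span, df$u), ]
  occupied <- rep(FALSE, L)
  keep <- logical(nrow(df))
  for (r in seq_len(nrow(df))) {
    rng <- df$start[r]:df$end[r]
    if (!any(occupied[rng])) { occupied[rng] <- TRUE; keep[r] <- TRUE }
  }
  df <- df[keep, ]
  unit <- vapply(seq_len(nrow(df)), function(r) {
    sub <- substr(seq, df$start[r], df$end[r])
    un <- if (nchar(sub) >= 2 * df$u[r]) {
      extract_unit_consensus(sub, df$u[r])$consensus
    } else substr(sub, 1, df$u[r])
    .min_rotation(.primitive_unit(un))
  }, character(1))
  out <- tibble::tibble(start = df$start - 1L, end = df$end,  # to 0-based half-open
                        unit = unit, length = df$span)
  dplyr::arrange(out, .data$start)
}

# Shannon entropy (bits) of mono-nucleotide composition, N excluded
.mono_entropy <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Find low-complexity regions by composition entropy
#'
#' Slides a window along the sequence, flags windows whose mononucleotide
#' Shannon entropy falls below `entropy_thresh`, merges overlapping
#' flagged windows and labels each merged interval by its dominant base(s)
#' (`C-rich`, `GA-rich`, ...).
#'
#' @param seq DNA string.
#' @param window Window size in bp (default 64; shrunk for shorter input).
#' @param entropy_thresh Entropy threshold in bits (default 1.5).
#' @param step Window step (default `window / 4`).
#' @return A tibble `start`, `end` (0-based half-open), `label`,
#'   `entropy` (entropy of the merged interval).
#' @examples
#' find_low_complexity(paste0(strrep("AGCT", 40), strrep("C", 80)))
#' @export
find_low_complexity <- function(seq, window = 64, entropy_thresh = 1.5,
                                step = max(1, window %/% 4)) {
  .assert_seq(seq)
  L <- nchar(seq)
  window <- min(window, L)
  idx <- .seq_index(seq)
  starts <- unique(c(seq(1L, max(1L, L - window + 1L), by = step), L - window + 1L))
  flagged <- purrr::keep(starts, function(s0) {
    counts <- tabulate(idx[s0:(s0 + window - 1L)], 5L)[1:4]
    sum(counts) > 0 && .mono_entropy(counts) < entropy_thresh
  })
  if (length(flagged) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          label = character(0), entropy = numeric(0)))
  }
  iv <- tibble::tibble(start = flagged, end = flagged + window - 1L)
  iv <- iv[order(iv$start), ]
  merged <- list(c(iv$start[1], iv$end[1]))
  for (r in seq_len(nrow(iv))[-1]) {
    last <- merged[[length(merged)]]
    if (iv$start[r] <= last[2] + 1L) {
      merged[[length(merged)]][2] <- max(last[2], iv$end[r])
    } else merged[[length(merged) + 1L]] <- c(iv$start[r], iv$end[r])
  }
  rows <- purrr::map(merged, function(m) {
    counts <- tabulate(idx[m[1]:m[2]], 5L)[1:4]
    frac <- counts / sum(counts)
    ord <- order(-frac, DNA_BASES)
    label <- if (frac[ord[1]] >= 0.6) {
      paste0(DNA_BASES[ord[1]], "-rich")
    } else {
      paste0(paste(DNA_BASES[ord[1:2]], collapse = ""), "-rich")
    }
    tibble::tibble(start = m[1] - 1L, end = m[2], label = label,
                   entropy = .mono_entropy(counts))
  })
  dplyr::bind_rows(rows)
}

#' Tabulate the feature census of a read set
#'
#' Implements the survey's double accounting: a read carrying a feature
#' contributes its full length to that feature's bp tally (so reads with
#' several features are counted once per feature). `pct_actual` divides by
#' the true sample bp; `pct_pie` divides by the sum of per-feature bp
#' (the pie-chart denominator, an overestimate of the sample).
#'
#' @param reads Tibble with `id` and either `length` or `seq`.
#' @param annotations Tibble with `id` and `feature`; reads absent from it
#'   fall into the `no_feature` category. A read may appear under several
#'   features; duplicate (id, feature) pairs count once.
#' @return A `feature_census`: a tibble `feature`, `n_reads`, `total_bp`,
#'   `pct_pie`, `pct_actual`, with attributes `actual_total_bp`,
#'   `pie_total_bp` and `n_reads_total`.
#' @export
feature_census <- function(reads, annotations) {
  if (!"length" %in% names(reads)) {
    reads <- dplyr::mutate(reads, length = nchar(.data$seq))
  }
  if (anyDuplicated(reads$id)) rlang::abort("Duplicate read ids in `reads`.")
  ann <- annotations |>
    dplyr::distinct(.data$id, .data$feature) |>
    dplyr::filter(.data$id %in% reads$id)
  bare <- setdiff(reads$id, ann$id)
  if (length(bare) > 0) {
    ann <- dplyr::bind_rows(ann, tibble::tibble(id = bare, feature = "no_feature"))
  }
  actual_total <- sum(reads$length)
  tab <- ann |>
    dplyr::left_join(reads[, c("id", "length")], by = "id") |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(n_reads = dplyr::n(), total_bp = sum(.data$length),
                     .groups = "drop")
  pie_total <- sum(tab$total_bp)
  tab <- tab |>
    dplyr::mutate(pct_pie = 100 * .data$total_bp / pie_total,
                  pct_actual = 100 * .data$total_bp / actual_total) |>
    dplyr::arrange(dplyr::desc(.data$total_bp))
  structure(tab, class = c("feature_census", class(tab)),
            actual_total_bp = actual_total, pie_total_bp = pie_total,
            n_reads_total = nrow(reads))
}

#' Genome size from DNA content
#'
#' `genome size (bp) = 0.921e9 x DNA content (pg)`.
#'
#' @param dna_pg Nuclear DNA content in picograms per cell; positive.
#' @return Genome size in bp.
#' @examples
#' genome_size_from_pg(114.9)
#' @export
genome_size_from_pg <- function(dna_pg) {
  if (!is.numeric(dna_pg) || any(dna_pg <= 0)) {
    rlang::abort("`dna_pg` must be positive.")
  }
  0.921e9 * dna_pg
}

#' Fraction of the genome covered by a sequenced sample
#'
#' @param sample_bp Total sample bp; positive.
#' @param dna_pg Nuclear DNA content in pg per cell; positive.
#' @return Percent of the genome covered.
#' @examples
#' sample_fraction(6208876, 114.9)
#' @export
sample_fraction <- function(sample_bp, dna_pg) {
  if (!is.numeric(sample_bp) || any(sample_bp <= 0)) {
    rlang::abort("`sample_bp` must be positive.")
  }
  100 * sample_bp / genome_size_from_pg(dna_pg)
}
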