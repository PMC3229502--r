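# Stop-codon usage, EST abundance tables, and the exhaustive k-mer scan of
# polyA-upstream windows for overrepresented candidate polyadenylation
# signals (reported as enrichment against a composition background with
# Bonferroni control, mirroring the survey's negative-result design).

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Infer the stop codon of a transcript
#'
#' With a `frame_hint` (0, 1 or 2), the first in-frame stop codon is
#' returned. Without a hint, the longest start-to-stop open reading frame
#' across the three forward frames is located and its terminal codon
#' returned. The search stops at the polyA tail when one is detectable.
#'
#' @param seq mRNA-sense DNA string.
#' @param frame_hint Optional reading frame (0-based) of the CDS.
#' @return `"TAA"`, `"TAG"`, `"TGA"`, or `NA_character_` when no stop is
#'   found.
#' @examples
#' infer_stop_codon("ATGAAATGA", frame_hint = 0)
#' @export
infer_stop_codon <- function(seq, frame_hint = NULL) {
  .assert_seq(seq)
  pA <- find_polya_start(seq)
  body <- if (!is.na(pA)) substr(seq, 1, pA) else seq
  codons_in_frame <- function(f) {
    starts <- seq(f + 1L, nchar(body) - 2L, by = 3L)
    if (length(starts) == 0) return(character(0))
    substring(body, starts, starts + 2L)
  }
  if (!is.null(frame_hint)) {
    stopifnot(frame_hint %in% 0:2)
    cds <- codons_in_frame(as.integer(frame_hint))
    hit <- which(cds %in% STOP_CODONS)
    return(if (length(hit) == 0) NA_character_ else cds[hit[1]])
  }
  if (nchar(body) < 6) return(NA_character_)
  best_len <- 0L
  best_stop <- NA_character_
  for (f in 0:2) {
    cds <- codons_in_frame(f)
    atg <- which(cds == "ATG")
    stp <- which(cds %in% STOP_CODONS)
    for (a in atg) {
      s <- stp[stp > a]
      if (length(s) == 0) next
      orf_len <- (s[1] - a + 1L) * 3L
      if (orf_len > best_len) {
        best_len <- orf_len
        best_stop <- cds[s[1]]
      }
    }
  }
  best_stop
}

#' Stop codon usage table
#'
#' @param codons Tibble with columns `set` (dataset label) and `codon`
#'   (each `TAA`, `TAG` or `TGA`).
#' @return A tibble per set and codon: `n`, `total` (stop predictions in
#'   the set) and `pct` (percent of the set, 1 decimal, conventional
#'   rounding). Percentages within a set sum to 100 up to rounding.
#' @export
stop_codon_table <- function(codons) {
  if (!all(c("set", "codon") %in% names(codons))) {
    rlang::abort("`codons` needs columns `set` and `codon`.")
  }
  bad <- setdiff(unique(codons$codon), STOP_CODONS)
  if (length(bad) > 0) {
    rlang::abort(sprintf("Not a stop codon: %s.",
                         paste0("'", bad, "'", collapse = ", ")))
  }
  codons |>
    dplyr::mutate(codon = factor(.data$codon, levels = STOP_CODONS)) |>
    dplyr::count(.data$set, .data$codon, name = "n", .drop = FALSE) |>
    dplyr::group_by(.data$set) |>
    dplyr::mutate(total = sum(.data$n),
                  pct = round_half_up(100 * .data$n / .data$total, 1)) |>
    dplyr::ungroup() |>
    dplyr::mutate(codon = as.character(.data$codon))
}

#' Transcript abundance table from EST clusters
#'
#' Clusters (tentative consensus sequences) sharing an annotation are
#' pooled; the table reports, per annotation, the number of clusters, the
#' number of ESTs and their percentage of the whole library.
#'
#' @param clusters Tibble `id`, `cluster` (EST to cluster assignment).
#' @param annotations Tibble `cluster`, `annotation`.
#' @param total_ests Library size used as the percentage denominator.
#' @return A tibble `annotation`, `n_tcs`, `n_ests`, `pct` (2 decimals),
#'   sorted by `n_ests` descending.
#' @export
abundance_table <- function(clusters, annotations, total_ests) {
  if (total_ests <= 0) rlang::abort("`total_ests` must be positive.")
  clusters |>
    dplyr::inner_join(annotations, by = "cluster") |>
    dplyr::group_by(.data$annotation) |>
    dplyr::summarise(n_tcs = dplyr::n_distinct(.data$cluster),
                     n_ests = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(pct = round_half_up(100 * .data$n_ests / total_ests, 2)) |>
    dplyr::arrange(dplyr::desc(.data$n_ests), .data$annotation)
}

# expected k-mer counts under a per-sequence composition background
.expected_counts <- function(motifs, wins, k, background) {
  n_pos <- pmax(0L, nchar(wins) - k + 1L)
  base_counts <- t(vapply(wins, function(w) {
    tabulate(.seq_index(w), 5L)[1:4]
  }, numeric(4), USE.NAMES = FALSE))
  p <- base_counts / pmax(1, rowSums(base_counts))
  lp <- log(p)
  lp[!is.finite(lp)] <- -1e9  # a base absent from the window cannot occur
  mot_idx <- lapply(strsplit(motifs, "", fixed = TRUE), function(v) .base_index()[utf8ToInt(paste(v, collapse = ""))])
  if (background == "mono") {
    C <- t(vapply(mot_idx, function(ix) tabulate(ix, 5L)[1:4], numeric(4)))
    logprob <- C %*% t(lp)                     # motifs x windows
  } else {
    # first-order Markov: start-base composition + transition frequencies
    trans <- t(vapply(wins, function(w) {
      ix <- .seq_index(w)
      ok <- ix[-length(ix)] <= 4 & ix[-1] <= 4
      tabulate((ix[-length(ix)][ok] - 1L) * 4L + ix[-1][ok], 16L)
    }, numeric(16), USE.NAMES = FALSE))
    tp <- trans
    # row-normalise within each source base
    for (b in 0:3) {
      block <- trans[, (b * 4 + 1):(b * 4 + 4), drop = FALSE]
      tp[, (b * 4 + 1):(b * 4 + 4)] <- block / pmax(1, rowSums(block))
    }
    ltp <- log(tp); ltp[!is.finite(ltp)] <- -1e9
    Cs <- t(vapply(mot_idx, function(ix) tabulate(ix[1], 5L)[1:4], numeric(4)))
    Ct <- t(vapply(mot_idx, function(ix) {
      tabulate((ix[-length(ix)] - 1L) * 4L + ix[-1], 16L)
    }, numeric(16)))
    logprob <- Cs %*% t(lp) + Ct %*% t(ltp)
  }
  prob <- exp(logprob)
  as.numeric(prob %*% n_pos)
}

#' Scan polyA-upstream windows for overrepresented motifs
#'
#' Extracts the `window` bp immediately 5' of each transcript's polyA
#' start (clipped at the transcript start), counts every observed k-mer
#' for `k` in `k_range`, computes its expected count under a per-sequence
#' base-composition background (positions independent; optionally a
#' first-order Markov background), and tests enrichment with a one-sided
#' binomial p-value. Significance is Bonferroni-controlled over every
#' motif the scan interrogates (all `4^k` motifs summed across the sizes
#' in `k_range`), so a negative scan controls the experiment-wise error
#' of the whole search at `alpha`.
#'
#' @param records Record tibble of mRNA-sense transcripts with polyA
#'   tails.
#' @param window Upstream window in bp (the survey used 60 and 30).
#' @param k_range Length-2 integer vector, motif sizes scanned.
#' @param alpha Family-wise significance level after correction.
#' @param background `"mono"` (default) or `"di"` (first-order Markov).
#' @param min_run,max_mismatch PolyA detection parameters, see
#'   [find_polya_start()].
#' @return A `polya_motif_scan`: tibble `motif`, `k`, `observed`,
#'   `expected`, `p_value`, `p_adj`, `significant`, sorted by `p_adj`;
#'   attributes record `n_windows`, `window`, `alpha`, `background`.
#' @export
polya_motif_scan <- function(records, window = 60, k_range = c(5, 9),
                             alpha = 0.05, background = c("mono", "di"),
                             min_run = 10, max_mismatch = 1) {
  .check_records(records)
  background <- rlang::arg_match(background)
  pa <- vapply(records$seq, find_polya_start, integer(1),
               min_run = min_run, max_mismatch = max_mismatch,
               USE.NAMES = FALSE)
  keep <- !is.na(pa)
  if (!any(keep)) rlang::abort("No record has a detectable polyA tail.")
  wins <- substr(records$seq[keep], pmax(1L, pa[keep] - window + 1L), pa[keep])
  wins <- wins[nchar(wins) > 0]
  m_total <- sum(4^(k_range[1]:k_range[2]))
  res <- purrr::map(k_range[1]:k_range[2], function(k) {
    pieces <- unlist(lapply(wins, function(w) {
      L <- nchar(w)
      if (L < k) return(character(0))
      substring(w, 1:(L - k + 1L), k:L)
    }))
    if (length(pieces) == 0) return(NULL)
    counts <- table(pieces)
    motifs <- names(counts)
    obs <- as.integer(counts)
    expected <- .expected_counts(motifs, wins, k, background)
    n_pos_total <- sum(pmax(0L, nchar(wins) - k + 1L))
    pval <- stats::pbinom(obs - 1L, n_pos_total,
                          pmin(1, expected / n_pos_total),
                          lower.tail = FALSE)
    tibble::tibble(motif = motifs, k = k, observed = obs,
                   expected = expected, p_value = pval,
                   p_adj = pmin(1, pval * m_total))
  })
  out <- dplyr::bind_rows(res) |>
    dplyr::mutate(significant = .data$p_adj < alpha) |>
    dplyr::arrange(.data$p_adj, dplyr::desc(.data$observed))
  structure(out, class = c("polya_motif_scan", class(out)),
            n_windows = length(wins), window = window,
            alpha = alpha, background = background)
}
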