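# Synthetic EST, clone-end read and CDS sets with planted ground truth.
# Each generator seeds its own RNG stream from `seed` (and restores the
# caller's RNG state), so a given call is byte-reproducible regardless of
# what else has been generated.

.resolve_iupac <- function(pattern) {
  pv <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(pv, function(cd) {
    exp <- strsplit(Biostrings::IUPAC_CODE_MAP[[cd]], "", fixed = TRUE)[[1]]
    sample(exp, 1L)
  }, character(1)), collapse = "")
}

#' Generate ESTs carrying spliced-leader relict cascades
#'
#' Each EST is a resolved copy of the SL consensus followed by `depth`
#' relict copies of the 15-nt truncated SL and a random UTR/CDS tail with
#' a polyA tail. Mutation is cumulative with rank: the r-th relict carries
#' `Binomial(15, r * per_cycle_sub_rate)` substitutions, emulating the
#' progressive decay of older recycling cycles. The base immediately 5' of
#' the polyA tail is always non-A so the planted tail start is
#' unambiguous.
#'
#' @param n Number of ESTs.
#' @param cfg An [sl_config()].
#' @param depth_probs Probabilities of cascade depths `0..length-1`.
#' @param per_cycle_sub_rate Per-cycle substitution rate (0-0.3).
#' @param tail_len,polya_len Ranges (length-2) for tail and polyA lengths.
#' @param tail_gc GC fraction of the random tail.
#' @param seed Integer seed; fully determines the output.
#' @return A list with `records` (tibble `id`, `seq`, `source`, `length`)
#'   and `truth` (tibble `id`, `depth`, `identities` list column,
#'   `polya_start`, `resolved_sl`).
#' @export
generate_sl_ests <- function(n, cfg = sl_config(),
                             depth_probs = c(0.74, 0.21, 0.04, 0.008, 0.002),
                             per_cycle_sub_rate = 0.05,
                             tail_len = c(150, 400), polya_len = c(15, 30),
                             tail_gc = 0.55, seed = 1) {
  stopifnot(abs(sum(depth_probs) - 1) < 1e-6,
            per_cycle_sub_rate >= 0, per_cycle_sub_rate <= 0.3)
  withr::local_preserve_seed()
  set.seed(seed)
  tail_probs <- c((1 - tail_gc) / 2, tail_gc / 2, tail_gc / 2, (1 - tail_gc) / 2)
  rows <- purrr::map(seq_len(n), function(i) {
    sl <- .resolve_iupac(cfg$sl_consensus)
    depth <- sample(seq_along(depth_probs) - 1L, 1L, prob = depth_probs)
    relicts <- character(0)
    idents <- numeric(0)
    motif <- substr(sl, 8, 22)
    if (depth > 0) {
      for (r in seq_len(depth)) {
        n_sub <- stats::rbinom(1L, 15L, min(1, r * per_cycle_sub_rate))
        relicts <- c(relicts, .mutate_seq(motif, n_sub))
        idents <- c(idents, 1 - n_sub / 15)
      }
    }
    tl <- sample(tail_len[1]:tail_len[2], 1L)
    tail <- .random_seq(tl, tail_probs)
    substr(tail, tl, tl) <- sample(c("C", "G", "T"), 1L)
    pa <- strrep("A", sample(polya_len[1]:polya_len[2], 1L))
    seq <- paste0(sl, paste(relicts, collapse = ""), tail, pa)
    list(seq = seq, depth = depth, idents = idents,
         polya_start = nchar(seq) - nchar(pa), sl = sl)
  })
  ids <- sprintf("est_%05d", seq_len(n))
  list(
    records = tibble::tibble(
      id = ids,
      seq = vapply(rows, `[[`, character(1), "seq"),
      source = "synthetic",
      length = vapply(rows, function(r) nchar(r$seq), integer(1))),
    truth = tibble::tibble(
      id = ids,
      depth = vapply(rows, `[[`, integer(1), "depth"),
      identities = purrr::map(rows, "idents"),
      polya_start = vapply(rows, `[[`, integer(1), "polya_start"),
      resolved_sl = vapply(rows, `[[`, character(1), "sl"))
  )
}

.default_gss_composition <- function(families = aost_repeat_units()) {
  tandem <- rlang::set_names(families$genome_pct / 100, families$family)
  c(tandem, simple_repeat = 0.13, low_complexity = 0.08,
    unique = 1 - sum(tandem) - 0.13 - 0.08)
}

# dominant-pair compositions (entropy ~1.4 bits): biased enough to flag as
# low complexity, but iid so they do not double as homopolymer/dimer
# simple repeats
.low_complexity_styles <- list(
  "GA" = c(0.46, 0.04, 0.46, 0.04),
  "GC" = c(0.04, 0.46, 0.46, 0.04),
  "CT" = c(0.04, 0.46, 0.04, 0.46)
)

#' Generate clone-end survey reads with planted repeat structure
#'
#' Reads of 300-1200 bp (a typical Sanger clone-end range) are drawn from
#' a composition over tandem-repeat families, simple repeats,
#' low-complexity tracts and unique background. A tandem read is a
#' random-phase tiling of its family unit; each copy is divergent (at
#' `divergent_range` substitution vs the unit, emulating the survey's
#' 88-98%-identity interspersed copies) with probability `divergent_prob`
#' and otherwise carries only `copy_noise` sequencing-style noise.
#'
#' @param n Number of reads.
#' @param length_range Read length range in bp.
#' @param composition Named probabilities over the family names plus
#'   `simple_repeat`, `low_complexity`, `unique`; must sum to 1. The
#'   default plants the four reference units at their published genome
#'   shares.
#' @param families Tibble `family`, `unit` (each unit at least 20 bp).
#' @param divergent_prob,divergent_range,copy_noise Tandem copy model.
#' @param simple_noise Substitution rate inside simple-repeat reads.
#' @param seed Integer seed.
#' @return A list with `records` and `truth` (per read: `category`,
#'   `family`, `unit_length`, `n_units` complete planted copies,
#'   `array_start` 0-based, `planted_bp = n_units * unit_length`,
#'   `style`, `unit`).
#' @export
generate_gss_reads <- function(n, length_range = c(300, 1200),
                               composition = NULL,
                               families = aost_repeat_units(),
                               divergent_prob = 0.25,
                               divergent_range = c(0.02, 0.12),
                               copy_noise = 0.005, simple_noise = 0.02,
                               seed = 1) {
  if (any(nchar(families$unit) < 20)) {
    rlang::abort("Family units must be at least 20 bp.")
  }
  composition <- composition %||% .default_gss_composition(families)
  cats <- names(composition)
  if (abs(sum(composition) - 1) > 1e-6) {
    rlang::abort("`composition` must sum to 1.")
  }
  empty <- function() {
    list(records = tibble::tibble(id = character(0), seq = character(0),
                                  source = character(0), length = integer(0)),
         truth = tibble::tibble(id = character(0), category = character(0),
                                family = character(0), unit_length = integer(0),
                                n_units = integer(0), array_start = integer(0),
                                planted_bp = integer(0), style = character(0),
                                unit = character(0)))
  }
  if (n == 0) return(empty())
  withr::local_preserve_seed()
  set.seed(seed)
  unique_probs <- c(0.2, 0.3, 0.3, 0.2)  # 60% GC background
  rows <- purrr::map(seq_len(n), function(i) {
    L <- sample(length_range[1]:length_range[2], 1L)
    cat_i <- sample(cats, 1L, prob = composition)
    tr <- list(category = cat_i, family = NA_character_,
               unit_length = NA_integer_, n_units = NA_integer_,
               array_start = NA_integer_, planted_bp = 0L,
               style = NA_character_, unit = NA_character_)
    if (cat_i %in% families$family) {
      unit <- families$unit[families$family == cat_i]
      p <- nchar(unit)
      phi <- sample(0:(p - 1L), 1L)
      m <- ceiling((phi + L) / p)
      copies <- vapply(seq_len(m), function(j) {
        if (stats::runif(1) < divergent_prob) {
          .noisy_copy(unit, stats::runif(1, divergent_range[1], divergent_range[2]))
        } else .noisy_copy(unit, copy_noise)
      }, character(1))
      seq <- substr(paste(copies, collapse = ""), phi + 1L, phi + L)
      j0 <- if (phi == 0L) 1L else 2L
      jmax <- (phi + L) %/% p
      k <- max(0L, jmax - j0 + 1L)
      tr$category <- "tandem"
      tr$family <- cat_i
      tr$unit_length <- p
      tr$n_units <- k
      tr$array_start <- (j0 - 1L) * p - phi
      tr$planted_bp <- k * p
      tr$unit <- unit
    } else if (cat_i == "simple_repeat") {
      u <- sample(2:6, 1L)
      unit <- .random_seq(u)
      while (nchar(.primitive_unit(unit)) < u) unit <- .random_seq(u)
      seq <- .noisy_copy(substr(strrep(unit, ceiling(L / u)), 1, L), simple_noise)
      tr$unit <- .min_rotation(unit)
      tr$unit_length <- u
      tr$planted_bp <- L
    } else if (cat_i == "low_complexity") {
      style <- sample(names(.low_complexity_styles), 1L)
      seq <- .random_seq(L, .low_complexity_styles[[style]])
      tr$style <- style
      tr$planted_bp <- L
    } else {
      seq <- .random_seq(L, unique_probs)
    }
    c(list(seq = seq), tr)
  })
  ids <- sprintf("read_%05d", seq_len(n))
  list(
    records = tibble::tibble(
      id = ids,
      seq = vapply(rows, `[[`, character(1), "seq"),
      source = "synthetic",
      length = vapply(rows, function(r) nchar(r$seq), integer(1))),
    truth = tibble::tibble(
      id = ids,
      category = vapply(rows, `[[`, character(1), "category"),
      family = vapply(rows, `[[`, character(1), "family"),
      unit_length = vapply(rows, `[[`, integer(1), "unit_length"),
      n_units = vapply(rows, `[[`, integer(1), "n_units"),
      array_start = vapply(rows, `[[`, integer(1), "array_start"),
      planted_bp = vapply(rows, `[[`, integer(1), "planted_bp"),
      style = vapply(rows, `[[`, character(1), "style"),
      unit = vapply(rows, `[[`, character(1), "unit"))
  )
}

#' Generate CDS transcripts with chosen stop-codon usage and GC3 bias
#'
#' Each transcript is `ATG` + random non-stop codons (third positions
#' drawn G/C with probability `gc3`) + a stop codon drawn from
#' `stop_probs` + a 3' UTR (ending in a non-A base) + a polyA tail. The
#' CDS always starts at position 0 (frame 0).
#'
#' @param n Number of transcripts.
#' @param stop_probs Named probabilities for `TAA`, `TAG`, `TGA`; sum 1.
#' @param gc3 Probability that a codon third position is G or C.
#' @param n_codons Range of internal codon counts.
#' @param utr3_len,polya_len Ranges for UTR and tail lengths.
#' @param seed Integer seed.
#' @return A list with `records` and `truth` (per transcript: `stop_codon`,
#'   `frame`, `polya_start`, `n_codons`).
#' @export
generate_cds_set <- function(n, stop_probs = c(TAA = 0.072, TAG = 0.165, TGA = 0.763),
                             gc3 = 0.8, n_codons = c(50, 200),
                             utr3_len = c(20, 60), polya_len = c(15, 30),
                             seed = 1) {
  stopifnot(abs(sum(stop_probs) - 1) < 1e-6)
  stop_probs <- stop_probs[STOP_CODONS]
  if (n == 0) {
    return(list(records = tibble::tibble(id = character(0), seq = character(0),
                                         source = character(0), length = integer(0)),
                truth = tibble::tibble(id = character(0), stop_codon = character(0),
                                       frame = integer(0), polya_start = integer(0),
                                       n_codons = integer(0))))
  }
  withr::local_preserve_seed()
  set.seed(seed)
  utr_probs <- c(0.225, 0.275, 0.275, 0.225)
  rand_codon <- function() {
    repeat {
      b12 <- sample(DNA_BASES, 2L, replace = TRUE)
      b3 <- if (stats::runif(1) < gc3) sample(c("G", "C"), 1L) else sample(c("A", "T"), 1L)
      cod <- paste(c(b12, b3), collapse = "")
      if (!cod %in% STOP_CODONS) return(cod)
    }
  }
  rows <- purrr::map(seq_len(n), function(i) {
    nc <- sample(n_codons[1]:n_codons[2], 1L)
    cds <- vapply(seq_len(nc), function(j) rand_codon(), character(1))
    stop <- sample(STOP_CODONS, 1L, prob = stop_probs)
    ul <- sample(utr3_len[1]:utr3_len[2], 1L)
    utr <- .random_seq(ul, utr_probs)
    substr(utr, ul, ul) <- sample(c("C", "G", "T"), 1L)
    pa <- strrep("A", sample(polya_len[1]:polya_len[2], 1L))
    seq <- paste0("ATG", paste(cds, collapse = ""), stop, utr, pa)
    list(seq = seq, stop = stop, polya_start = nchar(seq) - nchar(pa),
         n_codons = nc)
  })
  ids <- sprintf("cds_%05d", seq_len(n))
  list(
    records = tibble::tibble(
      id = ids,
      seq = vapply(rows, `[[`, character(1), "seq"),
      source = "synthetic",
      length = vapply(rows, function(r) nchar(r$seq), integer(1))),
    truth = tibble::tibble(
      id = ids,
      stop_codon = vapply(rows, `[[`, character(1), "stop"),
      frame = 0L,
      polya_start = vapply(rows, `[[`, integer(1), "polya_start"),
      n_codons = vapply(rows, `[[`, integer(1), "n_codons"))
  )
}
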