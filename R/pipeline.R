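# End-to-end survey pipeline: validated configuration, stage orchestration
# and a TSV/JSON report bundle with provenance (seed + config hash) on
# every output.

#' Pipeline configuration
#'
#' Collects and validates everything the pipeline stages need. Input FASTA
#' paths are optional: a stage with no input runs on synthetic data
#' generated from `simulate` and `seed`, so the whole pipeline is runnable
#' without any external file.
#'
#' @param out_dir Output directory (created if needed).
#' @param est_fasta,gss_fasta,cds_fasta Optional input FASTA paths.
#' @param seed Integer seed for all synthetic stages.
#' @param sl An [sl_config()].
#' @param cluster A [cluster_params()] for the genomic read clustering.
#' @param tandem List of [annotate_arrays()] thresholds.
#' @param families Reference repeat units for family seeding.
#' @param dna_pg Nuclear DNA content in pg (genome-size arithmetic).
#' @param motif_window PolyA-upstream window in bp.
#' @param simulate Synthetic sample sizes (`n_ests`, `n_reads`, `n_cds`)
#'   used for stages without an input file.
#' @param annotations Optional external pass-through labels, a tibble with
#'   `id` and `feature` (e.g. library-annotated genes or transposons);
#'   never computed by the package.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            est_fasta = NULL, gss_fasta = NULL, cds_fasta = NULL,
                            seed = 1,
                            sl = sl_config(),
                            cluster = cluster_params(),
                            tandem = list(min_p = 20, max_p = 300,
                                          min_identity = 0.85,
                                          divergent_floor = 0.85),
                            families = aost_repeat_units(),
                            dna_pg = 114.9,
                            motif_window = 60,
                            simulate = list(n_ests = 200, n_reads = 250, n_cds = 150),
                            annotations = NULL) {
  for (p in c(est_fasta, gss_fasta, cds_fasta)) {
    if (!file.exists(p)) {
      rlang::abort(sprintf("Input FASTA '%s' does not exist.", p))
    }
  }
  stopifnot(inherits(sl, "sl_config"), inherits(cluster, "cluster_params"),
            dna_pg > 0, motif_window > 0)
  cfg <- list(out_dir = out_dir, est_fasta = est_fasta, gss_fasta = gss_fasta,
              cds_fasta = cds_fasta, seed = as.integer(seed), sl = sl,
              cluster = cluster, tandem = tandem, families = families,
              dna_pg = dna_pg, motif_window = motif_window,
              simulate = simulate, annotations = annotations)
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = "pipeline_config")
}

#' Annotate whole reads with sequence features
#'
#' Combines repetitiveness categories, tandem arrays, simple repeats,
#' low-complexity tracts and optional external labels into the per-read
#' feature table that [feature_census()] consumes. Interval-level features
#' (arrays, simple repeats, low complexity) annotate a read when they
#' cover at least `min_coverage` of it; repetitiveness annotates the whole
#' read by construction.
#'
#' @param reads Record tibble.
#' @param clusters Optional output of [greedy_overlap_cluster()].
#' @param arrays Optional output of [annotate_arrays()].
#' @param external Optional tibble `id`, `feature` of pass-through labels.
#' @param min_coverage Minimum covered fraction for interval features
#'   (default 0.5: a read is annotated with an interval feature when that
#'   feature makes up the majority of it).
#' @param highly_threshold See [classify_repetitiveness()].
#' @return A tibble `id`, `feature` (multiple rows per read possible).
#' @export
annotate_read_features <- function(reads, clusters = NULL, arrays = NULL,
                                   external = NULL, min_coverage = 0.5,
                                   highly_threshold = 20) {
  .check_records(reads)
  feats <- list()
  if (!is.null(clusters)) {
    cat <- classify_repetitiveness(clusters, highly_threshold)
    feats$rep <- cat |>
      dplyr::filter(.data$category != "unique") |>
      dplyr::transmute(.data$id, feature = .data$category)
  }
  if (!is.null(arrays) && nrow(arrays) > 0) {
    lens <- rlang::set_names(nchar(reads$seq), reads$id)
    feats$arr <- arrays |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(bp = sum(.data$end - .data$start), .groups = "drop") |>
      dplyr::filter(.data$bp >= min_coverage * lens[.data$id]) |>
      dplyr::transmute(.data$id, feature = "tandem_array")
  }
  interval_bp <- function(f) {
    vapply(reads$seq, function(s) {
      iv <- f(s)
      if (nrow(iv) == 0) 0 else sum(as.numeric(iv$end - iv$start))
    }, numeric(1), USE.NAMES = FALSE)
  }
  sr <- interval_bp(find_simple_repeats)
  lc <- interval_bp(find_low_complexity)
  lens <- nchar(reads$seq)
  feats$sr <- tibble::tibble(id = reads$id[sr >= min_coverage * lens],
                             feature = "simple_repeats")
  feats$lc <- tibble::tibble(id = reads$id[lc >= min_coverage * lens],
                             feature = "low_complexity")
  if (!is.null(external)) feats$ext <- external[, c("id", "feature")]
  dplyr::bind_rows(feats) |> dplyr::distinct()
}

.write_tsv_prov <- function(x, path, cfg) {
  writeLines(sprintf("# dinogss %s seed=%d config=%s",
                     as.character(utils::packageVersion("dinogss")),
                     cfg$seed, cfg$hash), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("Pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)))
  })
}

#' Run the full survey pipeline
#'
#' Runs SL scanning, tandem-array detection, the repetitiveness census and
#' coding statistics on the configured (or synthetic) inputs, and writes
#' `chains.tsv`, `arrays.tsv`, `families.tsv`, `census.tsv`,
#' `stop_codons.tsv`, `motifs.tsv` and `summary.json` to the output
#' directory. Every TSV starts with a provenance comment (package version,
#' seed, config hash). Reruns with the same config and seed produce
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the in-memory stage results
#'   (`chains`, `chain_summary`, `arrays`, `family_fractions`, `census`,
#'   `stop_table`, `motifs`, `summary`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  ests <- .stage("inputs", {
    if (is.null(config$est_fasta)) {
      generate_sl_ests(config$simulate$n_ests, cfg = config$sl,
                       seed = config$seed)$records
    } else read_fasta(config$est_fasta, source = "est")
  })
  gss <- .stage("inputs", {
    if (is.null(config$gss_fasta)) {
      generate_gss_reads(config$simulate$n_reads, families = config$families,
                         seed = config$seed + 1L)$records
    } else read_fasta(config$gss_fasta, source = "gss")
  })
  cds <- .stage("inputs", {
    if (is.null(config$cds_fasta)) {
      generate_cds_set(config$simulate$n_cds, seed = config$seed + 2L)$records
    } else read_fasta(config$cds_fasta, source = "cds")
  })

  # --- SL scan ---
  sl_res <- .stage("slscan", {
    matches <- find_canonical_sl(ests, config$sl)
    uniq <- dedupe_and_trim(ests, matches)
    chains <- scan_relict_chain(uniq, config$sl)
    list(matches = matches, uniq = uniq, chains = chains,
         summary = classify_chain_counts(chains))
  })
  chains_tsv <- sl_res$chains |>
    dplyr::left_join(sl_res$matches, by = "id") |>
    dplyr::transmute(.data$id, .data$sl_start, .data$sl_identity, .data$k,
                     identities = vapply(.data$identities, function(x)
                       paste(sprintf("%.3f", x), collapse = ","), character(1)))
  .write_tsv_prov(chains_tsv, out("chains.tsv"), config)

  # --- tandem arrays ---
  td <- config$tandem
  tandem_res <- .stage("tandem", {
    arrays <- annotate_arrays(gss, min_p = td$min_p, max_p = td$max_p,
                              min_identity = td$min_identity,
                              divergent_floor = td$divergent_floor)
    arrays <- assign_repeat_families(arrays, ref_units = config$families)
    fractions <- estimate_family_fraction(arrays, total_bp = sum(nchar(gss$seq)))
    list(arrays = arrays, fractions = fractions)
  })
  .write_tsv_prov(
    dplyr::select(tandem_res$arrays, -"per_unit_identity"),
    out("arrays.tsv"), config)
  .write_tsv_prov(tandem_res$fractions, out("families.tsv"), config)

  # --- census ---
  census_res <- .stage("census", {
    clusters <- greedy_overlap_cluster(gss, config$cluster)
    features <- annotate_read_features(gss, clusters = clusters,
                                       arrays = tandem_res$arrays,
                                       external = config$annotations)
    census <- feature_census(gss, features)
    list(clusters = clusters, census = census)
  })
  .write_tsv_prov(tibble::as_tibble(census_res$census), out("census.tsv"), config)

  # --- coding statistics ---
  coding_res <- .stage("codingstats", {
    stops <- vapply(cds$seq, infer_stop_codon, character(1),
                    frame_hint = 0, USE.NAMES = FALSE)
    stop_tab <- stop_codon_table(
      tibble::tibble(set = "cds", codon = stops[!is.na(stops)]))
    motifs <- polya_motif_scan(cds, window = config$motif_window)
    list(stop_table = stop_tab, motifs = motifs)
  })
  .write_tsv_prov(coding_res$stop_table, out("stop_codons.tsv"), config)
  .write_tsv_prov(tibble::as_tibble(coding_res$motifs), out("motifs.tsv"), config)

  summary <- list(
    seed = config$seed,
    config_hash = config$hash,
    n_ests = nrow(ests),
    n_sl_matches = nrow(sl_res$matches),
    n_unique_sl = attr(sl_res$uniq, "n_unique"),
    chain_histogram = sl_res$summary$histogram,
    n_gss_reads = nrow(gss),
    gss_total_bp = sum(nchar(gss$seq)),
    gss_gc = round(mean(gc_content(gss$seq)), 4),
    family_fractions = tandem_res$fractions,
    census = tibble::as_tibble(census_res$census),
    n_cds = nrow(cds),
    stop_codons = coding_res$stop_table,
    n_significant_motifs = sum(coding_res$motifs$significant),
    genome_size_bp = genome_size_from_pg(config$dna_pg),
    sample_fraction_pct = sample_fraction(sum(nchar(gss$seq)), config$dna_pg)
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    chains = sl_res$chains, chain_summary = sl_res$summary,
    arrays = tandem_res$arrays, family_fractions = tandem_res$fractions,
    clusters = census_res$clusters, census = census_res$census,
    stop_table = coding_res$stop_table, motifs = coding_res$motifs,
    summary = summary,
    paths = vapply(c("chains.tsv", "arrays.tsv", "families.tsv", "census.tsv",
                     "stop_codons.tsv", "motifs.tsv", "summary.json"),
                   out, character(1))
  ))
}
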