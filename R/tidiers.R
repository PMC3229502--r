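# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname classify_chain_counts
#' @param x An `sl_chain_summary`.
#' @param ... Unused.
#' @method tidy sl_chain_summary
#' @export
tidy.sl_chain_summary <- function(x, ...) x$histogram

#' @rdname classify_chain_counts
#' @method glance sl_chain_summary
#' @export
glance.sl_chain_summary <- function(x, ...) {
  with_rel <- sum(x$histogram$n[x$histogram$k > 0])
  tibble::tibble(
    n_records = x$n_records,
    n_with_relict = with_rel,
    frac_with_relict = with_rel / x$n_records,
    max_depth = max(x$histogram$k)
  )
}

#' @rdname feature_census
#' @param x A `feature_census`.
#' @param ... Unused.
#' @method tidy feature_census
#' @export
tidy.feature_census <- function(x, ...) tibble::as_tibble(x)

#' @rdname feature_census
#' @method glance feature_census
#' @export
glance.feature_census <- function(x, ...) {
  tibble::tibble(
    n_reads = attr(x, "n_reads_total"),
    actual_total_bp = attr(x, "actual_total_bp"),
    pie_total_bp = attr(x, "pie_total_bp"),
    n_features = nrow(x)
  )
}

#' @rdname polya_motif_scan
#' @param x A `polya_motif_scan`.
#' @param ... Unused.
#' @method tidy polya_motif_scan
#' @export
tidy.polya_motif_scan <- function(x, ...) tibble::as_tibble(x)

#' @rdname polya_motif_scan
#' @method glance polya_motif_scan
#' @export
glance.polya_motif_scan <- function(x, ...) {
  tibble::tibble(
    n_windows = attr(x, "n_windows"),
    window = attr(x, "window"),
    alpha = attr(x, "alpha"),
    background = attr(x, "background"),
    n_motifs_tested = nrow(x),
    n_significant = sum(x$significant)
  )
}
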