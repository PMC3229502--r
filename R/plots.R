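# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a relict-chain depth histogram
#'
#' @param object An `sl_chain_summary` from [classify_chain_counts()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sl_chain_summary
#' @export
autoplot.sl_chain_summary <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = factor(.data$k), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", 100 * .data$fraction)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = "relict SL copies downstream of the canonical SL",
                  y = "ESTs",
                  title = sprintf("Relict SL cascade depths (n = %d)",
                                  object$n_records)) +
    ggplot2::theme_minimal()
}

#' Plot a feature census
#'
#' @param object A `feature_census` from [feature_census()].
#' @param which `"actual"` or `"pie"` percentages.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot feature_census
#' @export
autoplot.feature_census <- function(object, which = c("actual", "pie"), ...) {
  which <- rlang::arg_match(which)
  col <- if (which == "actual") "pct_actual" else "pct_pie"
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature, .data[[col]]),
                                   y = .data[[col]])) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("%% of total bp (%s)", which),
                  title = "Genomic feature census") +
    ggplot2::theme_minimal()
}

#' Plot a polyA-motif enrichment scan
#'
#' Observed versus expected counts, coloured by Bonferroni-corrected
#' significance; a diagonal marks the null.
#'
#' @param object A `polya_motif_scan`.
#' @param top Motifs with the smallest adjusted p-values labelled.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot polya_motif_scan
#' @export
autoplot.polya_motif_scan <- function(object, top = 5, ...) {
  df <- tibble::as_tibble(object)
  lab <- utils::head(df[order(df$p_adj), ], top)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed,
                                   colour = .data$significant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$motif),
                       vjust = -0.6, size = 3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red")) +
    ggplot2::labs(x = "expected count", y = "observed count",
                  title = sprintf("polyA-upstream motif scan (%d windows, %d bp)",
                                  attr(object, "n_windows"), attr(object, "window"))) +
    ggplot2::theme_minimal()
}

#' Plot an in-silico digest fragment ladder
#'
#' @param fragments Integer fragment lengths from [in_silico_digest()].
#' @param binwidth Histogram bin width in bp.
#' @return A ggplot.
#' @export
plot_fragment_ladder <- function(fragments, binwidth = 10) {
  df <- tibble::tibble(length = fragments)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::labs(x = "fragment length (bp)", y = "fragments",
                  title = "In-silico restriction digest") +
    ggplot2::theme_minimal()
}
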