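#' Plot mutation frequencies
#'
#' Bar chart of family/gene mutation frequencies; when length-normalized
#' values are present a second panel shows the %/kbp scale.
#'
#' @param freqs Frequency-entry tibble (e.g. from [frequency_table()]).
#' @return A ggplot object.
#' @export
plot_frequencies <- function(freqs) {
  df <- dplyr::mutate(freqs, unit = stats::reorder(.data$unit, -.data$frequency_pct))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$unit, y = .data$frequency_pct)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$frequency_pct)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "mutated cell lines (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (length(unique(df$stratum)) > 1L) {
    p <- p + ggplot2::facet_wrap(~stratum)
  }
  p
}

#' @export
autoplot.ms_freq <- function(object, ...) plot_frequencies(object)

#' Plot mutation-type distributions
#'
#' Stacked bar chart of the four protein-altering mutation classes per
#' stratum.
#'
#' @param dist Output of [type_distribution()] (rows over strata allowed).
#' @return A ggplot object.
#' @export
plot_type_distribution <- function(dist) {
  df <- dist[!is.na(dist$share), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$share,
                                   fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "share of mutations", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.ms_typedist <- function(object, ...) plot_type_distribution(object)

#' Lollipop-style positional plot of mutations on one protein
#'
#' Plain positional rendering: domain intervals as a track, one stemmed
#' point per mutated position sized by recurrence and colored by
#' classification.
#'
#' @param records Mutation records of one gene (positioned).
#' @param gene_model The gene's [gene_model()].
#' @return A ggplot object.
#' @export
plot_lollipop <- function(records, gene_model) {
  recs <- records[records$gene_symbol == gene_model$gene_symbol &
                    !is.na(records$protein_position), , drop = FALSE]
  counts <- dplyr::count(recs, .data$protein_position, .data$classification)
  dom <- gene_model$domains
  p <- ggplot2::ggplot()
  if (nrow(dom)) {
    p <- p + ggplot2::geom_rect(
      data = dom,
      ggplot2::aes(xmin = .data$start_aa, xmax = .data$end_aa,
                   ymin = -0.6, ymax = -0.1),
      fill = "steelblue", alpha = 0.5
    )
  }
  p +
    ggplot2::geom_segment(
      data = counts,
      ggplot2::aes(x = .data$protein_position, xend = .data$protein_position,
                   y = 0, yend = .data$n), color = "grey60"
    ) +
    ggplot2::geom_point(
      data = counts,
      ggplot2::aes(x = .data$protein_position, y = .data$n,
                   color = .data$classification, size = .data$n)
    ) +
    ggplot2::scale_size_continuous(range = c(1.5, 4), guide = "none") +
    ggplot2::xlim(1, gene_model$protein_length_aa) +
    ggplot2::labs(x = sprintf("%s amino-acid position", gene_model$gene_symbol),
                  y = "records", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot copy-number alteration frequencies
#'
#' @param cna Output of [cna_frequencies()].
#' @return A ggplot object.
#' @export
plot_cna <- function(cna) {
  df <- cna |>
    tidyr::pivot_longer(c("amplified_pct", "deleted_pct"),
                        names_to = "alteration", values_to = "pct") |>
    dplyr::mutate(alteration = ifelse(.data$alteration == "amplified_pct",
                                      "amplification", "deep deletion"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_symbol, y = .data$pct,
                                   fill = .data$alteration)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "cell lines (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ms_cna <- function(object, ...) plot_cna(object)

#' Plot ranked cell-line vs primary-tumor deltas
#'
#' @param deltas Output of [rank_deltas()] (or [compute_deltas()]).
#' @return A ggplot object.
#' @export
plot_cohort_deltas <- function(deltas) {
  df <- if (!"rank" %in% names(deltas)) rank_deltas(deltas) else deltas
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$delta_per_10kbp,
                                   color = .data$unit)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "rank", y = expression(Delta * "% / 10 kbp"),
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ms_deltas <- function(object, ...) plot_cohort_deltas(object)
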