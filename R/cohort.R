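#' Default cell-line / primary-tumor cohort pairing
#'
#' The twelve cell-type strata with a matched primary-tumor dataset, with
#' the documented tumor-cohort sizes of the reference datasets (endometrial
#' n = 248, prostate 112, large intestine 224, oesophagus 146, lung 230,
#' glioblastoma/CNS 291, ovary 316, skin/melanoma 121, liver 231, pancreas
#' 99, breast 507, renal 424; > 2900 tumors in total).
#'
#' @return Tibble `cell_type`, `tumor_dataset`, `tumor_n`.
#' @export
default_pairing <- function() {
  tibble::tribble(
    ~cell_type,               ~tumor_dataset,            ~tumor_n,
    "endometrium",            "endometrium",             248L,
    "prostate",               "prostate",                112L,
    "large_intestine",        "large_intestine",         224L,
    "oesophagus",             "oesophagus",              146L,
    "lung",                   "lung",                    230L,
    "central_nervous_system", "central_nervous_system",  291L,
    "ovary",                  "ovary",                   316L,
    "melanoma",               "melanoma",                121L,
    "liver",                  "liver",                   231L,
    "pancreas",               "pancreas",                 99L,
    "breast",                 "breast",                  507L,
    "kidney",                 "kidney",                  424L
  )
}

#' Pair cell-line and primary-tumor frequency entries
#'
#' Matches frequency entries from the two cohorts stratum by stratum
#' according to a pairing config. Only paired strata are emitted; cell-line
#' strata without a pairing are reported via the `unpaired` attribute. A
#' pairing that references a stratum missing from either cohort's
#' frequencies is a hard error naming it.
#'
#' @param cellline_freqs,tumor_freqs Frequency-entry tibbles (from
#'   [frequency_table()]) computed with the same family definitions; the
#'   tumor table's `stratum` holds the tumor dataset label.
#' @param pairing Tibble with `cell_type` and `tumor_dataset` columns (see
#'   [default_pairing()]) or a named character vector
#'   `cell_type -> tumor_dataset`.
#' @return Tibble `unit` (family), `cell_type`, `freq_cell_lines_pct`,
#'   `freq_tumors_pct`, plus carried-through denominators.
#' @export
pair_cohorts <- function(cellline_freqs, tumor_freqs, pairing = default_pairing()) {
  if (!is.data.frame(pairing)) {
    pairing <- tibble::tibble(cell_type = names(pairing),
                              tumor_dataset = unname(pairing))
  }
  missing_cl <- setdiff(pairing$cell_type, cellline_freqs$stratum)
  if (length(missing_cl)) {
    rlang::abort(sprintf("pairing references missing cell-line stratum: %s",
                         paste(missing_cl, collapse = ", ")))
  }
  missing_tu <- setdiff(pairing$tumor_dataset, tumor_freqs$stratum)
  if (length(missing_tu)) {
    rlang::abort(sprintf("pairing references missing tumor cohort: %s",
                         paste(missing_tu, collapse = ", ")))
  }
  cl <- cellline_freqs |>
    dplyr::select("unit", cell_type = "stratum",
                  freq_cell_lines_pct = "frequency_pct",
                  n_cell_lines = "n_lines")
  tu <- tumor_freqs |>
    dplyr::select("unit", tumor_dataset = "stratum",
                  freq_tumors_pct = "frequency_pct",
                  n_tumors = "n_lines")
  out <- pairing |>
    dplyr::select("cell_type", "tumor_dataset") |>
    dplyr::inner_join(cl, by = "cell_type", relationship = "many-to-many") |>
    dplyr::inner_join(tu, by = c("tumor_dataset", "unit")) |>
    dplyr::relocate("unit", "cell_type")
  attr(out, "unpaired") <- setdiff(unique(cellline_freqs$stratum),
                                   c(pairing$cell_type, "ALL"))
  out
}

#' Cell-line minus primary-tumor frequency differences
#'
#' For each paired (family, cell type), the percentage-point difference
#' `delta_pct = freq_cell_lines_pct - freq_tumors_pct` and its
#' length-normalized counterpart
#' `delta_per_10kbp = delta_pct / (avg_cds_length_bp / 10000)`, which makes
#' families with different coding-region sizes comparable. Negative deltas
#' are meaningful (a stratum more mutated in primary tumors than in lines).
#'
#' @param pairs Output of [pair_cohorts()].
#' @param families Named list of [gene_family()] objects (or member
#'   vectors) covering every `unit` in `pairs`.
#' @param gene_models `gene_model_set` supplying member CDS lengths; a
#'   family without lengths is a hard error.
#' @return Tibble of cohort deltas, class `ms_deltas`.
#' @export
compute_deltas <- function(pairs, families, gene_models) {
  fams <- purrr::imap(families, function(f, nm) {
    if (inherits(f, "gene_family")) f else gene_family(nm, f)
  })
  lengths <- purrr::map_dbl(fams, avg_cds_length, models = gene_models)
  names(lengths) <- purrr::map_chr(fams, "name")
  missing <- setdiff(unique(pairs$unit), names(lengths))
  if (length(missing)) {
    rlang::abort(sprintf("no family length for unit(s): %s",
                         paste(missing, collapse = ", ")))
  }
  out <- pairs |>
    dplyr::mutate(
      avg_cds_length_bp = unname(lengths[.data$unit]),
      delta_pct = .data$freq_cell_lines_pct - .data$freq_tumors_pct,
      delta_per_10kbp = .data$delta_pct / (.data$avg_cds_length_bp / 10000)
    )
  class(out) <- c("ms_deltas", class(out))
  out
}

#' Rank cohort deltas
#'
#' Orders deltas by length-normalized difference, largest cell-line excess
#' first; ties break by family name then cell type, so the ranking is
#' deterministic and invariant under a common positive rescaling of all
#' lengths.
#'
#' @param deltas Output of [compute_deltas()].
#' @return `deltas` sorted, with a `rank` column.
#' @export
rank_deltas <- function(deltas) {
  out <- deltas |>
    dplyr::arrange(dplyr::desc(.data$delta_per_10kbp), .data$unit,
                   .data$cell_type) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- unique(c("ms_deltas", class(out)))
  out
}
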