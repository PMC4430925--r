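#' Gene-family mutation frequency
#'
#' Fraction of cell lines in a stratum carrying at least one mutation in any
#' family member, counting each line at most once (the max-one-mutation-
#' per-line rule). The denominator is the number of annotated cell lines in
#' the stratum, mutated or not.
#'
#' @param records Filtered mutation record tibble.
#' @param annotations Sample annotations defining the stratum denominators.
#' @param family A [gene_family()] (or character vector of member symbols).
#' @param stratum `"ALL"` (default) or a retained cell-type label; an
#'   unknown stratum is a hard error.
#' @param gene_models Optional `gene_model_set`; when supplied, a family
#'   with no member present in the models is a hard error.
#' @return One-row tibble (a frequency entry): `unit`, `stratum`,
#'   `n_mutated_lines`, `n_lines`, `frequency_pct`, `per_kbp_pct`
#'   (`NA` until [normalize_by_length()] is applied).
#' @examples
#' ann <- tibble::tibble(sample_id = paste0("s", 1:10),
#'                       cell_type = "lung", cohort = "cell_line")
#' rec <- tibble::tibble(gene_symbol = c("NOTCH1", "NOTCH2", "NOTCH3"),
#'                       sample_id = c("s1", "s1", "s2"),
#'                       cell_type = "lung", classification = "missense",
#'                       protein_position = c(10L, 20L, 30L),
#'                       ref_aa = "A", alt_aa = "T",
#'                       allelic_fraction = 0.5, protein_change = "")
#' family_frequency(rec, ann, gene_family("NOTCH", paste0("NOTCH", 1:4)))
#' @export
family_frequency <- function(records, annotations, family, stratum = "ALL",
                             gene_models = NULL) {
  fam <- as_family(family)
  check_family_models(fam, gene_models)
  ann <- stratum_annotations(annotations, stratum)
  in_family <- records[records$gene_symbol %in% fam$members &
                         records$sample_id %in% ann$sample_id, , drop = FALSE]
  n_mut <- dplyr::n_distinct(in_family$sample_id)
  n_lines <- nrow(ann)
  freq_entry(fam$name, stratum, n_mut, n_lines)
}

#' Single-gene mutation frequency
#'
#' [family_frequency()] for a one-member family: distinct mutated lines
#' over annotated lines in the stratum.
#'
#' @inheritParams family_frequency
#' @param gene Gene symbol.
#' @return One-row frequency-entry tibble.
#' @export
gene_frequency <- function(records, annotations, gene, stratum = "ALL",
                           gene_models = NULL) {
  family_frequency(records, annotations, gene_family(gene, gene), stratum,
                   gene_models = gene_models)
}

#' Length-normalize frequency entries
#'
#' Rescales `frequency_pct` by the family's average coding-sequence length
#' so that families with large coding regions are comparable to small ones:
#' `per_kbp_pct = frequency_pct / (avg_cds_length_bp / 1000)` (or `/ 10000`
#' for the `per_10kbp` scale, stored in `per_10kbp_pct`). `frequency_pct`
#' itself is unchanged, so multiplying back by `length/scale` recovers it
#' exactly.
#'
#' @param entries Frequency-entry tibble (any number of rows, one unit).
#' @param family A [gene_family()], gene symbol vector, or `NULL` if
#'   `avg_cds_length_bp` is given directly.
#' @param gene_models `gene_model_set` used to look up member CDS lengths.
#' @param scale `"per_kbp"` (default) or `"per_10kbp"`.
#' @param avg_cds_length_bp Optional explicit average CDS length in bp.
#' @return `entries` with the normalized column filled in.
#' @export
normalize_by_length <- function(entries, family = NULL, gene_models = NULL,
                                scale = c("per_kbp", "per_10kbp"),
                                avg_cds_length_bp = NULL) {
  scale <- match.arg(scale)
  if (is.null(avg_cds_length_bp)) {
    if (is.null(family) || is.null(gene_models)) {
      rlang::abort("supply either avg_cds_length_bp or family + gene_models")
    }
    avg_cds_length_bp <- avg_cds_length(family, gene_models)
  }
  if (!is.numeric(avg_cds_length_bp) || avg_cds_length_bp <= 0) {
    rlang::abort("avg_cds_length_bp must be positive")
  }
  divisor <- avg_cds_length_bp / switch(scale, per_kbp = 1000, per_10kbp = 10000)
  col <- switch(scale, per_kbp = "per_kbp_pct", per_10kbp = "per_10kbp_pct")
  entries[[col]] <- entries$frequency_pct / divisor
  entries$avg_cds_length_bp <- avg_cds_length_bp
  entries
}

#' Mutation-type distribution within a stratum
#'
#' Relative shares of the four protein-altering mutation classes
#' (missense, nonsense, frameshift, in-frame indel) among ALL mutation
#' records in the stratum — no per-line deduplication. Records outside the
#' bins (splice, other, ...) are excluded from the denominator and their
#' count reported in the `n_excluded` attribute.
#'
#' @param records Filtered mutation records, already restricted to the gene
#'   set of interest.
#' @param stratum `"ALL"` or a cell-type label.
#' @param class_bins Classes forming the distribution.
#' @return Tibble with one row per bin: `stratum`, `classification`, `n`,
#'   `share` (sums to 1 when any binned mutation exists; all-`NA` shares,
#'   flagged by the `empty` attribute, otherwise). Class `ms_typedist`.
#' @export
type_distribution <- function(records, stratum = "ALL",
                              class_bins = TYPE_DISTRIBUTION_BINS) {
  recs <- stratum_records(records, stratum)
  binned <- recs[recs$classification %in% class_bins, , drop = FALSE]
  counts <- table(factor(binned$classification, levels = class_bins))
  total <- sum(counts)
  out <- tibble::tibble(
    stratum = stratum,
    classification = class_bins,
    n = as.integer(counts),
    share = if (total > 0) as.numeric(counts) / total else rep(NA_real_, length(class_bins))
  )
  attr(out, "empty") <- total == 0
  attr(out, "n_excluded") <- nrow(recs) - nrow(binned)
  class(out) <- c("ms_typedist", class(out))
  out
}

#' Per-receptor mutation distribution within a stratum
#'
#' Relative share of ALL mutation records falling on each gene of a
#' receptor set (by default the four Notch receptors), per stratum; sums to
#' 1 whenever any of the genes is mutated in the stratum.
#'
#' @inheritParams type_distribution
#' @param genes Receptor gene symbols.
#' @return Tibble `stratum`, `gene_symbol`, `n`, `share`.
#' @export
receptor_distribution <- function(records, stratum = "ALL",
                                  genes = paste0("NOTCH", 1:4)) {
  recs <- stratum_records(records, stratum)
  hit <- recs[recs$gene_symbol %in% genes, , drop = FALSE]
  counts <- table(factor(hit$gene_symbol, levels = genes))
  total <- sum(counts)
  out <- tibble::tibble(
    stratum = stratum,
    gene_symbol = genes,
    n = as.integer(counts),
    share = if (total > 0) as.numeric(counts) / total else rep(NA_real_, length(genes))
  )
  attr(out, "empty") <- total == 0
  out
}

#' Fraction of cell lines with more than one family mutation
#'
#' Percentage of ALL annotated cell lines in the stratum whose total record
#' count across family members is at least two (two mutations in one member
#' count as much as one in each of two members).
#'
#' @inheritParams family_frequency
#' @return One-row tibble: `unit`, `stratum`, `n_multi_lines`, `n_lines`,
#'   `fraction_pct`.
#' @export
multi_mutation_fraction <- function(records, annotations, family,
                                    stratum = "ALL") {
  fam <- as_family(family)
  ann <- stratum_annotations(annotations, stratum)
  in_family <- records[records$gene_symbol %in% fam$members &
                         records$sample_id %in% ann$sample_id, , drop = FALSE]
  per_line <- table(in_family$sample_id)
  n_multi <- sum(per_line >= 2L)
  tibble::tibble(
    unit = fam$name, stratum = stratum,
    n_multi_lines = as.integer(n_multi), n_lines = nrow(ann),
    fraction_pct = if (nrow(ann) > 0) 100 * n_multi / nrow(ann) else NA_real_
  )
}

#' Frequency table over many families and strata
#'
#' Convenience wrapper mapping [family_frequency()] (and optionally
#' [normalize_by_length()]) over families and strata.
#'
#' @inheritParams family_frequency
#' @param families Named list of [gene_family()] objects or member vectors.
#' @param strata Character vector of strata (`"ALL"` and/or cell types).
#' @param normalize `NULL`, `"per_kbp"` or `"per_10kbp"`; normalization
#'   requires `gene_models`.
#' @return Frequency-entry tibble with one row per family x stratum,
#'   class `ms_freq` (has an [autoplot()] method).
#' @export
frequency_table <- function(records, annotations, families, strata = "ALL",
                            gene_models = NULL, normalize = NULL) {
  fams <- purrr::imap(families, function(f, nm) {
    if (inherits(f, "gene_family")) f else gene_family(nm, f)
  })
  out <- purrr::map(fams, function(fam) {
    purrr::map(strata, function(st) {
      e <- family_frequency(records, annotations, fam, st, gene_models = gene_models)
      if (!is.null(normalize)) {
        e <- normalize_by_length(e, fam, gene_models, scale = normalize)
      }
      e
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  class(out) <- c("ms_freq", class(out))
  out
}

# ---- internal helpers -------------------------------------------------------

as_family <- function(family) {
  if (inherits(family, "gene_family")) return(family)
  members <- as.character(family)
  gene_family(paste(members, collapse = "+"), members)
}

check_family_models <- function(fam, gene_models) {
  if (is.null(gene_models)) return(invisible())
  if (!any(fam$members %in% names(gene_models))) {
    rlang::abort(sprintf("family %s has no member with a known gene model", fam$name))
  }
  invisible()
}

stratum_annotations <- function(annotations, stratum) {
  if (identical(stratum, "ALL")) return(annotations)
  if (!stratum %in% annotations$cell_type) {
    rlang::abort(sprintf("unknown stratum: %s", stratum))
  }
  annotations[annotations$cell_type == stratum, , drop = FALSE]
}

stratum_records <- function(records, stratum) {
  if (identical(stratum, "ALL")) return(records)
  records[!is.na(records$cell_type) & records$cell_type == stratum, , drop = FALSE]
}

freq_entry <- function(unit, stratum, n_mut, n_lines) {
  tibble::tibble(
    unit = unit, stratum = stratum,
    n_mutated_lines = as.integer(n_mut), n_lines = as.integer(n_lines),
    frequency_pct = if (n_lines > 0) 100 * n_mut / n_lines else NA_real_,
    per_kbp_pct = NA_real_
  )
}
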