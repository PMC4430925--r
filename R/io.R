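#' Default MAF-vocabulary classification map
#'
#' Maps common MAF `Variant_Classification` strings (and the pipeline's own
#' canonical labels, which map to themselves) onto the canonical
#' classification set `missense, nonsense, frameshift, inframe_indel,
#' silent, splice, intronic, other`. Strings absent from the map fall back
#' to `other` with a warning, so an unfamiliar vocabulary never aborts a
#' load. Shipped as data so a dialect can override it.
#'
#' @return Named character vector: input string -> canonical classification.
#' @export
default_classification_map <- function() {
  c(
    Missense_Mutation = "missense",
    Nonsense_Mutation = "nonsense",
    Nonstop_Mutation = "other",
    Frame_Shift_Del = "frameshift",
    Frame_Shift_Ins = "frameshift",
    In_Frame_Del = "inframe_indel",
    In_Frame_Ins = "inframe_indel",
    Silent = "silent",
    Splice_Site = "splice",
    Splice_Region = "splice",
    Intron = "intronic",
    IGR = "other",
    `3'UTR` = "other",
    `5'UTR` = "other",
    `5'Flank` = "other",
    `3'Flank` = "other",
    Translation_Start_Site = "other",
    setNames(CLASSIFICATION_LEVELS, CLASSIFICATION_LEVELS)
  )
}

# Column mappings for the two supported dialects.
dialect_columns <- function(dialect) {
  switch(dialect,
    generic_tsv = list(
      gene = "gene_symbol", sample = "sample_id", cell_type = "cell_type",
      classification = "classification", protein_change = "protein_change",
      allelic_fraction = "allelic_fraction",
      required = c("gene_symbol", "sample_id", "classification")
    ),
    ccle_maf = list(
      gene = "Hugo_Symbol", sample = "Tumor_Sample_Barcode", cell_type = NULL,
      classification = "Variant_Classification",
      protein_change = "Protein_Change", allelic_fraction = "Tumor_Alt_Fraction",
      required = c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
    ),
    rlang::abort(sprintf("unknown dialect: %s", dialect))
  )
}

#' Read a MAF-like somatic mutation table
#'
#' Reads a tab-delimited mutation table (one row per mutation call) into the
#' canonical record layout. Two dialects are supported: `"generic_tsv"`
#' (columns `gene_symbol`, `sample_id`, `cell_type`, `classification`,
#' `protein_change`, `allelic_fraction` — the dialect the synthetic
#' generator writes) and `"ccle_maf"` (`Hugo_Symbol`,
#' `Tumor_Sample_Barcode`, `Variant_Classification`, `Protein_Change`, with
#' the cell type taken from the barcode suffix after the first underscore,
#' lower-cased, as in `MCF7_BREAST`).
#'
#' Classification strings are mapped through `class_map`; unmappable values
#' become `other` with a warning. Protein changes are parsed with
#' [parse_protein_change()]; for missense rows the parsed position and
#' residues are required. Rows missing a gene symbol or sample ID are
#' rejected and their count reported.
#'
#' @param path Path to the tab-separated file.
#' @param dialect `"generic_tsv"` (default) or `"ccle_maf"`.
#' @param class_map Named vector mapping classification vocabulary to the
#'   canonical set; defaults to [default_classification_map()].
#' @return A tibble of mutation records with columns `gene_symbol`,
#'   `sample_id`, `cell_type`, `classification`, `protein_position`,
#'   `ref_aa`, `alt_aa`, `allelic_fraction`, `protein_change`.
#' @export
read_mutation_table <- function(path, dialect = c("generic_tsv", "ccle_maf"),
                                class_map = default_classification_map()) {
  dialect <- match.arg(dialect)
  cols <- dialect_columns(dialect)
  if (!file.exists(path)) rlang::abort(sprintf("mutation table not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L && ncol(raw) == 0L) rlang::abort(sprintf("empty mutation table: %s", path))
  missing_cols <- setdiff(cols$required, names(raw))
  if (length(missing_cols)) {
    rlang::abort(sprintf(
      "mutation table %s is missing mandatory column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }

  gene <- raw[[cols$gene]]
  sample <- raw[[cols$sample]]
  keep <- !is.na(gene) & gene != "" & !is.na(sample) & sample != ""
  n_rejected <- sum(!keep)
  if (n_rejected > 0L) {
    rlang::warn(sprintf("rejected %d row(s) missing gene symbol or sample ID", n_rejected))
  }
  raw <- raw[keep, , drop = FALSE]
  gene <- gene[keep]; sample <- sample[keep]

  cls_raw <- raw[[cols$classification]]
  cls <- unname(class_map[cls_raw])
  unmapped <- is.na(cls) & !is.na(cls_raw)
  if (any(unmapped)) {
    rlang::warn(sprintf(
      "%d record(s) with unmappable classification(s) (%s) mapped to 'other'",
      sum(unmapped), paste(unique(cls_raw[unmapped]), collapse = ", ")
    ))
  }
  cls[is.na(cls)] <- "other"

  cell_type <- if (!is.null(cols$cell_type) && cols$cell_type %in% names(raw)) {
    raw[[cols$cell_type]]
  } else if (dialect == "ccle_maf") {
    tolower(stringr::str_remove(sample, "^[^_]*_"))
  } else {
    rep(NA_character_, nrow(raw))
  }

  pchange <- if (!is.null(cols$protein_change) && cols$protein_change %in% names(raw)) {
    dplyr::coalesce(raw[[cols$protein_change]], "")
  } else rep("", nrow(raw))
  parsed <- parse_protein_change(pchange)

  af <- if (!is.null(cols$allelic_fraction) && cols$allelic_fraction %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[cols$allelic_fraction]]))
  } else rep(NA_real_, nrow(raw))

  records <- tibble::tibble(
    gene_symbol = gene,
    sample_id = sample,
    cell_type = cell_type,
    classification = cls,
    protein_position = parsed$protein_position,
    ref_aa = parsed$ref_aa,
    alt_aa = parsed$alt_aa,
    allelic_fraction = af,
    protein_change = pchange
  )
  attr(records, "n_rejected") <- n_rejected
  validate_mutation_records(records)
}

#' Validate mutation records against the record invariants
#'
#' Checks that classifications belong to the canonical set, missense records
#' carry position and both residues, positions are >= 1 and allelic
#' fractions lie in `[0, 1]`.
#'
#' @param records A mutation record tibble.
#' @return `records`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_mutation_records <- function(records) {
  bad_cls <- setdiff(unique(records$classification), CLASSIFICATION_LEVELS)
  if (length(bad_cls)) {
    rlang::abort(sprintf("invalid classification(s): %s", paste(bad_cls, collapse = ", ")))
  }
  mis <- records$classification == "missense"
  incomplete <- mis & (is.na(records$protein_position) |
                         is.na(records$ref_aa) | is.na(records$alt_aa))
  if (any(incomplete)) {
    rlang::abort(sprintf(
      "%d missense record(s) lack protein position or residues (e.g. %s %s)",
      sum(incomplete), records$gene_symbol[which(incomplete)[1]],
      records$sample_id[which(incomplete)[1]]
    ))
  }
  if (any(!is.na(records$protein_position) & records$protein_position < 1L)) {
    rlang::abort("protein_position must be >= 1")
  }
  af <- records$allelic_fraction
  if (any(!is.na(af) & (af < 0 | af > 1))) {
    rlang::abort("allelic_fraction must lie in [0, 1]")
  }
  records
}

#' Write mutation records in the generic TSV dialect
#'
#' Inverse of [read_mutation_table()] for the `generic_tsv` dialect;
#' round-trips every generator-produced record field-for-field.
#'
#' @param records Mutation record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(records, path) {
  pchange <- records$protein_change %||% rep("", nrow(records))
  rebuilt <- hgvsp_string(records)
  use_rebuilt <- (is.na(pchange) | pchange == "") & rebuilt != ""
  pchange[use_rebuilt] <- rebuilt[use_rebuilt]
  out <- tibble::tibble(
    gene_symbol = records$gene_symbol,
    sample_id = records$sample_id,
    cell_type = records$cell_type,
    classification = records$classification,
    protein_change = pchange,
    allelic_fraction = records$allelic_fraction
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# Reconstruct an HGVS-p short string from parsed fields.
hgvsp_string <- function(records) {
  dplyr::case_when(
    records$classification == "missense" ~
      paste0("p.", records$ref_aa, records$protein_position, records$alt_aa),
    records$classification == "nonsense" ~
      paste0("p.", records$ref_aa, records$protein_position, "*"),
    records$classification == "frameshift" ~
      paste0("p.", records$ref_aa, records$protein_position, "fs"),
    records$classification == "inframe_indel" ~
      paste0("p.", records$ref_aa, records$protein_position, "del"),
    records$classification == "silent" & !is.na(records$protein_position) ~
      paste0("p.", records$ref_aa, records$protein_position, records$ref_aa),
    TRUE ~ ""
  )
}

#' Read a sample annotation table
#'
#' @param path TSV with columns `sample_id`, `cell_type` and optionally
#'   `cohort` (defaults to `"cell_line"`).
#' @return Tibble with `sample_id`, `cell_type`, `cohort`.
#' @export
read_sample_annotations <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("annotation table not found: %s", path))
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(c("sample_id", "cell_type"), names(ann))
  if (length(missing_cols)) {
    rlang::abort(sprintf(
      "annotation table missing column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"cohort" %in% names(ann)) ann$cohort <- "cell_line"
  if (anyDuplicated(ann[c("sample_id", "cohort")])) {
    rlang::abort("duplicate sample_id within a cohort in annotation table")
  }
  if (any(is.na(ann$cell_type) | ann$cell_type == "")) {
    rlang::abort("annotation table has empty cell_type values")
  }
  tibble::as_tibble(ann[c("sample_id", "cell_type", "cohort")])
}

#' Read a discrete (GISTIC-style) copy-number table
#'
#' Accepts either long form (columns `gene_symbol`, `sample_id`,
#' `gistic_call`) or wide form (first column the gene symbol, remaining
#' columns one per sample). Every call must be an integer in
#' `{-2, -1, 0, 1, 2}`; anything else is a hard error naming the offending
#' gene and sample.
#'
#' @param path Path to the TSV.
#' @return Long-form tibble with `gene_symbol`, `sample_id`, `gistic_call`.
#' @export
read_cna_table <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("CNA table not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  long <- if (all(c("gene_symbol", "sample_id", "gistic_call") %in% names(raw))) {
    tibble::tibble(
      gene_symbol = raw$gene_symbol,
      sample_id = raw$sample_id,
      call_chr = raw$gistic_call
    )
  } else {
    gene_col <- names(raw)[1]
    tidyr::pivot_longer(raw, -dplyr::all_of(gene_col),
                        names_to = "sample_id", values_to = "call_chr") |>
      dplyr::rename(gene_symbol = dplyr::all_of(gene_col))
  }
  calls <- suppressWarnings(as.numeric(long$call_chr))
  bad <- is.na(calls) | calls != round(calls) | calls < -2 | calls > 2
  if (any(bad)) {
    i <- which(bad)[1]
    rlang::abort(sprintf(
      "invalid GISTIC call '%s' for gene %s, sample %s (must be integer in -2..2)",
      long$call_chr[i], long$gene_symbol[i], long$sample_id[i]
    ))
  }
  tibble::tibble(
    gene_symbol = long$gene_symbol,
    sample_id = long$sample_id,
    gistic_call = as.integer(calls)
  )
}
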