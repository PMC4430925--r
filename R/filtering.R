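#' Record-level filter cascade for hybrid-capture mutation calls
#'
#' Applies, in order, the record-level filters used before any frequency is
#' computed: (1) non-coding records (classification `intronic`, or a
#' coding-required classification without a protein position); (2) silent
#' (synonymous) records; (3) records whose allelic fraction is present and
#' below the floor; (4) NOTCH4 records falling inside the configured exon-1
#' repeat-polymorphism window (the (CTG)n polyleucine tract, excluded
#' because it is a common polymorphism rather than a somatic event);
#' (5) optionally splice records (kept by default). Every step is reported
#' with its in/out counts, so injected decoys are auditable. The cascade is
#' idempotent and total: unknown classifications pass through.
#'
#' @param records Mutation record tibble (see [read_mutation_table()]).
#' @param af_floor Allelic-fraction floor; records with a fraction present
#'   and strictly below it are removed. Default 0.10, matching the upstream
#'   hybrid-capture filter, so re-application on compliant input is a no-op.
#' @param notch4_window Closed aa interval `c(start, end)` of the exon-1
#'   repeat window; default `c(1, 60)` covers the N-terminal leucine tract.
#' @param notch4_gene Gene symbol the window applies to.
#' @param drop_splice Drop splice records as a filter step? Default `FALSE`
#'   (they are retained and counted outside the four-class distributions).
#' @return A list of class `filter_result`: `records` (survivors), `report`
#'   (tibble `filter_name`, `records_in`, `records_out`) and
#'   `samples_removed` (empty here; populated by
#'   [relabel_and_threshold_cell_types()]).
#' @export
filter_records <- function(records, af_floor = 0.10,
                           notch4_window = c(1L, 60L),
                           notch4_gene = "NOTCH4",
                           drop_splice = FALSE) {
  steps <- list()
  step <- function(name, keep) {
    n_in <- nrow(records)
    records <<- records[keep, , drop = FALSE]
    steps[[length(steps) + 1L]] <<- tibble::tibble(
      filter_name = name, records_in = n_in, records_out = nrow(records)
    )
  }

  step("noncoding", !(records$classification == "intronic" |
    (records$classification %in% CODING_REQUIRED_CLASSES &
       is.na(records$protein_position))))
  step("silent", records$classification != "silent")
  step("low_allelic_fraction",
       is.na(records$allelic_fraction) | records$allelic_fraction >= af_floor)
  step("notch4_repeat_window", !(records$gene_symbol == notch4_gene &
    !is.na(records$protein_position) &
    records$protein_position >= notch4_window[1] &
    records$protein_position <= notch4_window[2]))
  if (drop_splice) step("splice", records$classification != "splice")

  structure(
    list(
      records = records,
      report = purrr::list_rbind(steps),
      samples_removed = tibble::tibble(cell_type = character(), n_samples = integer())
    ),
    class = "filter_result"
  )
}

#' Relabel cell types and drop under-represented strata
#'
#' Rewrites cell-type labels per a relabeling map (by default the panel
#' barcodes `haematopoietic_and_lymphoid_tissue` -> `blood` and `skin` ->
#' `melanoma`), then drops every cell type annotated with fewer than
#' `min_lines` cell lines, removing those samples' mutation records. The
#' threshold counts annotated cell lines, not mutated lines and not
#' mutation records.
#'
#' @param records Mutation record tibble; every `sample_id` must appear in
#'   `annotations` (a record with an unknown sample is a hard error listing
#'   the offenders).
#' @param annotations Sample annotation tibble (`sample_id`, `cell_type`,
#'   `cohort`).
#' @param min_lines Minimum number of cell lines per retained cell type.
#' @param relabel_map Named character vector `old_label -> new_label`; an
#'   empty map leaves labels unchanged.
#' @return A list of class `filter_result` with relabeled, thresholded
#'   `records` and `annotations`, the step `report`, and `samples_removed`
#'   (tibble `cell_type`, `n_samples` of dropped strata, post-relabeling).
#' @export
relabel_and_threshold_cell_types <- function(records, annotations,
                                             min_lines = 5L,
                                             relabel_map = default_relabel_map()) {
  unknown <- setdiff(unique(records$sample_id), annotations$sample_id)
  if (length(unknown)) {
    rlang::abort(sprintf(
      "record sample ID(s) absent from annotations: %s",
      paste(head(unknown, 10L), collapse = ", ")
    ))
  }
  relabel <- function(x) {
    hit <- x %in% names(relabel_map)
    x[hit] <- unname(relabel_map[x[hit]])
    x
  }
  annotations <- dplyr::mutate(annotations, cell_type = relabel(.data$cell_type))
  # records take their (relabeled) type from the annotation table
  records <- records |>
    dplyr::select(-dplyr::any_of("cell_type")) |>
    dplyr::left_join(annotations[c("sample_id", "cell_type")], by = "sample_id") |>
    dplyr::relocate("cell_type", .after = "sample_id")

  type_counts <- dplyr::count(annotations, .data$cell_type, name = "n_samples")
  dropped <- dplyr::filter(type_counts, .data$n_samples < min_lines)
  keep_types <- setdiff(type_counts$cell_type, dropped$cell_type)

  n_in <- nrow(records)
  annotations <- dplyr::filter(annotations, .data$cell_type %in% keep_types)
  records <- dplyr::filter(records, .data$cell_type %in% keep_types)

  structure(
    list(
      records = records,
      annotations = annotations,
      report = tibble::tibble(
        filter_name = "small_cell_types",
        records_in = n_in, records_out = nrow(records)
      ),
      samples_removed = dplyr::mutate(dropped, n_samples = as.integer(.data$n_samples))
    ),
    class = "filter_result"
  )
}

#' Default cell-type relabeling map
#' @return Named character vector used by [relabel_and_threshold_cell_types()].
#' @export
default_relabel_map <- function() {
  c(haematopoietic_and_lymphoid_tissue = "blood", skin = "melanoma")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result>\n")
  print(x$report)
  if (nrow(x$samples_removed)) {
    cat("samples removed:\n")
    print(x$samples_removed)
  }
  invisible(x)
}

#' @describeIn filter_records Tidy method: the per-step filter report.
#' @param x A `filter_result`.
#' @param ... Unused.
#' @export
tidy.filter_result <- function(x, ...) x$report

#' @describeIn filter_records Glance method: one-row summary of the cascade.
#' @export
glance.filter_result <- function(x, ...) {
  tibble::tibble(
    records_in = if (nrow(x$report)) x$report$records_in[1] else 0L,
    records_out = if (nrow(x$report)) x$report$records_out[nrow(x$report)] else 0L,
    n_steps = nrow(x$report),
    n_cell_types_removed = nrow(x$samples_removed),
    n_samples_removed = sum(x$samples_removed$n_samples)
  )
}

#' Combine sequential filter results into one audit report
#'
#' @param ... `filter_result` objects in application order.
#' @return A tibble chaining the step reports; consecutive steps satisfy
#'   `records_in[k] == records_out[k-1]`.
#' @export
combine_filter_reports <- function(...) {
  purrr::list_rbind(purrr::map(list(...), "report"))
}
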