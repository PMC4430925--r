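#' Classify missense mutations as deleterious from subPSEC-style scores
#'
#' subPSEC (substitution position-specific evolutionary conservation)
#' scores estimate the likelihood that a missense substitution impairs
#' protein function, on a scale from 0 (neutral) to -10 (most likely
#' deleterious); scores strictly below -3 are conventionally taken as
#' functionally significant. Scoring itself is external (e.g. PANTHER
#' cSNP); this function consumes pre-computed scores attached to missense
#' records and applies the strict-threshold rule, so a score of exactly -3
#' is NOT deleterious.
#'
#' @param scored Tibble of missense records with a numeric `subpsec`
#'   column in `[-10, 0]`. A non-missense record or out-of-range score is
#'   a hard error.
#' @param threshold Deleteriousness cutoff; default -3.
#' @return `scored` with a logical `deleterious` column
#'   (`subpsec < threshold`).
#' @export
classify_impact <- function(scored, threshold = -3) {
  if (!"subpsec" %in% names(scored)) rlang::abort("scored records need a 'subpsec' column")
  if ("classification" %in% names(scored) &&
      any(scored$classification != "missense")) {
    rlang::abort("classify_impact only accepts missense records")
  }
  s <- scored$subpsec
  if (any(is.na(s)) || any(s < -10 | s > 0)) {
    rlang::abort("subPSEC scores must lie in [-10, 0]")
  }
  scored$deleterious <- s < threshold
  scored
}

#' Deleterious fraction of scored missense mutations
#'
#' @param impacts Output of [classify_impact()].
#' @return One-row tibble: `n_deleterious`, `n_scored`, `fraction_pct`.
#' @export
deleterious_fraction <- function(impacts) {
  n <- nrow(impacts)
  k <- sum(impacts$deleterious)
  tibble::tibble(
    n_deleterious = as.integer(k), n_scored = as.integer(n),
    fraction_pct = if (n > 0) 100 * k / n else NA_real_
  )
}

#' Where do deleterious mutations cluster? Per-domain summary
#'
#' Counts scored and deleterious missense mutations per protein domain
#' (including zero-count domains and the interdomain stretch) for each
#' gene with a model, so clustering — e.g. in the ankyrin repeats or
#' individual EGF repeats — is directly visible. Counts are conserved:
#' summing `n_deleterious` over a gene's rows gives its total.
#'
#' @param impacts Output of [classify_impact()] with `gene_symbol` and
#'   `protein_position` columns.
#' @param gene_models `gene_model_set`.
#' @return Tibble `gene_symbol`, `domain`, `n_deleterious`, `n_scored`.
#' @export
deleterious_domain_summary <- function(impacts, gene_models) {
  genes <- intersect(unique(impacts$gene_symbol), names(gene_models))
  purrr::map(genes, function(g) {
    gm <- gene_models[[g]]
    recs <- impacts[impacts$gene_symbol == g, , drop = FALSE]
    recs$domain <- assign_domain(recs$protein_position, gm)
    levels <- c(gm$domains$name, "interdomain", "unassigned")
    counts <- recs |>
      dplyr::count(domain = factor(.data$domain, levels = levels),
                   .data$deleterious, .drop = FALSE) |>
      tidyr::pivot_wider(names_from = "deleterious", values_from = "n",
                         values_fill = 0L)
    tibble::tibble(
      gene_symbol = g,
      domain = as.character(counts$domain),
      n_deleterious = as.integer(counts[["TRUE"]] %||% rep(0L, nrow(counts))),
      n_scored = as.integer((counts[["TRUE"]] %||% 0L) + (counts[["FALSE"]] %||% 0L))
    )
  }) |> purrr::list_rbind()
}

#' High-level copy-number alteration frequencies
#'
#' Per-gene percentages of samples with a high-level amplification
#' (GISTIC call +2) or deep deletion (call -2); single-copy gains/losses
#' (±1) are ignored. The denominator is the number of distinct samples in
#' the table. A requested gene absent from the table yields a flagged row
#' with `n_samples = 0` and `NA` percentages, not an error.
#'
#' @param cna_records Long-form CNA tibble from [read_cna_table()].
#' @param genes Gene symbols to summarize.
#' @return Tibble `gene_symbol`, `n_samples`, `amplified_pct`,
#'   `deleted_pct`, `missing` (class `ms_cna`).
#' @export
cna_frequencies <- function(cna_records, genes) {
  n_samples <- dplyr::n_distinct(cna_records$sample_id)
  out <- purrr::map(genes, function(g) {
    calls <- cna_records$gistic_call[cna_records$gene_symbol == g]
    if (length(calls) == 0L) {
      return(tibble::tibble(
        gene_symbol = g, n_samples = 0L,
        amplified_pct = NA_real_, deleted_pct = NA_real_, missing = TRUE
      ))
    }
    tibble::tibble(
      gene_symbol = g, n_samples = as.integer(n_samples),
      amplified_pct = 100 * sum(calls == 2L) / n_samples,
      deleted_pct = 100 * sum(calls == -2L) / n_samples,
      missing = FALSE
    )
  }) |> purrr::list_rbind()
  class(out) <- c("ms_cna", class(out))
  out
}

#' Deterministic mock subPSEC scorer (synthetic)
#'
#' A stand-in scorer for tests and examples only: it is NOT an impact
#' predictor. Each (gene, position, ref, alt) tuple is hashed to a
#' reproducible score in `[-10, 0]`; `deleterious_mass` tunes the fraction
#' of scores falling below -3. Real analyses should attach PANTHER cSNP
#' (or comparable) scores via the scored-records interface of
#' [classify_impact()].
#'
#' @param records Missense mutation records.
#' @param deleterious_mass Approximate fraction of scores below -3.
#' @return `records` with a `subpsec` column.
#' @export
mock_subpsec_scores <- function(records, deleterious_mass = 0.22) {
  key <- paste(records$gene_symbol, records$protein_position,
               records$ref_aa, records$alt_aa)
  u <- purrr::map_dbl(key, function(k) {
    h <- 7
    for (c in utf8ToInt(k)) h <- (h * 131 + c) %% 2147483647
    h / 2147483646
  })
  # u uniform-ish on [0,1]; map the lowest 'deleterious_mass' of it below -3
  scores <- ifelse(
    u < deleterious_mass,
    -3 - 7 * (deleterious_mass - u) / max(deleterious_mass, 1e-9),
    -3 * (1 - (u - deleterious_mass) / max(1 - deleterious_mass, 1e-9))
  )
  records$subpsec <- pmax(pmin(scores, 0), -10)
  records
}
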