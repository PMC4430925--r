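#' Assign protein positions to domains
#'
#' Maps 1-based amino-acid positions onto a gene model's domain intervals
#' (closed on both ends; a boundary residue belongs to its domain). A
#' position outside every domain is `"interdomain"`; an `NA` position is
#' `"unassigned"`. Domains are non-overlapping by construction, so every
#' in-range position gets exactly one label. A position beyond the protein
#' length is a hard error — it signals a model/data mismatch.
#'
#' @param position Integer vector of aa positions (`NA` allowed).
#' @param gene_model A [gene_model()].
#' @return Character vector of domain names.
#' @export
assign_domain <- function(position, gene_model) {
  position <- as.integer(position)
  over <- !is.na(position) & position > gene_model$protein_length_aa
  if (any(over)) {
    rlang::abort(sprintf(
      "position %d beyond %s protein length (%d aa): gene model / data mismatch",
      position[which(over)[1]], gene_model$gene_symbol,
      gene_model$protein_length_aa
    ))
  }
  under <- !is.na(position) & position < 1L
  if (any(under)) rlang::abort("positions must be >= 1")

  dom <- gene_model$domains
  out <- ifelse(is.na(position), "unassigned", "interdomain")
  if (nrow(dom)) {
    idx <- findInterval(position, dom$start_aa)
    inside <- !is.na(position) & idx >= 1L & position <= dom$end_aa[pmax(idx, 1L)]
    out[inside] <- dom$name[idx[inside]]
  }
  out
}

#' Annotate mutation records with their protein domain
#'
#' @param records Mutation record tibble.
#' @param gene_models `gene_model_set`; records of genes without a model
#'   get domain `"unassigned"`.
#' @return `records` with a `domain` column appended.
#' @export
map_domains <- function(records, gene_models) {
  records$domain <- "unassigned"
  for (g in intersect(unique(records$gene_symbol), names(gene_models))) {
    i <- records$gene_symbol == g
    records$domain[i] <- assign_domain(records$protein_position[i], gene_models[[g]])
  }
  records
}

# Expand region shorthands against a gene model's domain names:
# "EGF" -> all EGF-prefixed repeats, "NRR" -> LNR + HD.
expand_region <- function(region, gene_model) {
  nm <- gene_model$domains$name
  out <- character()
  for (r in region) {
    if (r %in% nm) {
      out <- c(out, r)
    } else if (r == "EGF") {
      hits <- nm[stringr::str_detect(nm, "^EGF(_|$)")]
      if (!length(hits)) {
        rlang::abort(sprintf("no EGF domains in %s gene model", gene_model$gene_symbol))
      }
      out <- c(out, hits)
    } else if (r == "NRR") {
      if (!all(c("LNR", "HD") %in% nm)) {
        rlang::abort(sprintf("NRR needs LNR and HD domains in %s gene model",
                             gene_model$gene_symbol))
      }
      out <- c(out, "LNR", "HD")
    } else if (r == "interdomain") {
      out <- c(out, "interdomain")
    } else {
      rlang::abort(sprintf("unknown region/domain name '%s' for %s",
                           r, gene_model$gene_symbol))
    }
  }
  unique(out)
}

#' Fraction of a gene's mutations falling in a protein region
#'
#' Percentage of positioned mutation records of one gene whose assigned
#' domain lies in the named region. Region names are domain names of the
#' gene model plus two shorthands: `"EGF"` (union of all `EGF`-prefixed
#' repeats) and `"NRR"` (the negative regulatory region, the union of the
#' LNR repeats and the heterodimerization domain). Records without a
#' protein position are excluded from the denominator; their count is
#' available as the `n_unpositioned` attribute.
#'
#' @param records Mutation records (all genes; filtered internally).
#' @param gene Gene symbol.
#' @param gene_models `gene_model_set` containing `gene`.
#' @param region Character vector of region/domain names; an empty vector
#'   yields 0.
#' @return Percentage in `[0, 100]` (`NA` if the gene has no positioned
#'   records), with attributes `n_region`, `n_positioned`,
#'   `n_unpositioned`.
#' @export
region_fraction <- function(records, gene, gene_models, region) {
  if (!gene %in% names(gene_models)) {
    rlang::abort(sprintf("no gene model for %s", gene))
  }
  gm <- gene_models[[gene]]
  recs <- records[records$gene_symbol == gene, , drop = FALSE]
  positioned <- recs[!is.na(recs$protein_position), , drop = FALSE]
  doms <- assign_domain(positioned$protein_position, gm)
  wanted <- if (length(region)) expand_region(region, gm) else character()
  n_region <- sum(doms %in% wanted)
  n_pos <- nrow(positioned)
  out <- if (n_pos > 0) 100 * n_region / n_pos else NA_real_
  attr(out, "n_region") <- n_region
  attr(out, "n_positioned") <- n_pos
  attr(out, "n_unpositioned") <- nrow(recs) - n_pos
  out
}

#' Scan a region for cysteine-gain/loss missense mutations
#'
#' Cysteine-affecting missense mutations in the EGF repeats are the
#' hallmark of CADASIL alleles of NOTCH3; this scan finds, among a gene's
#' missense records inside a region, those where the reference residue is
#' cysteine (loss) or the alternate residue is cysteine (gain).
#'
#' @inheritParams region_fraction
#' @param region Region names, default `"EGF"`.
#' @return Tibble of hits: the record columns plus `domain` and `change`
#'   (`"gain"` or `"loss"`); zero rows when no cysteine is touched.
#' @export
cysteine_change_scan <- function(records, gene, gene_models, region = "EGF") {
  gm <- gene_models[[gene]]
  if (is.null(gm)) rlang::abort(sprintf("no gene model for %s", gene))
  recs <- records[records$gene_symbol == gene &
                    records$classification == "missense" &
                    !is.na(records$protein_position), , drop = FALSE]
  if (nrow(recs) == 0L) {
    return(dplyr::mutate(recs, domain = character(), change = character()))
  }
  recs$domain <- assign_domain(recs$protein_position, gm)
  wanted <- expand_region(region, gm)
  recs <- recs[recs$domain %in% wanted, , drop = FALSE]
  recs$change <- dplyr::case_when(
    recs$ref_aa == "C" ~ "loss",
    recs$alt_aa == "C" ~ "gain",
    TRUE ~ NA_character_
  )
  recs[!is.na(recs$change), , drop = FALSE]
}

#' Scan for recurrent-position mutation hotspots
#'
#' Groups positioned records by gene and amino-acid position (and, by
#' default, classification) and reports groups reaching the minimum
#' recurrence, sorted by count descending, then gene, then position — a
#' deterministic ranking.
#'
#' @param records Mutation record tibble.
#' @param min_count Minimum records per hotspot (default 3).
#' @param same_class Require identical classification within a hotspot?
#' @return Tibble `gene_symbol`, `protein_position`, `classification`
#'   (`NA` when `same_class = FALSE`), `n_records`.
#' @export
hotspot_scan <- function(records, min_count = 3L, same_class = TRUE) {
  recs <- records[!is.na(records$protein_position), , drop = FALSE]
  keys <- if (same_class) {
    c("gene_symbol", "protein_position", "classification")
  } else {
    c("gene_symbol", "protein_position")
  }
  out <- recs |>
    dplyr::count(dplyr::across(dplyr::all_of(keys)), name = "n_records") |>
    dplyr::filter(.data$n_records >= min_count) |>
    dplyr::arrange(dplyr::desc(.data$n_records), .data$gene_symbol,
                   .data$protein_position)
  if (!same_class) out$classification <- NA_character_
  dplyr::relocate(out, "gene_symbol", "protein_position", "classification",
                  "n_records")
}
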