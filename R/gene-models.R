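#' Construct a gene model
#'
#' A gene model records, for one gene, the coding-sequence length of the
#' chosen transcript, the protein length, and an ordered list of protein
#' domains as closed 1-based amino-acid intervals. Domains must lie within
#' `[1, protein_length_aa]`, be sorted by start and be non-overlapping; a
#' boundary residue belongs to its domain.
#'
#' @param gene_symbol HGNC-style gene symbol.
#' @param cds_length_bp Coding-sequence length in base pairs (>= 3).
#' @param protein_length_aa Protein length in amino acids (>= 1).
#' @param domains A data frame with columns `name`, `start_aa`, `end_aa`
#'   (closed intervals), or `NULL` for a gene with no annotated domains.
#' @return An object of class `gene_model`.
#' @examples
#' gene_model("NOTCH1", 7668, 2555,
#'   data.frame(name = "PEST", start_aa = 2480, end_aa = 2555))
#' @export
gene_model <- function(gene_symbol, cds_length_bp, protein_length_aa,
                       domains = NULL) {
  stopifnot(is.character(gene_symbol), length(gene_symbol) == 1L)
  cds_length_bp <- as.numeric(cds_length_bp)
  protein_length_aa <- as.integer(protein_length_aa)
  if (is.na(cds_length_bp) || cds_length_bp < 3)
    rlang::abort(sprintf("gene %s: cds_length_bp must be >= 3", gene_symbol))
  if (is.na(protein_length_aa) || protein_length_aa < 1L)
    rlang::abort(sprintf("gene %s: protein_length_aa must be >= 1", gene_symbol))

  if (is.null(domains) || nrow(as.data.frame(domains)) == 0L) {
    domains <- tibble::tibble(
      name = character(), start_aa = integer(), end_aa = integer()
    )
  } else {
    domains <- tibble::as_tibble(domains)
    stopifnot(all(c("name", "start_aa", "end_aa") %in% names(domains)))
    domains <- domains |>
      dplyr::mutate(
        name = as.character(.data$name),
        start_aa = as.integer(.data$start_aa),
        end_aa = as.integer(.data$end_aa)
      ) |>
      dplyr::arrange(.data$start_aa)
    bad <- domains$start_aa > domains$end_aa |
      domains$start_aa < 1L | domains$end_aa > protein_length_aa
    if (any(bad)) {
      rlang::abort(sprintf(
        "gene %s: domain(s) %s out of range or inverted (protein length %d aa)",
        gene_symbol, paste(domains$name[bad], collapse = ", "),
        protein_length_aa
      ))
    }
    if (nrow(domains) > 1L) {
      overlap <- domains$start_aa[-1L] <= domains$end_aa[-nrow(domains)]
      if (any(overlap)) {
        rlang::abort(sprintf(
          "gene %s: overlapping domains %s and %s",
          gene_symbol,
          domains$name[which(overlap)[1L]],
          domains$name[which(overlap)[1L] + 1L]
        ))
      }
    }
  }

  structure(
    list(
      gene_symbol = gene_symbol,
      cds_length_bp = cds_length_bp,
      protein_length_aa = protein_length_aa,
      domains = domains
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s: %d aa, CDS %g bp, %d domain(s)\n",
    x$gene_symbol, x$protein_length_aa, x$cds_length_bp, nrow(x$domains)
  ))
  invisible(x)
}

#' @describeIn gene_model Tidy a gene model into its domain table.
#' @param x A `gene_model`.
#' @param ... Unused.
#' @export
tidy.gene_model <- function(x, ...) {
  dplyr::mutate(x$domains, gene_symbol = x$gene_symbol, .before = 1L)
}

#' Read gene models from a YAML config
#'
#' The config maps each gene symbol to its CDS length, protein length and an
#' optional ordered domain list. Two layouts are accepted: a mapping
#' `gene: {cds_length_bp:, protein_length_aa:, domains: [...]}` or a list of
#' entries each carrying a `gene` field. All gene-model invariants are
#' validated at load; a duplicated gene, an overlapping domain or a domain
#' extending past the protein end is a hard error naming the offender.
#'
#' @param path Path to the YAML file. The package ships a default at
#'   `system.file("extdata", "gene_models.yaml", package = "mutscape")`
#'   covering the four Notch receptors (with domain annotations), their
#'   ligands and a set of comparator genes; its domain boundaries are
#'   approximate canonical-transcript annotations, documented in the file.
#' @return A named list of [gene_model()] objects (class `gene_model_set`).
#' @export
read_gene_models <- function(path = default_gene_models_path()) {
  if (!file.exists(path)) rlang::abort(sprintf("gene model config not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$genes)) raw <- raw$genes
  if (is.null(names(raw))) {
    syms <- purrr::map_chr(raw, function(e) e$gene %||% e$gene_symbol %||% NA_character_)
    if (anyNA(syms)) rlang::abort("list-form gene model config requires a 'gene' field per entry")
    if (anyDuplicated(syms)) {
      rlang::abort(sprintf(
        "duplicate gene in gene model config: %s",
        paste(unique(syms[duplicated(syms)]), collapse = ", ")
      ))
    }
    raw <- setNames(raw, syms)
  }
  models <- purrr::imap(raw, function(entry, sym) {
    dom <- entry$domains
    if (!is.null(dom) && length(dom)) {
      dom <- purrr::map(dom, function(d) {
        tibble::tibble(
          name = as.character(d$name),
          start_aa = as.integer(d$start %||% d$start_aa),
          end_aa = as.integer(d$end %||% d$end_aa)
        )
      }) |> purrr::list_rbind()
    }
    gene_model(sym, entry$cds_length_bp, entry$protein_length_aa, dom)
  })
  structure(models, class = "gene_model_set")
}

#' Path to the shipped default gene-model config
#' @return File path of the packaged YAML config.
#' @export
default_gene_models_path <- function() {
  system.file("extdata", "gene_models.yaml", package = "mutscape")
}

#' Summarize a set of gene models as a table
#'
#' @param models A `gene_model_set` (named list of [gene_model()]).
#' @return A tibble with one row per gene: symbol, CDS length, protein
#'   length and domain count.
#' @export
gene_model_table <- function(models) {
  purrr::map(models, function(m) {
    tibble::tibble(
      gene_symbol = m$gene_symbol,
      cds_length_bp = m$cds_length_bp,
      protein_length_aa = m$protein_length_aa,
      n_domains = nrow(m$domains)
    )
  }) |> purrr::list_rbind()
}

#' Define a gene family
#'
#' A gene family is a named, non-empty set of gene symbols analysed as one
#' unit: a cell line counts as mutated in the family if it carries at least
#' one mutation in any member, and is counted at most once. The family's
#' average CDS length (the arithmetic mean of its members' coding-sequence
#' lengths) is computed from gene models on demand, never stored.
#'
#' @param name Family name (e.g. `"NOTCH"`).
#' @param members Character vector of unique member gene symbols.
#' @return An object of class `gene_family`.
#' @examples
#' gene_family("NOTCH", c("NOTCH1", "NOTCH2", "NOTCH3", "NOTCH4"))
#' @export
gene_family <- function(name, members) {
  members <- as.character(members)
  if (length(members) == 0L) rlang::abort("a gene family needs at least one member")
  if (anyDuplicated(members)) rlang::abort(sprintf("family %s: duplicate members", name))
  structure(list(name = name, members = members), class = "gene_family")
}

#' Average coding-sequence length of a gene family
#'
#' @param family A [gene_family()] or character vector of gene symbols.
#' @param models A `gene_model_set` containing every member.
#' @return The arithmetic mean of the members' `cds_length_bp`, in bp.
#' @export
avg_cds_length <- function(family, models) {
  members <- if (inherits(family, "gene_family")) family$members else as.character(family)
  missing <- setdiff(members, names(models))
  if (length(missing)) {
    rlang::abort(sprintf(
      "no gene model for family member(s): %s", paste(missing, collapse = ", ")
    ))
  }
  mean(purrr::map_dbl(models[members], "cds_length_bp"))
}
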