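#' Default gene-family definitions
#'
#' The analysis units of the standard run: the four Notch receptors as one
#' family, the four canonical ligands, the three RAS genes, the four ERBB
#' receptors, the two Patched genes, the single-gene units TP53 and APC,
#' and three housekeeping control genes.
#'
#' @return Named list of member-symbol vectors.
#' @export
default_families <- function() {
  list(
    NOTCH = paste0("NOTCH", 1:4),
    NOTCH_LIGANDS = c("JAG1", "JAG2", "DLL1", "DLL4"),
    RAS = c("HRAS", "KRAS", "NRAS"),
    ERBB = c("EGFR", "ERBB2", "ERBB3", "ERBB4"),
    PTCH = c("PTCH1", "PTCH2"),
    TP53 = "TP53",
    APC = "APC",
    PABPN1 = "PABPN1",
    FPGT = "FPGT",
    NONO = "NONO"
  )
}

default_run_config <- function() {
  list(
    dialect = "generic_tsv",
    gene_models = default_gene_models_path(),
    families = default_families(),
    receptor_genes = paste0("NOTCH", 1:4),
    filters = list(af_floor = 0.10, min_lines = 5L,
                   notch4_window = c(1L, 60L), drop_splice = FALSE),
    thresholds = list(subpsec = -3, hotspot_min = 3L),
    seed = 1L
  )
}

#' Run the full mutation-landscape pipeline
#'
#' Orchestrates filtering, frequency analysis, domain mapping, impact /
#' copy-number summaries (when their inputs are configured) and the
#' cell-line versus primary-tumor comparison (when a tumor cohort is
#' configured), writing every stage's TSV plus a YAML manifest with input
#' checksums, the effective config, the filter report and per-stage
#' status. Any stage error aborts with the stage name.
#'
#' @param config A named list or the path to a YAML file. Recognized
#'   fields: `mutations`, `annotations` (paths, required), `dialect`,
#'   `gene_models`, `cna`, `scored_impact`, `tumor_mutations`,
#'   `tumor_annotations`, `pairing`, `families` (named list of member
#'   vectors), `receptor_genes`, `filters` (`af_floor`, `min_lines`,
#'   `notch4_window`, `drop_splice`, `relabel`), `thresholds` (`subpsec`,
#'   `hotspot_min`), `outdir`, `seed`.
#' @param outdir Output directory; overrides `config$outdir`.
#' @return Invisibly, a list of class `mutscape_run`: `tables` (the result
#'   tibbles), `files` (written paths), `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) rlang::abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(default_run_config(), config)
  cfg$outdir <- outdir %||% cfg$outdir
  if (is.null(cfg$outdir)) rlang::abort("config needs an output directory (outdir)")
  if (is.null(cfg$mutations) || is.null(cfg$annotations)) {
    rlang::abort("config needs 'mutations' and 'annotations' paths")
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stage_status <- list()
  tables <- list()
  files <- character()
  emit <- function(tbl, name) {
    path <- file.path(cfg$outdir, paste0(name, ".tsv"))
    out <- dplyr::mutate(
      as.data.frame(tbl),
      dplyr::across(dplyr::where(is.numeric), function(x) round(x, 6))
    )
    readr::write_tsv(out, path, progress = FALSE)
    tables[[name]] <<- tibble::as_tibble(tbl)
    files[name] <<- path
    invisible(path)
  }
  run_stage <- function(name, code) {
    tryCatch({
      force(code)
      stage_status[[name]] <<- "ok"
    }, error = function(e) {
      stage_status[[name]] <<- conditionMessage(e)
      rlang::abort(sprintf("stage %s failed: %s", name, conditionMessage(e)))
    })
  }

  models <- read_gene_models(cfg$gene_models)
  relabel <- if (!is.null(cfg$filters$relabel)) {
    unlist(cfg$filters$relabel)
  } else default_relabel_map()

  # ---- filtering ----
  records <- NULL; annotations <- NULL; filter_report <- NULL
  run_stage("filtering", {
    raw <- read_mutation_table(cfg$mutations, dialect = cfg$dialect)
    ann <- read_sample_annotations(cfg$annotations)
    f1 <- filter_records(raw, af_floor = cfg$filters$af_floor,
                         notch4_window = unlist(cfg$filters$notch4_window),
                         drop_splice = isTRUE(cfg$filters$drop_splice))
    f2 <- relabel_and_threshold_cell_types(f1$records, ann,
                                           min_lines = cfg$filters$min_lines,
                                           relabel_map = relabel)
    records <- f2$records
    annotations <- f2$annotations
    filter_report <- combine_filter_reports(f1, f2)
    emit(filter_report, "filter_report")
    emit(f2$samples_removed, "cell_types_removed")
  })

  receptor_genes <- cfg$receptor_genes
  receptor_records <- records[records$gene_symbol %in% receptor_genes, , drop = FALSE]
  cell_types <- sort(unique(annotations$cell_type))

  # ---- frequency analysis ----
  run_stage("frequency_analysis", {
    overall <- frequency_table(records, annotations, cfg$families,
                               strata = "ALL", gene_models = models,
                               normalize = "per_kbp")
    per_gene <- purrr::map(
      intersect(c(receptor_genes, cfg$families$NOTCH_LIGANDS), names(models)),
      function(g) {
        e <- gene_frequency(records, annotations, g)
        normalize_by_length(e, g, models, scale = "per_kbp")
      }
    ) |> purrr::list_rbind()
    emit(dplyr::bind_rows(overall, per_gene), "frequencies_overall")

    by_type <- frequency_table(records, annotations, cfg$families,
                               strata = cell_types, gene_models = models)
    emit(by_type, "frequencies_by_celltype")

    emit(purrr::map(c("ALL", cell_types), function(st) {
      type_distribution(receptor_records, st)
    }) |> purrr::list_rbind(), "type_distribution")

    emit(purrr::map(c("ALL", cell_types), function(st) {
      receptor_distribution(receptor_records, st, genes = receptor_genes)
    }) |> purrr::list_rbind(), "receptor_distribution")

    emit(multi_mutation_fraction(records, annotations,
                                 gene_family("NOTCH", receptor_genes)),
         "multi_mutation")
  })

  # ---- domain mapping ----
  run_stage("domain_mapping", {
    mapped <- map_domains(receptor_records, models)
    emit(mapped[!is.na(mapped$protein_position),
                c("gene_symbol", "sample_id", "cell_type", "classification",
                  "protein_position", "domain")] |>
           dplyr::arrange(.data$gene_symbol, .data$protein_position),
         "domain_positions")

    regions <- c("EGF", "NRR", "PEST")
    emit(purrr::map(intersect(receptor_genes, names(models)), function(g) {
      purrr::map(regions, function(r) {
        frac <- tryCatch(region_fraction(records, g, models, r),
                         error = function(e) NA_real_)
        tibble::tibble(
          gene_symbol = g, region = r,
          fraction_pct = as.numeric(frac),
          n_region = attr(frac, "n_region") %||% NA_integer_,
          n_positioned = attr(frac, "n_positioned") %||% NA_integer_
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind(), "region_fractions")

    emit(hotspot_scan(receptor_records,
                      min_count = cfg$thresholds$hotspot_min), "hotspots")

    emit(purrr::map(intersect(receptor_genes, names(models)), function(g) {
      hits <- tryCatch(cysteine_change_scan(records, g, models),
                       error = function(e) NULL)
      if (is.null(hits) || nrow(hits) == 0L) return(NULL)
      dplyr::mutate(hits, gene_symbol = g)
    }) |> purrr::list_rbind() %||%
      tibble::tibble(gene_symbol = character(), protein_position = integer(),
                     change = character()),
      "cysteine_scan")
  })

  # ---- impact (optional) ----
  if (!is.null(cfg$scored_impact)) {
    run_stage("impact", {
      scored <- readr::read_tsv(cfg$scored_impact,
                                col_types = readr::cols(), progress = FALSE)
      impacts <- classify_impact(scored, threshold = cfg$thresholds$subpsec)
      emit(impacts, "impact_scores")
      emit(deleterious_fraction(impacts), "impact_summary")
      if (all(c("gene_symbol", "protein_position") %in% names(impacts))) {
        emit(deleterious_domain_summary(impacts, models), "deleterious_domains")
      }
    })
  } else stage_status$impact <- "skipped"

  # ---- CNA (optional) ----
  if (!is.null(cfg$cna)) {
    run_stage("cna", {
      cna <- read_cna_table(cfg$cna)
      emit(cna_frequencies(cna, receptor_genes), "cna_frequencies")
    })
  } else stage_status$cna <- "skipped"

  # ---- cohort comparison (optional) ----
  if (!is.null(cfg$tumor_mutations)) {
    run_stage("cohort_comparison", {
      traw <- read_mutation_table(cfg$tumor_mutations, dialect = cfg$dialect)
      tann <- read_sample_annotations(cfg$tumor_annotations)
      tf <- filter_records(traw, af_floor = cfg$filters$af_floor,
                           notch4_window = unlist(cfg$filters$notch4_window))
      pairing <- if (is.null(cfg$pairing)) {
        default_pairing()
      } else if (is.character(cfg$pairing)) {
        tibble::as_tibble(readr::read_tsv(cfg$pairing, col_types = readr::cols(),
                                          progress = FALSE))
      } else {
        tibble::as_tibble(purrr::map(purrr::transpose(cfg$pairing), unlist))
      }
      pairing <- pairing[pairing$cell_type %in% annotations$cell_type &
                           pairing$tumor_dataset %in% tann$cell_type, , drop = FALSE]
      cl_freq <- frequency_table(records, annotations, cfg$families,
                                 strata = unique(pairing$cell_type))
      tu_freq <- frequency_table(tf$records, tann, cfg$families,
                                 strata = unique(pairing$tumor_dataset))
      pairs <- pair_cohorts(cl_freq, tu_freq, pairing)
      deltas <- compute_deltas(pairs, cfg$families, models)
      emit(deltas, "cohort_deltas")
      emit(rank_deltas(deltas), "cohort_deltas_ranked")
    })
  } else stage_status$cohort_comparison <- "skipped"

  # ---- manifest ----
  input_paths <- purrr::compact(cfg[c("mutations", "annotations", "gene_models",
                                      "cna", "scored_impact", "tumor_mutations",
                                      "tumor_annotations")])
  manifest <- list(
    package = "mutscape",
    version = as.character(utils::packageVersion("mutscape")),
    inputs = purrr::imap(input_paths, function(p, nm) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    config = cfg[setdiff(names(cfg), c("families"))],
    families = purrr::map(cfg$families, as.list),
    stages = stage_status,
    outputs = as.list(files),
    filter_report = purrr::transpose(as.list(filter_report))
  )
  manifest_path <- file.path(cfg$outdir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  files["manifest"] <- manifest_path

  invisible(structure(
    list(tables = tables, files = files, manifest = manifest),
    class = "mutscape_run"
  ))
}

#' @export
print.mutscape_run <- function(x, ...) {
  cat("<mutscape_run>\n")
  cat("stages:\n")
  for (nm in names(x$manifest$stages)) {
    cat(sprintf("  %-18s %s\n", nm, x$manifest$stages[[nm]]))
  }
  cat(sprintf("%d output file(s) in %s\n", length(x$files),
              dirname(x$files[[1]])))
  invisible(x)
}

#' @describeIn run_pipeline Tidy method: one row per output table.
#' @param x A `mutscape_run`.
#' @param ... Unused.
#' @export
tidy.mutscape_run <- function(x, ...) {
  tibble::tibble(
    output = names(x$files),
    path = unname(x$files),
    n_rows = purrr::map_int(names(x$files), function(nm) {
      if (nm %in% names(x$tables)) nrow(x$tables[[nm]]) else NA_integer_
    })
  )
}

#' @describeIn run_pipeline Glance method: one-row run summary.
#' @export
glance.mutscape_run <- function(x, ...) {
  st <- unlist(x$manifest$stages)
  tibble::tibble(
    n_stages_run = sum(st == "ok"),
    n_stages_skipped = sum(st == "skipped"),
    n_outputs = length(x$files),
    records_in = x$manifest$filter_report[[1]]$records_in,
    records_out = x$manifest$filter_report[[length(x$manifest$filter_report)]]$records_out
  )
}
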