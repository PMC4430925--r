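#' Default per-gene mutation probabilities for the panel emulation
#'
#' Per-cell-line probabilities of carrying at least one mutation in each
#' gene, chosen so the emulated panel reproduces the reported headline
#' marginals of a ~900-line hybrid-capture panel: NOTCH1 7.3%,
#' NOTCH1-4 family ~20.4% (`1-(1-.073)(1-.05)^3`), TP53 60.0%, the
#' three-gene RAS family ~26.4%, the four ERBB receptors ~21.8%, APC
#' 15.5%, the two Patched genes ~10.5%, ligands 2.9-5%, and ~1%
#' housekeeping controls.
#'
#' @return Named numeric vector gene -> probability.
#' @export
default_mutation_probs <- function() {
  c(
    NOTCH1 = 0.073, NOTCH2 = 0.05, NOTCH3 = 0.05, NOTCH4 = 0.05,
    JAG1 = 0.05, JAG2 = 0.045, DLL1 = 0.04, DLL4 = 0.029,
    TP53 = 0.60,
    HRAS = 0.097, KRAS = 0.097, NRAS = 0.097,
    EGFR = 0.06, ERBB2 = 0.06, ERBB3 = 0.06, ERBB4 = 0.06,
    APC = 0.155,
    PTCH1 = 0.054, PTCH2 = 0.054,
    PABPN1 = 0.01, FPGT = 0.01, NONO = 0.01
  )
}

#' Default cell-type panel composition
#'
#' Twenty cell-type strata totalling 905 cell lines, shaped like a large
#' cell-line encyclopedia panel (pre-relabeling barcodes, so the
#' `haematopoietic_and_lymphoid_tissue` and `skin` labels exercise the
#' relabeling step).
#'
#' @return Tibble `cell_type`, `n_lines`.
#' @export
default_cell_types <- function() {
  tibble::tribble(
    ~cell_type,                            ~n_lines,
    "haematopoietic_and_lymphoid_tissue",  165L,
    "lung",                                130L,
    "skin",                                 60L,
    "central_nervous_system",               60L,
    "breast",                               58L,
    "large_intestine",                      56L,
    "ovary",                                51L,
    "pancreas",                             44L,
    "stomach",                              35L,
    "kidney",                               30L,
    "upper_aerodigestive_tract",            32L,
    "urinary_tract",                        27L,
    "liver",                                28L,
    "endometrium",                          27L,
    "oesophagus",                           26L,
    "bone",                                 20L,
    "soft_tissue",                          20L,
    "autonomic_ganglia",                    17L,
    "thyroid",                              12L,
    "prostate",                              7L
  )
}

#' Specify a synthetic cohort
#'
#' Bundles and validates everything the cohort generator needs: the
#' stratified panel composition, gene models, per-(gene, cell type)
#' mutation probabilities, the chance of a second mutation in an already
#' mutated line, the classification mixture, positional hotspots, decoy
#' (noise) fractions and the tumor-cohort probability margin. Identical
#' specs with identical seeds generate byte-identical cohorts.
#'
#' @param seed Integer RNG seed.
#' @param cell_types Tibble `cell_type`, `n_lines`.
#' @param gene_models `gene_model_set` for the simulated genes.
#' @param mutation_prob Named per-gene probability vector (expanded
#'   uniformly over cell types) or a tibble `gene_symbol`, `cell_type`,
#'   `prob`.
#' @param extra_mutation_prob Probability that a mutated line carries a
#'   second mutation in the same gene; default 0.175, which together with
#'   the default per-gene probabilities puts ~5% of lines at two or more
#'   family mutations.
#' @param class_mixture Named weights over classifications, summing to 1;
#'   default missense .72, frameshift .16, nonsense .08, in-frame indel
#'   .04 (the observed dominance order: missense >> frameshift > nonsense
#'   > indel).
#' @param hotspots Tibble `gene_symbol`, `position`, `classification`,
#'   `weight`: a matching record is relocated to the hotspot position with
#'   probability `weight`. Default: a NOTCH3 frameshift cluster at aa 1802
#'   with weight 0.6.
#' @param noise Named list of decoy fractions (of the true record count)
#'   to inject: `intronic`, `silent`, `low_af`, `notch4_window`. True
#'   records never fall inside the NOTCH4 exon-1 window, so injected
#'   window decoys are exactly recoverable by the filter audit.
#' @param tumor_margin Named numeric: probability decrement applied per
#'   paired tumor stratum (scalar default 0.1); negative values emulate
#'   strata more mutated in primary tumors. Default: 0.1 everywhere,
#'   0 for lung, -0.05 for melanoma.
#' @return Validated list of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L,
                           cell_types = default_cell_types(),
                           gene_models = read_gene_models(),
                           mutation_prob = default_mutation_probs(),
                           extra_mutation_prob = 0.175,
                           class_mixture = c(missense = 0.72, frameshift = 0.16,
                                             nonsense = 0.08, inframe_indel = 0.04),
                           hotspots = tibble::tibble(
                             gene_symbol = "NOTCH3", position = 1802L,
                             classification = "frameshift", weight = 0.6
                           ),
                           noise = list(intronic = 0.05, silent = 0.05,
                                        low_af = 0.03, notch4_window = 0.01),
                           tumor_margin = c(.default = 0.1, lung = 0,
                                            melanoma = -0.05)) {
  cell_types <- tibble::as_tibble(cell_types)
  stopifnot(all(c("cell_type", "n_lines") %in% names(cell_types)),
            all(cell_types$n_lines >= 1L))
  if (!is.data.frame(mutation_prob)) {
    mutation_prob <- tidyr::expand_grid(
      gene_symbol = names(mutation_prob),
      cell_type = cell_types$cell_type
    ) |>
      dplyr::mutate(prob = unname(mutation_prob[.data$gene_symbol]))
  }
  if (any(mutation_prob$prob < 0 | mutation_prob$prob > 1)) {
    rlang::abort("mutation probabilities must lie in [0, 1]")
  }
  genes <- unique(mutation_prob$gene_symbol)
  missing <- setdiff(genes, names(gene_models))
  if (length(missing)) {
    rlang::abort(sprintf("no gene model for simulated gene(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (abs(sum(class_mixture) - 1) > 1e-9) {
    rlang::abort("class_mixture weights must sum to 1")
  }
  if (any(class_mixture < 0)) rlang::abort("class_mixture weights must be non-negative")
  if (extra_mutation_prob < 0 || extra_mutation_prob > 1) {
    rlang::abort("extra_mutation_prob must lie in [0, 1]")
  }
  noise <- modifyList(list(intronic = 0, silent = 0, low_af = 0, notch4_window = 0),
                      as.list(noise))
  if (any(unlist(noise) < 0)) rlang::abort("noise fractions must be non-negative")
  structure(
    list(
      seed = as.integer(seed), cell_types = cell_types,
      gene_models = gene_models, genes = genes,
      mutation_prob = mutation_prob,
      extra_mutation_prob = extra_mutation_prob,
      class_mixture = class_mixture,
      hotspots = tibble::as_tibble(hotspots),
      noise = noise, tumor_margin = tumor_margin,
      notch4_window = c(1L, 60L)
    ),
    class = "generator_spec"
  )
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Draw one cohort's worth of true records + decoys for the given lines.
draw_records <- function(spec, annotations, prob_tbl) {
  lines <- annotations
  mix <- spec$class_mixture
  classes <- names(mix)
  rows <- list()
  truth_counts <- list()

  for (g in spec$genes) {
    gm <- spec$gene_models[[g]]
    pg <- prob_tbl[prob_tbl$gene_symbol == g, , drop = FALSE]
    p <- pg$prob[match(lines$cell_type, pg$cell_type)]
    p[is.na(p)] <- 0
    mutated <- rbinom(nrow(lines), 1L, p) == 1L
    truth_counts[[g]] <- dplyr::count(
      lines[mutated, , drop = FALSE], .data$cell_type, name = "n_mutated"
    ) |> dplyr::mutate(gene_symbol = g, .before = 1L)
    if (!any(mutated)) next
    mut_lines <- lines[mutated, , drop = FALSE]
    n_rec <- 1L + rbinom(nrow(mut_lines), 1L, spec$extra_mutation_prob)
    idx <- rep(seq_len(nrow(mut_lines)), n_rec)
    n <- length(idx)

    cls <- sample(classes, n, replace = TRUE, prob = mix)
    # positions: uniform over the protein, avoiding the NOTCH4 exon-1 window
    lo <- if (g == "NOTCH4") spec$notch4_window[2] + 1L else 1L
    pos <- lo + floor(runif(n) * (gm$protein_length_aa - lo + 1L))
    pos <- as.integer(pmin(pos, gm$protein_length_aa))
    # hotspot relocation
    hs <- spec$hotspots[spec$hotspots$gene_symbol == g, , drop = FALSE]
    hs_hit <- rep(FALSE, n)
    if (nrow(hs)) {
      for (k in seq_len(nrow(hs))) {
        cand <- cls == hs$classification[k]
        take <- cand & runif(n) < hs$weight[k]
        pos[take] <- as.integer(hs$position[k])
        hs_hit <- hs_hit | take
      }
    }
    ref <- sample(AA20, n, replace = TRUE)
    alt <- purrr::map_chr(ref, function(r) sample(setdiff(AA20, r), 1L))
    alt <- dplyr::case_when(
      cls == "missense" ~ alt,
      cls == "nonsense" ~ "*",
      TRUE ~ NA_character_
    )
    af <- 0.1 + 0.9 * rbeta(n, 2, 2)
    rows[[g]] <- tibble::tibble(
      gene_symbol = g,
      sample_id = mut_lines$sample_id[idx],
      cell_type = mut_lines$cell_type[idx],
      classification = cls,
      protein_position = pos,
      ref_aa = ref, alt_aa = alt,
      allelic_fraction = round(af, 4),
      hotspot = hs_hit
    )
  }

  true_records <- purrr::list_rbind(rows)
  if (is.null(true_records) || nrow(true_records) == 0L) {
    true_records <- tibble::tibble(
      gene_symbol = character(), sample_id = character(), cell_type = character(),
      classification = character(), protein_position = integer(),
      ref_aa = character(), alt_aa = character(), allelic_fraction = numeric(),
      hotspot = logical()
    )
  }
  list(true_records = true_records,
       mutated_lines = purrr::list_rbind(truth_counts))
}

draw_decoys <- function(spec, annotations, n_true) {
  mk_base <- function(n) {
    i <- sample.int(nrow(annotations), n, replace = TRUE)
    tibble::tibble(
      gene_symbol = sample(spec$genes, n, replace = TRUE),
      sample_id = annotations$sample_id[i],
      cell_type = annotations$cell_type[i]
    )
  }
  n_int <- round(spec$noise$intronic * n_true)
  n_sil <- round(spec$noise$silent * n_true)
  n_low <- round(spec$noise$low_af * n_true)
  n_win <- round(spec$noise$notch4_window * n_true)

  decoys <- list()
  if (n_int > 0) {
    decoys$intronic <- mk_base(n_int) |>
      dplyr::mutate(classification = "intronic", protein_position = NA_integer_,
                    ref_aa = NA_character_, alt_aa = NA_character_,
                    allelic_fraction = round(0.1 + 0.9 * rbeta(n_int, 2, 2), 4))
  }
  if (n_sil > 0) {
    base <- mk_base(n_sil)
    len <- purrr::map_int(base$gene_symbol,
                          function(g) spec$gene_models[[g]]$protein_length_aa)
    ref <- sample(AA20, n_sil, replace = TRUE)
    decoys$silent <- base |>
      dplyr::mutate(classification = "silent",
                    protein_position = as.integer(ceiling(runif(n_sil) * len)),
                    ref_aa = ref, alt_aa = ref,
                    allelic_fraction = round(0.1 + 0.9 * rbeta(n_sil, 2, 2), 4))
  }
  if (n_low > 0) {
    base <- mk_base(n_low)
    len <- purrr::map_int(base$gene_symbol,
                          function(g) spec$gene_models[[g]]$protein_length_aa)
    ref <- sample(AA20, n_low, replace = TRUE)
    alt <- purrr::map_chr(ref, function(r) sample(setdiff(AA20, r), 1L))
    decoys$low_af <- base |>
      dplyr::mutate(classification = "missense",
                    protein_position = as.integer(ceiling(runif(n_low) * len)),
                    ref_aa = ref, alt_aa = alt,
                    allelic_fraction = round(runif(n_low, 0.01, 0.0999), 4))
  }
  if (n_win > 0) {
    i <- sample.int(nrow(annotations), n_win, replace = TRUE)
    ref <- sample(AA20, n_win, replace = TRUE)
    alt <- purrr::map_chr(ref, function(r) sample(setdiff(AA20, r), 1L))
    decoys$notch4_window <- tibble::tibble(
      gene_symbol = "NOTCH4",
      sample_id = annotations$sample_id[i],
      cell_type = annotations$cell_type[i],
      classification = "missense",
      protein_position = as.integer(
        spec$notch4_window[1] +
          floor(runif(n_win) * (spec$notch4_window[2] - spec$notch4_window[1] + 1L))
      ),
      ref_aa = ref, alt_aa = alt,
      allelic_fraction = round(0.1 + 0.9 * rbeta(n_win, 2, 2), 4)
    )
  }
  list(
    records = purrr::list_rbind(purrr::map(decoys, function(d) {
      dplyr::mutate(d, hotspot = FALSE)
    })),
    counts = tibble::tibble(
      kind = c("intronic", "silent", "low_af", "notch4_window"),
      n = c(n_int, n_sil, n_low, n_win)
    )
  )
}

finalize_cohort <- function(spec, annotations, drawn, decoys, cohort_label) {
  recs <- dplyr::bind_rows(drawn$true_records, decoys$records)
  hotspot_counts <- drawn$true_records |>
    dplyr::filter(.data$hotspot) |>
    dplyr::count(.data$gene_symbol, .data$protein_position,
                 .data$classification, name = "n")
  records <- recs |>
    dplyr::select(-"hotspot") |>
    dplyr::mutate(protein_change = hgvsp_string(
      tibble::tibble(classification = recs$classification,
                     ref_aa = recs$ref_aa, alt_aa = recs$alt_aa,
                     protein_position = recs$protein_position)
    ))
  truth <- list(
    n_lines = dplyr::count(annotations, .data$cell_type, name = "n_lines"),
    mutated_lines = drawn$mutated_lines,
    n_true_records = nrow(drawn$true_records),
    decoy_counts = decoys$counts,
    hotspot_counts = hotspot_counts,
    true_records = drawn$true_records
  )
  structure(
    list(mutations = records, annotations = annotations, truth = truth,
         cohort = cohort_label),
    class = "mutscape_cohort"
  )
}

#' Generate a synthetic cell-line cohort with known ground truth
#'
#' Draws, per cell line and gene, mutation presence from the spec's
#' probabilities; mutated lines receive one record (or two, with the extra
#' probability), each with a classification from the mixture, a position
#' uniform over the protein (except hotspot mass, and never inside the
#' NOTCH4 exon-1 window), residues consistent with the classification and
#' an allelic fraction above the 10% floor. Decoy records
#' (intronic/silent/low-AF/NOTCH4-window) are appended after the true
#' records per the noise spec, so the filter cascade's audit counts are
#' known exactly. The returned ground truth records per-(gene, cell type)
#' mutated-line counts, decoy counts and realized hotspot counts.
#'
#' @param spec A [generator_spec()].
#' @return List of class `mutscape_cohort`: `mutations` (record tibble in
#'   the generic dialect), `annotations`, `truth`, `cohort`.
#' @export
generate_cohort <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  with_cohort_seed(spec$seed, {
    annotations <- cohort_annotations(spec$cell_types, "cell_line")
    drawn <- draw_records(spec, annotations, spec$mutation_prob)
    decoys <- draw_decoys(spec, annotations, nrow(drawn$true_records))
    finalize_cohort(spec, annotations, drawn, decoys, "cell_line")
  })
}

#' Generate the paired primary-tumor cohort
#'
#' Applies the same generative process to the paired tumor strata, with
#' per-gene probabilities reduced by the spec's tumor margin (floored at 0,
#' capped at 1; a negative margin raises the tumor probability, emulating
#' strata more mutated in primary tumors, e.g. melanoma). Tumor strata and
#' sizes come from the pairing config; each tumor stratum inherits the
#' probabilities of its paired cell-line type.
#'
#' @param spec A [generator_spec()].
#' @param pairing Pairing tibble (see [default_pairing()]); `tumor_n`
#'   gives each tumor stratum's sample count.
#' @param relabel_map Map used to trace post-relabel cell-line strata back
#'   to the generator's barcode labels.
#' @return List of class `mutscape_cohort` with `cohort = "primary_tumor"`.
#' @export
generate_paired_tumor_cohort <- function(spec = generator_spec(),
                                         pairing = default_pairing(),
                                         relabel_map = default_relabel_map()) {
  stopifnot(inherits(spec, "generator_spec"))
  margin_for <- function(label) {
    m <- spec$tumor_margin
    if (is.null(names(m))) return(m[1])
    if (label %in% names(m)) unname(m[label]) else unname(m[".default"] %||% 0)
  }
  inv_relabel <- setNames(names(relabel_map), unname(relabel_map))
  with_cohort_seed(spec$seed + 1000003L, {
    ann <- cohort_annotations(
      tibble::tibble(cell_type = pairing$tumor_dataset, n_lines = pairing$tumor_n),
      "primary_tumor"
    )
    # tumor probabilities: paired cell-line probabilities minus the margin
    prob_tbl <- purrr::pmap(pairing, function(cell_type, tumor_dataset, tumor_n) {
      src <- if (cell_type %in% spec$mutation_prob$cell_type) {
        cell_type
      } else {
        inv_relabel[cell_type] %||% cell_type
      }
      src_p <- spec$mutation_prob[spec$mutation_prob$cell_type == src, , drop = FALSE]
      if (nrow(src_p) == 0L) {
        src_p <- spec$mutation_prob |>
          dplyr::summarise(prob = mean(.data$prob), .by = "gene_symbol") |>
          dplyr::mutate(cell_type = cell_type)
      }
      tibble::tibble(
        gene_symbol = src_p$gene_symbol,
        cell_type = tumor_dataset,
        prob = pmin(pmax(src_p$prob - margin_for(tumor_dataset), 0), 1)
      )
    }) |> purrr::list_rbind()
    drawn <- draw_records(spec, ann, prob_tbl)
    decoys <- draw_decoys(spec, ann, nrow(drawn$true_records))
    out <- finalize_cohort(spec, ann, drawn, decoys, "primary_tumor")
    out$truth$prob_tbl <- prob_tbl
    out
  })
}

cohort_annotations <- function(cell_types, cohort) {
  purrr::pmap(cell_types, function(cell_type, n_lines, ...) {
    tibble::tibble(
      sample_id = sprintf("%s_%s_%04d",
                          if (cohort == "cell_line") "L" else "T",
                          toupper(cell_type), seq_len(n_lines)),
      cell_type = cell_type,
      cohort = cohort
    )
  }) |> purrr::list_rbind()
}

# Run code under a private, restorable RNG state.
with_cohort_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Write a generated cohort to disk
#'
#' Emits the mutation table and sample annotations in the generic TSV
#' dialect read by [read_mutation_table()] / [read_sample_annotations()],
#' and the ground truth as YAML. Byte-identical across runs with the same
#' spec and seed.
#'
#' @param cohort A `mutscape_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    mutations = file.path(dir, "mutations.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth.yaml")
  )
  write_mutation_table(cohort$mutations, paths[["mutations"]])
  readr::write_tsv(cohort$annotations, paths[["annotations"]], progress = FALSE)
  truth <- cohort$truth
  yaml::write_yaml(list(
    cohort = cohort$cohort,
    n_true_records = truth$n_true_records,
    n_lines = purrr::transpose(as.list(truth$n_lines)),
    mutated_lines = purrr::transpose(as.list(truth$mutated_lines)),
    decoy_counts = purrr::transpose(as.list(truth$decoy_counts)),
    hotspot_counts = purrr::transpose(as.list(truth$hotspot_counts))
  ), paths[["truth"]])
  invisible(paths)
}

#' Generate a synthetic GISTIC-style CNA table
#'
#' Draws per-sample discrete copy-number calls for the given genes, with
#' independent high-level amplification (+2) and deep deletion (-2)
#' probabilities; everything else is 0 (the summary ignores +/-1 calls, so
#' they are not simulated). Defaults sit in the reported panel ranges:
#' amplifications 1.7-4.2% with NOTCH4 the most amplified, deletions
#' 0.6-2.3%.
#'
#' @param sample_ids Character vector of sample IDs.
#' @param amp_prob,del_prob Named per-gene probabilities.
#' @param seed RNG seed.
#' @return List: `records` (long-form CNA tibble), `truth` (per-gene
#'   amplified/deleted counts).
#' @export
generate_cna_table <- function(sample_ids,
                               amp_prob = c(NOTCH1 = 0.017, NOTCH2 = 0.025,
                                            NOTCH3 = 0.020, NOTCH4 = 0.042),
                               del_prob = c(NOTCH1 = 0.006, NOTCH2 = 0.010,
                                            NOTCH3 = 0.015, NOTCH4 = 0.023),
                               seed = 1L) {
  with_cohort_seed(seed + 2000003L, {
    genes <- union(names(amp_prob), names(del_prob))
    recs <- purrr::map(genes, function(g) {
      amp <- rbinom(length(sample_ids), 1L, amp_prob[g] %||% 0) == 1L
      del <- !amp & rbinom(length(sample_ids), 1L, del_prob[g] %||% 0) == 1L
      tibble::tibble(
        gene_symbol = g, sample_id = sample_ids,
        gistic_call = dplyr::case_when(amp ~ 2L, del ~ -2L, TRUE ~ 0L)
      )
    }) |> purrr::list_rbind()
    truth <- recs |>
      dplyr::summarise(
        n_amplified = sum(.data$gistic_call == 2L),
        n_deleted = sum(.data$gistic_call == -2L),
        n_samples = dplyr::n(), .by = "gene_symbol"
      )
    list(records = recs, truth = truth)
  })
}
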