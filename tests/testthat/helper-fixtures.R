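# Shared in-code fixtures: tiny record/annotation builders, a brute-force
# frequency oracle, and a small generator spec used where full panel scale
# is unnecessary.

toy_annotations <- function(n = 10L, cell_type = "lung", cohort = "cell_line",
                            prefix = "s") {
  tibble::tibble(
    sample_id = paste0(prefix, seq_len(n)),
    cell_type = cell_type,
    cohort = cohort
  )
}

toy_record <- function(gene = "NOTCH1", sample = "s1", cell_type = "lung",
                       classification = "missense", position = 100L,
                       ref = "A", alt = "T", af = 0.5) {
  tibble::tibble(
    gene_symbol = gene, sample_id = sample, cell_type = cell_type,
    classification = classification,
    protein_position = as.integer(position),
    ref_aa = ref, alt_aa = alt, allelic_fraction = af,
    protein_change = ""
  )
}

toy_records <- function(...) dplyr::bind_rows(...)

# Brute-force oracle: per-line set membership, no dplyr grouping.
oracle_family_frequency <- function(records, annotations, members,
                                    stratum = "ALL") {
  ann <- if (identical(stratum, "ALL")) annotations else
    annotations[annotations$cell_type == stratum, ]
  hit <- 0L
  for (s in ann$sample_id) {
    genes <- records$gene_symbol[records$sample_id == s]
    if (any(genes %in% members)) hit <- hit + 1L
  }
  list(n_mutated = hit, n_lines = nrow(ann),
       pct = if (nrow(ann)) 100 * hit / nrow(ann) else NA_real_)
}

# Random small cohort for oracle comparisons.
random_small_cohort <- function(seed, n_lines = 8L, genes = c("G1", "G2", "G3"),
                                max_records = 12L) {
  set.seed(seed)
  ann <- toy_annotations(n_lines, cell_type = sample(c("lung", "liver"), 1L))
  n <- sample.int(max_records, 1L)
  records <- tibble::tibble(
    gene_symbol = sample(genes, n, replace = TRUE),
    sample_id = sample(ann$sample_id, n, replace = TRUE),
    cell_type = ann$cell_type[1],
    classification = "missense",
    protein_position = sample.int(90L, n, replace = TRUE),
    ref_aa = "A", alt_aa = "T", allelic_fraction = 0.5, protein_change = ""
  )
  list(records = records, annotations = ann)
}

# Small in-code gene models used where the shipped config is overkill.
tiny_models <- function() {
  structure(list(
    GENEA = gene_model("GENEA", 300, 100, tibble::tibble(
      name = c("DOM1", "DOM2", "PEST"),
      start_aa = c(10L, 41L, 81L), end_aa = c(30L, 60L, 100L)
    )),
    GENEB = gene_model("GENEB", 600, 200)
  ), class = "gene_model_set")
}

shipped_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_gene_models(default_gene_models_path())
    cache
  }
})

# A scaled-down generator spec: 3 strata, 4 genes, quick to draw.
small_spec <- function(seed = 1L, noise = list(intronic = 0.1, silent = 0.1,
                                               low_af = 0.05,
                                               notch4_window = 0.05),
                       probs = c(NOTCH1 = 0.2, NOTCH3 = 0.15, NOTCH4 = 0.15,
                                 TP53 = 0.5),
                       cell_types = tibble::tibble(
                         cell_type = c("lung", "skin", "liver"),
                         n_lines = c(20L, 15L, 10L)
                       ),
                       ...) {
  generator_spec(
    seed = seed, cell_types = cell_types,
    gene_models = shipped_models(),
    mutation_prob = probs, noise = noise, ...
  )
}
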