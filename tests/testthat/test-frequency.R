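test_that("family frequency deduplicates lines across members", {
  ann <- toy_annotations(10)
  recs <- toy_records(
    toy_record(gene = "NOTCH1", sample = "s1"),
    toy_record(gene = "NOTCH2", sample = "s1"),
    toy_record(gene = "NOTCH3", sample = "s2")
  )
  fam <- gene_family("NOTCH", paste0("NOTCH", 1:4))
  out <- family_frequency(recs, ann, fam)
  expect_equal(out$n_mutated_lines, 2L)
  expect_equal(out$frequency_pct, 20)

  # two distinct mutations in one gene in one line still count once
  out1 <- gene_frequency(
    toy_records(toy_record(sample = "s1", position = 10L),
                toy_record(sample = "s1", position = 20L)),
    ann, "NOTCH1"
  )
  expect_equal(out1$frequency_pct, 10)
})

test_that("frequency bounds: no mutations give 0%, all lines mutated give 100%", {
  ann <- toy_annotations(5)
  fam <- gene_family("NOTCH", paste0("NOTCH", 1:4))
  expect_equal(family_frequency(toy_record()[0, ], ann, fam)$frequency_pct, 0)
  all_mut <- purrr::map(ann$sample_id,
                        function(s) toy_record(sample = s)) |> purrr::list_rbind()
  expect_equal(family_frequency(all_mut, ann, fam)$frequency_pct, 100)
})

test_that("unknown strata and model-less families are hard errors", {
  ann <- toy_annotations(5)
  fam <- gene_family("NOTCH", paste0("NOTCH", 1:4))
  expect_error(family_frequency(toy_record()[0, ], ann, fam, "mars"),
               "unknown stratum")
  expect_error(
    family_frequency(toy_record()[0, ], ann, gene_family("X", "NOSUCH"),
                     gene_models = tiny_models()),
    "no member"
  )
})

test_that("family frequency matches a brute-force per-line oracle", {
  fam_members <- c("G1", "G2")
  for (seed in 1:60) {
    fx <- random_small_cohort(seed)
    got <- family_frequency(fx$records, fx$annotations,
                            gene_family("FAM", fam_members))
    want <- oracle_family_frequency(fx$records, fx$annotations, fam_members)
    expect_equal(got$n_mutated_lines, want$n_mutated)
    expect_equal(got$frequency_pct, want$pct)
    # a single gene can never exceed its family
    g1 <- gene_frequency(fx$records, fx$annotations, "G1")
    expect_lte(g1$frequency_pct, got$frequency_pct)
  }
})

test_that("adding a record never decreases a frequency", {
  fx <- random_small_cohort(99)
  fam <- gene_family("FAM", c("G1", "G2", "G3"))
  base <- family_frequency(fx$records, fx$annotations, fam)$frequency_pct
  extra <- dplyr::bind_rows(fx$records,
                            toy_record(gene = "G2",
                                       sample = fx$annotations$sample_id[1],
                                       cell_type = fx$annotations$cell_type[1]))
  expect_gte(family_frequency(extra, fx$annotations, fam)$frequency_pct, base)
})

test_that("length normalization is exact arithmetic with an exact inverse", {
  entry <- family_frequency(
    toy_records(toy_record(sample = "s1"), toy_record(sample = "s2")),
    toy_annotations(10), gene_family("F", "NOTCH1")
  )
  expect_equal(entry$frequency_pct, 20)
  kbp <- normalize_by_length(entry, avg_cds_length_bp = 8000)
  expect_equal(kbp$per_kbp_pct, 2.5)
  tenk <- normalize_by_length(entry, avg_cds_length_bp = 8000, scale = "per_10kbp")
  expect_equal(tenk$per_10kbp_pct, 25)
  expect_equal(kbp$per_kbp_pct * 8000 / 1000, entry$frequency_pct)
  expect_error(normalize_by_length(entry, avg_cds_length_bp = 0), "positive")
})

test_that("type distribution uses all mutations and the four canonical bins", {
  recs <- dplyr::bind_rows(
    purrr::map(1:6, function(i) toy_record(sample = "s1", position = i)),
    toy_record(sample = "s2", classification = "nonsense", alt = "*"),
    toy_record(sample = "s2", classification = "nonsense", alt = "*",
               position = 7L),
    toy_record(sample = "s3", classification = "frameshift", alt = NA),
    toy_record(sample = "s3", classification = "frameshift", alt = NA,
               position = 9L)
  )
  out <- type_distribution(recs)
  expect_equal(out$share[match(c("missense", "nonsense", "frameshift",
                                 "inframe_indel"), out$classification)],
               c(0.6, 0.2, 0.2, 0))
  single <- type_distribution(toy_record(classification = "nonsense", alt = "*"))
  expect_equal(single$share[single$classification == "nonsense"], 1)
  empty <- type_distribution(toy_record()[0, ])
  expect_true(attr(empty, "empty"))
  expect_true(all(is.na(empty$share)))
})

test_that("splice records are excluded from the four-class distribution but counted", {
  recs <- dplyr::bind_rows(
    toy_record(),
    toy_record(classification = "splice", position = NA, ref = NA, alt = NA)
  )
  out <- type_distribution(recs)
  expect_equal(sum(out$n), 1L)
  expect_equal(attr(out, "n_excluded"), 1L)
})

test_that("receptor distribution reproduces a liver-like two-receptor pattern", {
  recs <- dplyr::bind_rows(
    toy_record(gene = "NOTCH1"), toy_record(gene = "NOTCH1", position = 5L),
    toy_record(gene = "NOTCH4", position = 100L),
    toy_record(gene = "NOTCH4", position = 200L)
  )
  out <- receptor_distribution(recs)
  expect_equal(out$share, c(0.5, 0, 0, 0.5))
  one <- receptor_distribution(toy_record(gene = "NOTCH3"))
  expect_equal(one$share[one$gene_symbol == "NOTCH3"], 1)
})

test_that("distribution shares sum to one on every non-empty generated stratum", {
  for (seed in 1:20) {
    cohort <- generate_cohort(small_spec(seed = seed, noise = list()))
    recs <- cohort$mutations
    for (st in unique(cohort$annotations$cell_type)) {
      td <- type_distribution(recs, st)
      if (!attr(td, "empty")) expect_equal(sum(td$share), 1, tolerance = 1e-9)
      rd <- receptor_distribution(recs, st,
                                  genes = c("NOTCH1", "NOTCH3", "NOTCH4"))
      if (!attr(rd, "empty")) expect_equal(sum(rd$share), 1, tolerance = 1e-9)
    }
  }
})

test_that("multi-mutation fraction counts lines with two or more records", {
  ann <- toy_annotations(10)
  recs <- toy_records(
    toy_record(sample = "s1", position = 10L),
    toy_record(sample = "s1", position = 20L),
    toy_record(gene = "NOTCH1", sample = "s2"),
    toy_record(gene = "NOTCH3", sample = "s2"),
    toy_record(sample = "s3")
  )
  fam <- gene_family("NOTCH", paste0("NOTCH", 1:4))
  out <- multi_mutation_fraction(recs, ann, fam)
  expect_equal(out$fraction_pct, 20)
  expect_equal(multi_mutation_fraction(toy_record(), ann, fam)$fraction_pct, 0)
  # >= 2 records implies >= 1 record, so multi <= family frequency
  expect_lte(out$fraction_pct, family_frequency(recs, ann, fam)$frequency_pct)
})

test_that("generated frequencies recover the design probability within binomial error", {
  cases <- tidyr::expand_grid(p = c(0.05, 0.2, 0.6), n = c(100L, 900L))
  for (i in seq_len(nrow(cases))) {
    p <- cases$p[i]; n <- cases$n[i]
    spec <- generator_spec(
      seed = 1000L + i,
      cell_types = tibble::tibble(cell_type = "lung", n_lines = n),
      mutation_prob = c(NOTCH1 = p), noise = list()
    )
    cohort <- generate_cohort(spec)
    est <- gene_frequency(cohort$mutations, cohort$annotations, "NOTCH1")
    expect_lt(abs(est$frequency_pct / 100 - p), 3 * sqrt(p * (1 - p) / n))
  }
})
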