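test_that("domain assignment is total and partitions the protein", {
  models <- shipped_models()
  for (g in c("NOTCH1", "NOTCH3")) {
    gm <- models[[g]]
    labels <- assign_domain(seq_len(gm$protein_length_aa), gm)
    expect_equal(length(labels), gm$protein_length_aa)
    expect_false(any(labels == "unassigned"))
    # every domain's width is recovered exactly: no overlap, no leakage
    tab <- table(labels)
    for (k in seq_len(nrow(gm$domains))) {
      expect_equal(unname(tab[gm$domains$name[k]]),
                   gm$domains$end_aa[k] - gm$domains$start_aa[k] + 1L,
                   label = paste(g, gm$domains$name[k]))
    }
  }
})

test_that("boundary residues belong to their domain, gaps are interdomain", {
  gm <- tiny_models()$GENEA
  expect_equal(assign_domain(c(10L, 30L, 31L, 40L, 41L), gm),
               c("DOM1", "DOM1", "interdomain", "interdomain", "DOM2"))
  expect_equal(assign_domain(NA_integer_, gm), "unassigned")
  expect_equal(assign_domain(85L, gm), "PEST")
  expect_error(assign_domain(101L, gm), "beyond")
})

test_that("region fractions count positioned records over named regions", {
  gm_set <- tiny_models()
  recs <- dplyr::bind_rows(
    purrr::map(c(12L, 15L, 20L, 28L), function(p)
      toy_record(gene = "GENEA", position = p)),           # 4 in DOM1
    purrr::map(c(35L, 50L, 70L, 95L), function(p)
      toy_record(gene = "GENEA", position = p))            # elsewhere
  )
  expect_equal(as.numeric(region_fraction(recs, "GENEA", gm_set, "DOM1")), 50)
  expect_equal(as.numeric(region_fraction(recs, "GENEA", gm_set, character())), 0)
  all_names <- c(gm_set$GENEA$domains$name, "interdomain")
  expect_equal(as.numeric(region_fraction(recs, "GENEA", gm_set, all_names)), 100)
  expect_error(region_fraction(recs, "GENEA", gm_set, "NOPE"), "unknown region")
})

test_that("region fractions over a partition sum to 100%", {
  cohort <- generate_cohort(small_spec(seed = 5, noise = list()))
  models <- shipped_models()
  parts <- c(models$NOTCH1$domains$name, "interdomain")
  total <- sum(purrr::map_dbl(parts, function(d) {
    as.numeric(region_fraction(cohort$mutations, "NOTCH1", models, d))
  }))
  expect_equal(total, 100, tolerance = 1e-9)
})

test_that("NRR expands to LNR plus HD and EGF to the repeat union", {
  models <- shipped_models()
  recs <- dplyr::bind_rows(
    toy_record(gene = "NOTCH1", position = 1460L),  # LNR
    toy_record(gene = "NOTCH1", position = 1600L),  # HD
    toy_record(gene = "NOTCH1", position = 30L),    # EGF_1
    toy_record(gene = "NOTCH1", position = 2500L)   # PEST
  )
  expect_equal(as.numeric(region_fraction(recs, "NOTCH1", models, "NRR")), 50)
  expect_equal(as.numeric(region_fraction(recs, "NOTCH1", models, "EGF")), 25)
  expect_equal(as.numeric(region_fraction(recs, "NOTCH1", models, "PEST")), 25)
})

test_that("unpositioned records are excluded from the denominator and reported", {
  recs <- dplyr::bind_rows(
    toy_record(gene = "GENEA", position = 12L),
    toy_record(gene = "GENEA", classification = "splice", position = NA,
               ref = NA, alt = NA)
  )
  frac <- region_fraction(recs, "GENEA", tiny_models(), "DOM1")
  expect_equal(as.numeric(frac), 100)
  expect_equal(attr(frac, "n_unpositioned"), 1L)
})

test_that("the cysteine scan flags gains and losses inside the region only", {
  models <- shipped_models()
  recs <- dplyr::bind_rows(
    toy_record(gene = "NOTCH1", position = 49L, ref = "C", alt = "Y"),
    toy_record(gene = "NOTCH1", position = 90L, ref = "R", alt = "C"),
    toy_record(gene = "NOTCH1", position = 123L, ref = "A", alt = "T"),
    toy_record(gene = "NOTCH1", position = 2500L, ref = "C", alt = "S") # PEST
  )
  hits <- cysteine_change_scan(recs, "NOTCH1", models, region = "EGF")
  expect_equal(nrow(hits), 2L)
  expect_equal(sort(hits$change), c("gain", "loss"))
  expect_equal(hits$change[hits$protein_position == 49L], "loss")
})

test_that("hotspot scan finds recurrent positions deterministically", {
  recs <- dplyr::bind_rows(
    purrr::map(1:4, function(i)
      toy_record(gene = "NOTCH3", sample = paste0("s", i),
                 classification = "frameshift", position = 1802L, alt = NA)),
    toy_record(gene = "NOTCH1", position = 100L),
    toy_record(gene = "NOTCH2", position = 200L)
  )
  hs <- hotspot_scan(recs)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$gene_symbol, "NOTCH3")
  expect_equal(hs$protein_position, 1802L)
  expect_equal(hs$classification, "frameshift")
  expect_equal(hs$n_records, 4L)

  expect_equal(nrow(hotspot_scan(dplyr::bind_rows(
    toy_record(position = 1L), toy_record(position = 2L)
  ))), 0L)
})

test_that("min_count = 1 reproduces brute-force grouping", {
  fx <- random_small_cohort(7)
  hs <- hotspot_scan(fx$records, min_count = 1L)
  brute <- unique(fx$records[c("gene_symbol", "protein_position",
                               "classification")])
  expect_equal(nrow(hs), nrow(brute))
  expect_equal(sum(hs$n_records), nrow(fx$records))
})

test_that("an injected generator hotspot is recovered as top-ranked", {
  n_checked <- 0L
  for (seed in c(3, 8, 21)) {
    cohort <- generate_cohort(generator_spec(
      seed = seed, gene_models = shipped_models(),
      cell_types = tibble::tibble(cell_type = c("lung", "liver"),
                                  n_lines = c(60L, 60L)),
      mutation_prob = c(NOTCH3 = 0.3, NOTCH1 = 0.1),
      class_mixture = c(missense = 0.5, frameshift = 0.5),
      hotspots = tibble::tibble(gene_symbol = "NOTCH3", position = 1802L,
                                classification = "frameshift", weight = 0.8),
      noise = list()
    ))
    realized <- cohort$truth$hotspot_counts
    realized <- realized[realized$protein_position == 1802L, ]
    if (nrow(realized) && realized$n[1] >= 3L) {
      hs <- hotspot_scan(filter_records(cohort$mutations)$records)
      expect_gt(nrow(hs), 0L)
      expect_equal(hs$gene_symbol[1], "NOTCH3")
      expect_equal(hs$protein_position[1], 1802L)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 0L)
})
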