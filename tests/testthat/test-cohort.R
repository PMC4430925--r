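freq_fixture <- function(units, strata, pcts) {
  tidyr::expand_grid(unit = units, stratum = strata) |>
    dplyr::mutate(
      n_lines = 100L,
      n_mutated_lines = as.integer(pcts),
      frequency_pct = pcts, per_kbp_pct = NA_real_
    )
}

test_that("cohort pairing matches strata and reports the unpaired", {
  cl <- freq_fixture("NOTCH", c("lung", "liver", "bone"), 30)
  tu <- freq_fixture("NOTCH", c("lung", "liver"), 10)
  pairing <- tibble::tibble(cell_type = c("lung", "liver"),
                            tumor_dataset = c("lung", "liver"))
  pairs <- pair_cohorts(cl, tu, pairing)
  expect_equal(nrow(pairs), 2L)
  expect_equal(attr(pairs, "unpaired"), "bone")

  empty <- pair_cohorts(cl, tu, pairing[0, ])
  expect_equal(nrow(empty), 0L)

  bad <- tibble::tibble(cell_type = "lung", tumor_dataset = "mars")
  expect_error(pair_cohorts(cl, tu, bad), "mars")
})

test_that("a full 12-stratum pairing yields 12 pairs per family", {
  strata <- default_pairing()$cell_type
  cl <- freq_fixture(c("NOTCH", "TP53"), strata, 30)
  tu <- freq_fixture(c("NOTCH", "TP53"), strata, 10)
  pairs <- pair_cohorts(cl, tu, default_pairing())
  expect_equal(nrow(pairs), 24L)
  expect_equal(unname(table(pairs$unit)), c(12L, 12L), ignore_attr = TRUE)
})

test_that("delta arithmetic covers positive, zero and negative differences", {
  models <- structure(
    list(F1 = gene_model("F1", 10000, 3000)),
    class = "gene_model_set"
  )
  pairs <- tibble::tibble(
    unit = "F1",
    cell_type = c("endometrium", "lung", "melanoma"),
    tumor_dataset = c("endometrium", "lung", "melanoma"),
    freq_cell_lines_pct = c(30, 15, 5),
    freq_tumors_pct = c(10, 15, 12),
    n_cell_lines = 100L, n_tumors = 100L
  )
  out <- compute_deltas(pairs, list(F1 = "F1"), models)
  expect_equal(out$delta_pct, c(20, 0, -7))
  expect_equal(out$delta_per_10kbp, c(20, 0, -7))
  expect_error(compute_deltas(pairs, list(F1 = "NOSUCH"), models), "NOSUCH")
})

test_that("swapping the cohorts negates every delta", {
  models <- shipped_models()
  fams <- list(NOTCH = paste0("NOTCH", 1:4), TP53 = "TP53")
  strata <- c("lung", "liver")
  cl <- freq_fixture(names(fams), strata, c(25, 40, 10, 60))
  tu <- freq_fixture(names(fams), strata, c(12, 15, 9, 55))
  pairing <- tibble::tibble(cell_type = strata, tumor_dataset = strata)
  fwd <- compute_deltas(pair_cohorts(cl, tu, pairing), fams, models)
  rev <- compute_deltas(pair_cohorts(tu, cl, pairing), fams, models)
  key <- c("unit", "cell_type")
  m <- dplyr::inner_join(fwd, rev, by = key, suffix = c("", ".rev"))
  expect_equal(m$delta_pct, -m$delta_pct.rev)
  expect_equal(m$delta_per_10kbp, -m$delta_per_10kbp.rev)
})

test_that("ranking sorts by normalized delta with deterministic tie-breaks", {
  models <- structure(
    list(F1 = gene_model("F1", 10000, 3000)),
    class = "gene_model_set"
  )
  pairs <- tibble::tibble(
    unit = "F1", cell_type = c("a", "b", "c"), tumor_dataset = c("a", "b", "c"),
    freq_cell_lines_pct = c(5, 0, 9), freq_tumors_pct = c(0, 1, 0),
    n_cell_lines = 10L, n_tumors = 10L
  )
  ranked <- rank_deltas(compute_deltas(pairs, list(F1 = "F1"), models))
  expect_equal(ranked$delta_per_10kbp, c(9, 5, -1))

  ties <- pairs |> dplyr::mutate(freq_cell_lines_pct = 3, freq_tumors_pct = 0)
  r1 <- rank_deltas(compute_deltas(ties, list(F1 = "F1"), models))
  r2 <- rank_deltas(compute_deltas(ties, list(F1 = "F1"), models))
  expect_equal(r1$cell_type, c("a", "b", "c"))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("ranking is invariant under a common rescaling of all lengths", {
  fams <- list(A = "FA", B = "FB")
  mk_models <- function(scale) structure(
    list(FA = gene_model("FA", 3000 * scale, 999),
         FB = gene_model("FB", 9000 * scale, 2999)),
    class = "gene_model_set"
  )
  pairs <- tidyr::expand_grid(unit = c("A", "B"), cell_type = c("x", "y")) |>
    dplyr::mutate(tumor_dataset = cell_type,
                  freq_cell_lines_pct = c(10, 4, 30, 2),
                  freq_tumors_pct = c(1, 2, 3, 4),
                  n_cell_lines = 10L, n_tumors = 10L)
  r1 <- rank_deltas(compute_deltas(pairs, fams, mk_models(1)))
  r5 <- rank_deltas(compute_deltas(pairs, fams, mk_models(5)))
  expect_equal(r1[c("unit", "cell_type")], r5[c("unit", "cell_type")])
})

test_that("a generator margin of 0.1 is recovered as a mean delta near 10 points", {
  n <- 200L
  strata <- c("endometrium", "prostate", "liver")
  spec <- generator_spec(
    seed = 31,
    cell_types = tibble::tibble(cell_type = strata, n_lines = n),
    mutation_prob = c(NOTCH1 = 0.3, NOTCH2 = 0.0, NOTCH3 = 0.0, NOTCH4 = 0.0),
    noise = list(), tumor_margin = 0.1,
    hotspots = tibble::tibble(gene_symbol = character(), position = integer(),
                              classification = character(), weight = numeric())
  )
  pairing <- tibble::tibble(cell_type = strata, tumor_dataset = strata,
                            tumor_n = n)
  cl <- generate_cohort(spec)
  tu <- generate_paired_tumor_cohort(spec, pairing = pairing)
  fams <- list(NOTCH1 = "NOTCH1")
  cl_freq <- frequency_table(cl$mutations, cl$annotations, fams, strata)
  tu_freq <- frequency_table(tu$mutations, tu$annotations, fams, strata)
  deltas <- compute_deltas(pair_cohorts(cl_freq, tu_freq, pairing),
                           fams, shipped_models())
  se <- 100 * sqrt(0.3 * 0.7 / n + 0.2 * 0.8 / n) / sqrt(length(strata))
  expect_lt(abs(mean(deltas$delta_pct) - 10), 3 * se)
})

test_that("equal-probability control families center their deltas on zero", {
  n <- 200L
  strata <- c("lung", "breast")
  spec <- generator_spec(
    seed = 77,
    cell_types = tibble::tibble(cell_type = strata, n_lines = n),
    mutation_prob = c(PABPN1 = 0.05, FPGT = 0.05, NONO = 0.05),
    noise = list(), tumor_margin = 0,
    hotspots = tibble::tibble(gene_symbol = character(), position = integer(),
                              classification = character(), weight = numeric())
  )
  pairing <- tibble::tibble(cell_type = strata, tumor_dataset = strata,
                            tumor_n = n)
  cl <- generate_cohort(spec)
  tu <- generate_paired_tumor_cohort(spec, pairing = pairing)
  fams <- list(HK = c("PABPN1", "FPGT", "NONO"))
  cl_freq <- frequency_table(cl$mutations, cl$annotations, fams, strata)
  tu_freq <- frequency_table(tu$mutations, tu$annotations, fams, strata)
  deltas <- compute_deltas(pair_cohorts(cl_freq, tu_freq, pairing),
                           fams, shipped_models())
  p <- 1 - (1 - 0.05)^3
  se <- 100 * sqrt(2 * p * (1 - p) / n) / sqrt(length(strata))
  expect_lt(abs(mean(deltas$delta_pct)), 3 * se)
})
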