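# mutscape

Mutation-landscape profiling for cancer cell-line panels.

Large cell-line panels such as the Cancer Cell Line Encyclopedia ship
MAF-like somatic mutation tables — one row per call, with a gene symbol,
sample barcode, variant classification and a protein change in HGVS-p short
form. `mutscape` turns such a table, a sample annotation table and a
gene-model config into the standard landscape statistics used to ask
whether a gene family (the four Notch receptors, say) is mutated as often
as established oncogenes, where its mutations sit on the protein, how
damaging they are predicted to be, and whether cell lines carry more of
them than matched primary tumors — the signature of an *in vitro* growth
advantage.

The central statistic is the **gene-family mutation frequency**

> f = 100 · |{lines with ≥ 1 mutation in any family member}| / |{annotated lines}| ,

counting each cell line at most once, optionally length-normalized as
f / (mean family CDS length / 1000) in %/kbp so that large coding regions
do not dominate. Around it the package implements the full workflow:

* the filter cascade for hybrid-capture calls (intronic/silent records,
  allelic fractions < 10%, the NOTCH4 exon-1 (CTG)n polymorphism window,
  cell types with < 5 lines), with a chained audit report;
* mutation-type and per-receptor distributions (all records, no
  deduplication), multi-mutation fractions;
* protein-domain mapping with closed 1-based intervals: EGF/NRR/PEST region
  fractions, a cysteine gain/loss scan, recurrent-position hotspot
  detection;
* functional-impact classification from subPSEC-style scores (strictly
  below −3 = deleterious) and GISTIC-style copy-number summaries (±2
  only);
* paired cell-line vs primary-tumor comparisons with ranked Δ% and
  Δ%/10 kbp;
* a synthetic cohort generator with exact ground truth, so every stage is
  testable offline.

Everything takes a data frame first and returns a tibble; results have
`autoplot()`, `tidy()` and `glance()` methods, and `run_pipeline()` /
the `exec/mutscape` script orchestrate the stages from one YAML config.

## Worked example

Simulate a panel-shaped cohort (905 lines, 20 cell types), filter it, and
compute family frequencies:

```r
library(mutscape)

spec    <- generator_spec(seed = 2026)
cohort  <- generate_cohort(spec)
filtered <- filter_records(cohort$mutations)
staged  <- relabel_and_threshold_cell_types(filtered$records, cohort$annotations)
tidy(filtered)
#> # A tibble: 4 × 3
#>   filter_name          records_in records_out
#>   <chr>                     <int>       <int>
#> 1 noncoding                  2213        2116
#> 2 silent                     2116        2019
#> 3 low_allelic_fraction       2019        1961
#> 4 notch4_repeat_window       1961        1942
```

The four decoy classes injected by the generator (97 intronic, 97 silent,
58 low-AF, 19 NOTCH4-window records) are recovered by the cascade exactly.

```r
models <- read_gene_models()
frequency_table(staged$records, staged$annotations,
                default_families()[c("NOTCH", "RAS", "TP53")],
                gene_models = models, normalize = "per_kbp")
#> # A tibble: 3 × 7
#>   unit  stratum n_mutated_lines n_lines frequency_pct per_kbp_pct
#> 1 NOTCH ALL                 178     905          19.7        2.80
#> 2 RAS   ALL                 224     905          24.8       43.4
#> 3 TP53  ALL                 535     905          59.1       50.0
```

19.7% of lines carry a Notch-receptor mutation — in the same range as the
RAS family (24.8%) on the raw scale, but an order of magnitude lower per
kilobase of coding sequence, because the receptors are ~7.5 kbp against
RAS's 0.57 kbp. The hotspot scan on receptor records recovers the injected
NOTCH3 frameshift cluster:

```r
notch <- dplyr::filter(staged$records, gene_symbol %in% paste0("NOTCH", 1:4))
hotspot_scan(notch)
#> # A tibble: 1 × 4
#>   gene_symbol protein_position classification n_records
#> 1 NOTCH3                  1802 frameshift             3

multi_mutation_fraction(staged$records, staged$annotations,
                        gene_family("NOTCH", paste0("NOTCH", 1:4)))
#> # A tibble: 1 × 5
#>   unit  stratum n_multi_lines n_lines fraction_pct
#> 1 NOTCH ALL                50     905         5.52
```

For real data, point `read_mutation_table(path, dialect = "ccle_maf")` at a
panel MAF and drive everything from a config:

```sh
exec/mutscape run --config analysis.yaml
```

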