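---
title: "Profiling the mutation landscape of a cell-line panel: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the mutation landscape of a cell-line panel: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutscape)
```

## The analysis

`mutscape` profiles somatic mutation landscapes of cancer cell-line panels
from MAF-like mutation tables — one row per mutation call, annotated with a
gene symbol, a sample, a variant classification and a protein change in
HGVS-p short form. The workflow it implements is the one used for
hybrid-capture panels such as the Cancer Cell Line Encyclopedia, where Notch
receptor genes turn out to be mutated at frequencies comparable to
established oncogenes, and more often in cell lines than in the matched
primary-tumor cohorts:

1. **Filtering.** Record-level filters remove what should not enter any
   frequency: intronic calls and calls without a usable protein position,
   synonymous (silent) changes, calls with an allelic fraction below a floor
   (default 0.10, the upstream hybrid-capture threshold), and NOTCH4 calls
   inside its exon-1 (CTG)n repeat window — a common polymorphism encoding a
   polyleucine tract, not a somatic event. Cohort-level steps then rewrite
   panel barcodes (`haematopoietic_and_lymphoid_tissue` to `blood`, `skin`
   to `melanoma`) and drop cell types with fewer than 5 cell lines. Every
   step is reported with chained in/out counts, so decoy injections in
   synthetic data are auditable to the record.

2. **Frequencies.** The central statistic is the *gene-family mutation
   frequency*: the percentage of cell lines carrying at least one mutation
   in any family member, counting each line at most once. The denominator
   is always the number of annotated cell lines in the stratum, mutated or
   not. Because a large coding region accumulates more mutations at equal
   per-base rates, frequencies are also reported length-normalized:
   `%/kbp = frequency / (mean family CDS length / 1000)`. Mutation-type and
   per-receptor distributions, by contrast, use *all* mutation records
   (no per-line deduplication); splice and unclassifiable records count
   toward "is this line mutated" but are excluded from the four-class type
   distribution (missense, nonsense, frameshift, in-frame indel), with
   their count reported.

3. **Domain mapping.** Protein positions are 1-based and domain intervals
   closed on both ends, so a boundary residue belongs to its domain; models
   are validated to be non-overlapping at load, which makes assignment a
   partition of the sequence. Region fractions (share of a gene's
   positioned mutations inside the EGF repeats, the negative regulatory
   region NRR = LNR + HD, or the PEST degron) use all positioned records in
   the denominator. Frameshift and nonsense records are mapped by their
   start position even though they affect everything downstream — this
   matches positional (lollipop) plotting. A cysteine scan flags
   missense records gaining or losing a cysteine inside a region (the
   CADASIL hallmark in NOTCH3 EGF repeats), and a hotspot scan reports
   recurrent (gene, position, classification) groups, by default those seen
   three or more times.

4. **Impact and copy number.** subPSEC-style conservation scores (0 neutral
   to −10 deleterious) are consumed through a scored-records table; the
   package deliberately does not reimplement PANTHER's scoring. The cutoff
   is a strict "below −3": a score of exactly −3 is *not* deleterious. A
   deterministic, range-correct mock scorer ships for tests and is labelled
   synthetic — it is not a predictor. Discrete GISTIC-style copy-number
   calls are likewise inputs; "amplified" means call +2 and "deleted" call
   −2 only, single-copy gains and losses are ignored.

5. **Cohort comparison.** Cell-line and primary-tumor cohorts in the same
   schema are paired stratum by stratum (twelve default pairings with the
   documented tumor-cohort sizes), and per-(family, cell type) differences
   Δ% = cell-line − tumor frequency are computed along with
   Δ%/10 kbp, then ranked by the normalized value with deterministic
   alphabetical tie-breaks. The identical max-one-mutation-per-line rule is
   applied to both cohorts. Negative deltas are meaningful — melanoma-like
   strata can be more mutated in primary tumors.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| allelic-fraction floor | 0.10 | fraction | upstream hybrid-capture filter; re-application is a no-op on compliant input |
| minimum lines per cell type | 5 | cell lines | strata below this give unstable percentages; the threshold counts lines, not mutated lines |
| NOTCH4 exon-1 window | aa 1–60 | amino acids | covers the N-terminal leucine repeat tract; configurable because the polymorphism is cited by locus, not coordinates |
| subPSEC cutoff | −3 (strict) | score | conventional functional-significance threshold |
| hotspot minimum | 3 | records | below three recurrences a "cluster" is indistinguishable from chance at panel scale |
| GISTIC calls counted | ±2 | call | "high-level" events only |

The gene-model config is data, not code. The shipped default
(`inst/extdata/gene_models.yaml`) uses canonical-transcript protein lengths
with `cds_length_bp = 3 × (protein_length_aa + 1)` and *approximate* domain
boundaries; NOTCH1's EGF repeats are laid out as 36 equal-width intervals
across the EGF region so that per-repeat statements ("EGF repeats 11 and
15") are expressible. Analyses that hinge on exact boundaries should supply
their own config — every pipeline computation reads it from the file, never
from constants.

## What the synthetic generator emulates — and what it does not

The generator (`generator_spec()`, `generate_cohort()`) draws a
panel-shaped cohort: 20 cell-type strata totalling 905 lines, per-gene
per-line mutation probabilities, a classification mixture, uniform protein
positions apart from configurable hotspot mass, allelic fractions above the
floor, and appended decoy records (intronic, silent, low-AF, NOTCH4-window)
whose counts are recorded as ground truth. Its defaults encode the reported
headline marginals of the real panel as study conditions, fixed once by
design: NOTCH1 at p = 0.073; NOTCH2–4 at p = 0.05 so the four-receptor
family frequency is 1 − (1 − 0.073)(1 − 0.05)³ ≈ 20.5%; a second-mutation
probability of 0.175 so ≈5% of lines carry two or more family records;
TP53 at 0.60; three RAS genes at 0.097 (family ≈ 26.4%); four ERBB
receptors at 0.060 (≈ 21.8%); APC at 0.155; two Patched genes at 0.054
(≈ 10.5%); ligands between 0.029 and 0.05; housekeeping controls at 0.01;
and a NOTCH3 frameshift hotspot at aa 1802. The paired tumor generator
subtracts a margin (default 0.1, floored at zero) from each paired
stratum's probabilities, with lung at 0 and melanoma at −0.05 to emulate
the observed equal-frequency and tumor-higher strata.

The generator is deliberately *not* a model of real mutational processes:
positions are uniform within a protein (no domain enrichment, so the
NOTCH1 EGF share under the default model is simply the EGF span share,
≈55%, not the empirically enriched value), there are no mutational
signatures, no trinucleotide context, no sample purity effects, and decoys
are independent of true records. Passing tests on synthetic cohorts
therefore certify the *bookkeeping* — deduplication, denominators, filter
audit trails, normalization arithmetic, recovery of injected structure —
not biological realism. Reproducing the published numbers from the real
archived panel additionally requires that archive as input (see the
acceptance test), since it cannot be redistributed with the package.

## Numerical and design choices

* **"Non-synonymous" filter wording.** The source protocol's filter list
  reads as removing non-synonymous mutations, which would contradict every
  downstream statistic (all analysed classes are protein-altering). The
  pipeline treats it as removing *synonymous* records.
* **Splice records** are kept by default (configurable), count toward
  family frequencies, and stay outside the four-class type distribution.
* **Degenerate inputs.** Empty strata yield all-`NA` distributions flagged
  `empty`, not errors; a gene absent from a CNA table yields a flagged row
  with `n_samples = 0`; unparseable protein changes degrade to `unknown`
  because real MAFs carry nulls for intronic calls. Filters are total and
  idempotent.
* **Determinism.** One seeded RNG stream per generated cohort (restored on
  exit, so callers' streams are untouched); hotspot and ranking outputs
  have total, deterministic orderings; reruns of the pipeline are
  byte-identical, which the tests assert via golden files.
* **Problem sizes in the test-suite** were chosen for tightness of the
  statistical bounds at small cost: 500 eight-line cohorts for the
  deduplication oracle, a (p, n) grid up to n = 900 for parameter recovery
  at the 3·SE binomial bound, 200 cohorts for distribution closure at
  1e−9, 100 fixtures for the exact filter audit, and 200 samples per
  stratum for cohort-delta recovery.

## Limitations

* Domain boundaries in the shipped config are approximations; per-repeat
  EGF statistics are only as good as the interval layout.
* subPSEC scores and GISTIC calls are consumed, not computed; conclusions
  inherit the upstream tools' assumptions.
* The tumor comparison reports no significance tests, mirroring the
  descriptive design of the original analysis; with the default cohort
  sizes a delta of a few percentage points is within sampling noise.
* Frequencies use annotated lines as denominators; panels with per-line
  coverage masks would need those masks applied upstream.
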