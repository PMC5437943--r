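# oncotally

Cohort-scale somatic mutation tabulation, consensus calling and
gene-centric visualization layouts for cancer genomics.

Somatic variant-calling pipelines for tumor cohorts wrap a handful of
bespoke computations around the callers themselves, and those are what
this package implements as plain, testable R:

* **Interval planning** for scatter/gather parallelization. Chromosomes
  are never split (callers may depend on intrachromosomal context), so
  scattering a per-chromosome caller reduces to grouping whole
  chromosomes. `plan_intervals()` packs them by first-fit-decreasing bin
  packing with capacity equal to the longest chromosome — pairing a
  large with a small chromosome whenever their sum fits is the classic
  special case — so no group outlasts the unavoidable longest job while
  the number of concurrent jobs shrinks. `merge_variant_outputs()`
  gathers per-group VCFs back into one sorted, deduplicated document.
* **k-of-n ensemble consensus** of somatic calls. `consensus_vote()`
  counts, per trim-normalized variant key (chrom, pos, REF, ALT), how
  many of *n* callers report it and keeps keys with at least *k*
  supporters: `k = 1` is the union, `k = n` the intersection, and the
  default `k = 2` the smallest non-trivial consensus. Output VCFs carry
  `CALLERS` and `NCALLERS` INFO annotations.
* **Cohort aggregation** of MAF and segmented copy-number data.
  `build_mutation_matrix()` tabulates a cohort MAF into a gene × patient
  matrix (all classifications per cell plus the worst under a fixed
  severity ranking); `gene_copy_states()` assigns each gene the log2
  ratio of its maximal-overlap segment, thresholded into the five
  ordinal states −2..+2 (GISTIC-style integer calls are accepted
  directly); `mutation_spectrum()` computes the six pyrimidine-collapsed
  substitution classes per patient; `summarize_cohort()` produces exact
  cohort tallies and gene-cloud weights.
* **Gene-centric circular layouts**. `oncocircos()` eliminates
  intergenic space and sub-threshold genes, gives every retained gene a
  unit slot in genomic order, and emits a Circos-dialect text bundle:
  pseudo-karyotype, stacked per-severity SNV bars, a total-count circle
  track, three inner copy-number tracks (gain fraction, loss fraction,
  mean state) and a label track where genes at twice the display
  threshold are bold and highlight-list/region genes are colored.
* **Oncoprints and molecular subgroups**. `build_oncoprint()` assembles
  the gene × patient matrix with burden, subgroup, recurrence and
  externally supplied significance covariates; samples order by the
  classic mutual-exclusivity ("memo") sort, by predicted subgroup
  blocks, or by any given permutation. `classify_subgroups()` labels
  each patient ABC, GCB or U (unclassifiable) by majority count of
  mutated subgroup-unique marker genes, ties and zero evidence going
  to U.
* **A seeded synthetic-cohort generator**. `cohort_design()` /
  `generate_cohort()` plant a full truth bundle — genome, gene table,
  drivers, passengers, subgroup markers consistent with planted labels,
  recurrent CNV regions, imperfect callers with false positives — so the
  entire pipeline is testable at desk scale with known answers.

Everything is tidyverse-native: readers return tibbles, analysis
functions take the data frame first and pipe, result objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_spectrum()` figures.

## Worked example

Simulate a 20-patient cohort, vote 2-of-3 consensus per patient,
aggregate, and lay the cohort out:

```r
library(oncotally)
library(dplyr)

design <- cohort_design(seed = 42, n_patients = 20, passenger_rate = 12)
truth  <- generate_cohort(design)
truth
#> Synthetic cohort: 20 patient(s), 320 truth variant(s), 42 CNV hit(s)

calls <- emit_caller_vcfs(truth)          # 3 callers at sensitivity 0.9
glance(consensus_vote(filter(calls, patient == "P001"), k = 2,
                      chrom_order = truth$chrom_table))
#> # A tibble: 1 × 4
#>   n_variants     k n_callers mean_support
#>        <int> <int>     <int>        <dbl>
#> 1         15     2         3         2.93
```

Fifteen of patient P001's calls survive 2-of-3 voting, supported by 2.93
callers on average. Aggregating the cohort MAF and copy-number segments:

```r
maf <- emit_maf(truth)
m <- build_mutation_matrix(maf) %>%
  add_copy_number(gene_copy_states(emit_seg(truth), truth$gene_table))
glance(m)
#> # A tibble: 1 × 5
#>   n_genes n_patients n_mutated_cells n_mutations has_copy_number
#>     <int>      <int>           <int>       <int> <lgl>
#> 1     200         20             311         320 TRUE

retained <- apply_gene_filters(m, min_patients = 4,
                               gene_table = truth$gene_table,
                               chrom_order = truth$chrom_table)
head(retained, 3)
#> # A tibble: 3 × 6
#>   gene    patient_count mutation_count chrom start   end
#>   <chr>           <int>          <int> <chr> <int> <int>
#> 1 GENE001            10             10 chr1   4375  7375
#> 2 GENE006            10             11 chr1  21875 24875
#> 3 GENE011             4              4 chr1  39375 42375
```

Fifteen genes clear the 4-patient display threshold; the planted drivers
(mutated in 4–11 of 20 patients) top the list in genomic order. The
circular layout and its labels follow the bold-at-twice-threshold rule:

```r
bundle <- oncocircos(maf, truth$gene_table, min_patients = 4,
                     seg = emit_seg(truth),
                     chrom_order = truth$chrom_table)
bundle
#> Circos bundle: 8 document(s) (karyotype, snv_stacked, snv_total,
#>   cn_gain, cn_loss, cn_mean, labels, circos.conf)
head(bundle$labels, 3)
#> [1] "chr1 0 1 GENE001 label_font=bold"
#> [2] "chr1 1 2 GENE006 label_font=bold"
#> [3] "chr1 2 3 GENE011 label_font=normal"
```

GENE001 (10 ≥ 2×4 patients) is bold, GENE011 (4 < 8) is not. Finally,
classifying patients on the planted subgroup markers recovers every
label:

```r
abc <- truth$gene_table$symbol[9:11]   # ABC-unique markers in this design
gcb <- truth$gene_table$symbol[12:14]  # GCB-unique markers
sg <- classify_subgroups(m, abc, gcb)
table(planted = as.character(truth$labels$subgroup),
      called = as.character(sg$subgroup))
#>        called
#> planted ABC GCB U
#>     ABC   9   0 0
#>     GCB   0   8 0
#>     U     0   0 3
```

`build_oncoprint(m, genes = retained$gene, sample_order = "subgroup",
subgroups = sg)` then yields the subgroup-blocked oncoprint;
`autoplot()` draws it and `write_oncoprint()` emits the TSV bundle.

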