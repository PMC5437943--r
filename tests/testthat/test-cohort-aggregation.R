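maf_row <- function(gene, patient, class, type = "SNP",
                    ref = "C", alt = "T") {
  tibble::tibble(
    Hugo_Symbol = gene, Chromosome = "chr1", Start_Position = 1L,
    End_Position = 1L, Reference_Allele = ref, Tumor_Seq_Allele2 = alt,
    Variant_Classification = class, Variant_Type = type,
    Tumor_Sample_Barcode = patient
  )
}

test_that("mutation matrix cells track classes and worst severity", {
  one <- build_mutation_matrix(maf_row("TP53", "S1", "Missense_Mutation"))
  expect_equal(one$genes, "TP53")
  expect_equal(one$snv$worst, "Missense_Mutation")
  expect_equal(one$gene_stats$patient_count, 1L)

  two <- build_mutation_matrix(dplyr::bind_rows(
    maf_row("KMT2D", "S1", "Silent"),
    maf_row("KMT2D", "S1", "Nonsense_Mutation")
  ))
  cell <- two$snv
  expect_equal(cell$worst, "Nonsense_Mutation")
  expect_equal(cell$n_mutations, 2L)
  expect_equal(two$gene_stats$mutation_count, 1L) # silent not counted
  expect_equal(two$gene_stats$patient_count, 1L)
  with_silent <- build_mutation_matrix(dplyr::bind_rows(
    maf_row("KMT2D", "S1", "Silent"),
    maf_row("KMT2D", "S1", "Nonsense_Mutation")
  ), include_silent = TRUE)
  expect_equal(with_silent$gene_stats$mutation_count, 2L)

  empty <- build_mutation_matrix(maf_row("X", "S1", "Silent")[0, ])
  expect_length(empty$genes, 0)
  expect_equal(nrow(empty$snv), 0)
})

test_that("worst-severity cell equals a brute-force maximum over ranks", {
  set.seed(9)
  sev <- severity_ranks()
  for (i in 1:20) {
    maf <- random_maf(n = 60)
    m <- build_mutation_matrix(maf, include_silent = TRUE)
    # conservation: cell counts sum to the record count
    expect_equal(sum(m$snv$n_mutations), nrow(maf))
    expect_equal(sum(m$gene_stats$mutation_count), nrow(maf))
    # every cell's worst equals the min rank of its records
    for (j in sample.int(nrow(m$snv), 5)) {
      cell <- m$snv[j, ]
      recs <- maf$Variant_Classification[
        maf$Hugo_Symbol == cell$gene &
          maf$Tumor_Sample_Barcode == cell$patient
      ]
      expect_equal(
        sev$rank[match(cell$worst, sev$classification)],
        min(sev$rank[match(recs, sev$classification)])
      )
    }
  }
})

test_that("log2 thresholds map to ordinal states with inclusive boundaries", {
  expect_equal(cn_state_from_log2(c(-1.3, -1, -0.25, -0.24, 0,
                                    0.24, 0.25, 1, 1.3)),
               c(-2L, -2L, -1L, 0L, 0L, 0L, 1L, 2L, 2L))
  expect_error(cn_state_from_log2(0, thresholds = c(-1, 0.1, 0.2, 1)),
               class = "oncotally_validation_error")
})

test_that("segment-to-gene assignment follows maximal overlap with extreme tie-break", {
  genes <- tibble::tibble(symbol = "G1", chrom = "chr1",
                          start = 100L, end = 200L)
  # fully inside one deep-loss segment
  seg <- tibble::tibble(sample_id = "S1", chrom = "chr1", start = 0L,
                        end = 1000L, n_markers = NA_integer_,
                        log2_ratio = -1.3)
  expect_equal(gene_copy_states(seg, genes)$state, -2L)
  # split 60/40: max overlap wins
  seg2 <- tibble::tibble(
    sample_id = "S1", chrom = "chr1", start = c(0L, 160L),
    end = c(160L, 400L), n_markers = NA_integer_,
    log2_ratio = c(0.5, -0.5)
  )
  expect_equal(gene_copy_states(seg2, genes)$state, 1L)
  # no segments at all -> neutral
  none <- gene_copy_states(seg[0, ], genes, patients = "S1")
  expect_equal(none$state, 0L)
  # 50/50 tie -> more extreme state
  seg3 <- tibble::tibble(
    sample_id = "S1", chrom = "chr1", start = c(0L, 150L),
    end = c(150L, 400L), n_markers = NA_integer_,
    log2_ratio = c(0.3, -1.4)
  )
  expect_equal(gene_copy_states(seg3, genes)$state, -2L)
})

test_that("gene states equal the per-base overlap oracle on random fixtures", {
  set.seed(17)
  for (i in 1:20) {
    genes <- tibble::tibble(
      symbol = paste0("G", 1:4), chrom = sample(c("c1", "c2"), 4,
                                                replace = TRUE),
      start = sample.int(8000, 4)
    ) %>% mutate(end = start + sample.int(2000, 4))
    seg <- dplyr::bind_rows(lapply(c("S1", "S2"), function(p) {
      n <- sample.int(8, 1)
      starts <- sort(sample.int(9000, n))
      ends <- pmin(starts + sample.int(1500, n), 10000)
      # clip to keep same-sample segments non-overlapping
      ends <- pmin(ends, c(starts[-1], 10000L))
      tibble::tibble(sample_id = p, chrom = sample(c("c1", "c2"), 1),
                     start = starts, end = ends,
                     n_markers = NA_integer_,
                     log2_ratio = round(rnorm(n, 0, 0.8), 3))
    })) %>% filter(end > start)
    got <- gene_copy_states(seg, genes) %>%
      arrange(gene, patient) %>% select(gene, patient, state)
    want <- cn_state_oracle(seg, genes) %>% arrange(gene, patient)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("GISTIC integer calls map directly onto states", {
  calls <- tibble::tibble(gene = c("A", "B"), patient = "S1",
                          state = c(-2L, 0L))
  out <- accept_gistic_states(calls)
  expect_equal(out$state, c(-2L, 0L))
  expect_error(
    accept_gistic_states(tibble::tibble(gene = "A", patient = "S1",
                                        state = 3L)),
    class = "oncotally_validation_error"
  )
})

test_that("gene filtering applies threshold, blacklist and genomic order", {
  maf <- dplyr::bind_rows(lapply(1:5, function(i) {
    dplyr::bind_rows(
      maf_row("A", paste0("S", i), "Missense_Mutation"),
      maf_row("C", paste0("S", i), "Missense_Mutation"),
      if (i <= 2) maf_row("B", paste0("S", i), "Missense_Mutation")
    )
  }))
  m <- build_mutation_matrix(maf)
  kept <- apply_gene_filters(m, min_patients = 3, blacklist = "C")
  expect_equal(kept$gene, "A")
  expect_setequal(apply_gene_filters(m, 1)$gene, c("A", "B", "C"))
  expect_equal(nrow(apply_gene_filters(m, 1,
                                       blacklist = c("A", "B", "C"))), 0)
  # monotone: raising the threshold never adds genes
  for (t in 1:6) {
    hi <- apply_gene_filters(m, t)$gene
    lo <- apply_gene_filters(m, max(t - 1, 1))$gene
    expect_true(all(hi %in% lo))
  }
  # genomic ordering with a gene table
  gt <- tibble::tibble(symbol = c("A", "B", "C"),
                       chrom = c("chr2", "chr1", "chr1"),
                       start = c(5L, 100L, 7L), end = c(6L, 101L, 8L))
  co <- tibble::tibble(chrom = c("chr1", "chr2"), length = 1000L)
  kept <- apply_gene_filters(m, 1, gene_table = gt, chrom_order = co)
  expect_equal(kept$gene, c("C", "B", "A"))
})

test_that("spectrum collapses to pyrimidine classes and conserves counts", {
  maf <- dplyr::bind_rows(
    maf_row("X", "S1", "Missense_Mutation", ref = "G", alt = "A"),
    maf_row("X", "S1", "Missense_Mutation", ref = "C", alt = "T"),
    maf_row("X", "S1", "Silent", ref = "T", alt = "G"),
    maf_row("Y", "S2", "Missense_Mutation", ref = "A", alt = "C")
  )
  sp <- mutation_spectrum(maf)
  expect_equal(sp$n[sp$patient == "S1" & sp$class == "C>T"], 2L)
  expect_equal(sp$n[sp$patient == "S2" & sp$class == "T>G"], 1L)
  expect_equal(sum(sp$n[sp$patient == "S1"]), 3L)
  expect_setequal(unique(sp$class), spectrum_classes())

  # strand invariance: complementing every record leaves counts unchanged
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(23)
  for (i in 1:10) {
    maf <- random_maf(n = 40)
    flipped <- maf %>%
      mutate(Reference_Allele = unname(comp[Reference_Allele]),
             Tumor_Seq_Allele2 = unname(comp[Tumor_Seq_Allele2]))
    expect_equal(mutation_spectrum(maf), mutation_spectrum(flipped),
                 ignore_attr = TRUE)
    expect_equal(sum(mutation_spectrum(maf)$n), nrow(maf))
  }
  # non-ACGT SNP alleles are skipped with a warning
  odd <- maf_row("X", "S1", "Missense_Mutation", ref = "N", alt = "A")
  odd$Variant_Type <- "SNP"
  expect_warning(sp <- mutation_spectrum(odd), "skipped")
  expect_equal(sum(sp$n), 0L)
})

test_that("cohort summaries are exact tallies", {
  maf <- random_maf(n = 80)
  s <- summarize_cohort(maf, top_n = 3, genecloud_min = 2)
  expect_equal(sum(s$classification_counts$n), nrow(maf))
  expect_equal(sum(s$type_counts$n), nrow(maf))
  expect_equal(sum(s$burden$n_mutations), nrow(maf))
  expect_lte(nrow(s$top_genes), 3)
  expect_true(all(s$genecloud$weight >= 2))
  # threshold beyond cohort size -> empty weights
  expect_equal(nrow(summarize_cohort(maf, genecloud_min = 100)$genecloud), 0)
  single <- summarize_cohort(maf_row("TP53", "S1", "Missense_Mutation"))
  expect_equal(single$burden$n_mutations, 1L)
  expect_equal(single$classification_counts$n, 1L)
  g <- glance(single)
  expect_equal(g$n_mutations, 1L)
})
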