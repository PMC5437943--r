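retained_fixture <- function() {
  tibble::tibble(
    gene = c("G1", "G2", "G3", "G4"),
    patient_count = c(10L, 4L, 9L, 12L),
    mutation_count = c(15L, 4L, 11L, 20L),
    chrom = c("chr1", "chr1", "chr1", "chr5"),
    start = c(10L, 50L, 90L, 5L),
    end = c(20L, 60L, 100L, 15L)
  )
}

test_that("pseudo-karyotype allocates one unit slot per retained gene", {
  k <- build_gene_karyotype(retained_fixture())
  expect_equal(k$chromosomes$chrom, c("chr1", "chr5"))
  expect_equal(k$chromosomes$n_genes, c(3L, 1L))
  # slot conservation
  expect_equal(sum(k$chromosomes$n_genes), 4L)
  expect_equal(k$slots$slot_start[k$slots$chrom == "chr1"], 0:2)
  expect_equal(k$slots$slot_end - k$slots$slot_start, rep(1L, 4))
  # genomic order within chromosome
  expect_equal(k$slots$gene[k$slots$chrom == "chr1"],
               c("G1", "G2", "G3"))
  one <- build_gene_karyotype(retained_fixture()[1, ])
  expect_equal(one$chromosomes$n_genes, 1L)
  expect_error(build_gene_karyotype(retained_fixture()[0, ]),
               class = "oncotally_validation_error")
})

circos_cohort <- function(seed = 77) {
  d <- small_design(seed = seed, n_patients = 12)
  tr <- generate_cohort(d)
  maf <- emit_maf(tr)
  list(truth = tr, maf = maf,
       bundle = oncocircos(maf, tr$gene_table, min_patients = 2,
                           seg = emit_seg(tr),
                           chrom_order = tr$chrom_table))
}

test_that("stacked SNV values conserve counts and order by severity", {
  maf <- dplyr::bind_rows(
    lapply(c("S1", "S2", "S3"), function(p) {
      tibble::tibble(
        Hugo_Symbol = "G1", Chromosome = "chr1",
        Start_Position = 1L, End_Position = 1L,
        Reference_Allele = "C", Tumor_Seq_Allele2 = "T",
        Variant_Classification = "Missense_Mutation",
        Variant_Type = "SNP", Tumor_Sample_Barcode = p
      )
    })
  )
  maf <- dplyr::bind_rows(
    maf, maf[1, ] %>%
      dplyr::mutate(Variant_Classification = "Nonsense_Mutation")
  )
  m <- build_mutation_matrix(maf)
  retained <- retained_fixture()[1, ] %>% dplyr::mutate(gene = "G1")
  k <- build_gene_karyotype(retained)
  snv <- build_snv_track(m, k)
  # severity order: nonsense (1 patient) before missense (3 patients)
  expect_equal(snv$stacked$classification,
               c("Nonsense_Mutation", "Missense_Mutation"))
  expect_equal(snv$stacked$value, c(1L, 3L))
  expect_equal(snv$total$value, 3L) # distinct patients
  snv_m <- build_snv_track(m, k, unit = "mutations")
  expect_equal(sum(snv_m$stacked$value), nrow(maf))
})

test_that("copy-number tracks report gain/loss fractions and mean state", {
  m <- build_mutation_matrix(
    tibble::tibble(
      Hugo_Symbol = "G1", Chromosome = "chr1", Start_Position = 1L,
      End_Position = 1L, Reference_Allele = "C", Tumor_Seq_Allele2 = "T",
      Variant_Classification = "Missense_Mutation", Variant_Type = "SNP",
      Tumor_Sample_Barcode = paste0("S", 1:4)
    )
  )
  cn <- tibble::tibble(
    gene = "G1", patient = paste0("S", 1:4), state = c(2L, 2L, 0L, 0L)
  )
  m <- add_copy_number(m, cn)
  k <- build_gene_karyotype(
    tibble::tibble(gene = "G1", patient_count = 4L, chrom = "chr1",
                   start = 1L)
  )
  tracks <- build_cn_tracks(m, k)
  expect_equal(tracks$gain_fraction, 0.5)
  expect_equal(tracks$loss_fraction, 0)
  expect_equal(tracks$mean_state, 1.0)
  # all-neutral gene sits at zero everywhere
  m2 <- add_copy_number(m, cn %>% dplyr::mutate(state = 0L))
  expect_equal(unlist(build_cn_tracks(m2, k)[
    , c("gain_fraction", "loss_fraction", "mean_state")
  ]), c(gain_fraction = 0, loss_fraction = 0, mean_state = 0))
  # fractions bounded on random cohorts
  cc <- circos_cohort()
  for (t in c("cn_gain", "cn_loss")) {
    vals <- as.numeric(sub(".* ", "", cc$bundle[[t]]))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("labels are bold exactly at twice the threshold and color highlights", {
  k <- build_gene_karyotype(retained_fixture())
  lab <- style_labels(k, retained_fixture(), min_patients = 5,
                      highlight = "G3")
  expect_equal(lab$bold[lab$gene == "G1"], TRUE)   # 10 == 2*5 boundary
  expect_equal(lab$bold[lab$gene == "G3"], FALSE)  # 9 < 10
  expect_true(lab$highlight[lab$gene == "G3"])
  expect_true(lab$bold[lab$gene == "G4"] && !lab$highlight[lab$gene == "G4"])
  expect_warning(style_labels(k, retained_fixture(), 5,
                              highlight = "NOT_THERE"), "ignored")
  # region-based highlighting: genes overlapping a recurrent-CNV region
  lab2 <- style_labels(
    k, retained_fixture(), 5,
    regions = tibble::tibble(chrom = "chr1", start = 55L, end = 95L)
  )
  expect_equal(lab2$gene[lab2$highlight], c("G2", "G3"))
})

test_that("bundle re-emission is byte-identical with full referential integrity", {
  cc <- circos_cohort()
  bundle <- cc$bundle
  expect_named(bundle, c("karyotype", "snv_stacked", "snv_total",
                         "cn_gain", "cn_loss", "cn_mean", "labels",
                         "circos.conf"))
  # determinism
  again <- oncocircos(cc$maf, cc$truth$gene_table, min_patients = 2,
                      seg = emit_seg(cc$truth),
                      chrom_order = cc$truth$chrom_table)
  expect_identical(unclass(bundle)[names(bundle)],
                   unclass(again)[names(again)])
  # slot conservation
  kary <- bundle$karyotype
  ends <- as.integer(sub(".* (\\d+) grey$", "\\1", kary))
  expect_equal(sum(ends), nrow(attr(bundle, "retained")))
  # referential integrity: every data line references a karyotype
  # chromosome and a valid slot
  kchrom <- sub("^chr - (\\S+).*", "\\1", kary)
  kend <- stats::setNames(ends, kchrom)
  for (t in c("snv_stacked", "snv_total", "cn_gain", "cn_loss",
              "cn_mean", "labels")) {
    parts <- strsplit(bundle[[t]], " ")
    chroms <- vapply(parts, `[[`, character(1), 1)
    s <- as.integer(vapply(parts, `[[`, character(1), 2))
    e <- as.integer(vapply(parts, `[[`, character(1), 3))
    expect_true(all(chroms %in% kchrom))
    expect_true(all(s >= 0 & e <= kend[chroms] & e == s + 1))
  }
  # every track file referenced exactly once in the conf
  conf <- bundle$circos.conf
  for (t in c("snv_stacked", "snv_total", "cn_gain", "cn_loss",
              "cn_mean", "labels")) {
    expect_equal(sum(grepl(paste0("^file = ", t, ".txt$"), conf)), 1)
  }
  # writing produces the files
  dir <- withr::local_tempdir()
  paths <- write_circos_bundle(bundle, dir)
  expect_true(all(file.exists(paths)))
  expect_equal(readLines(file.path(dir, "karyotype.txt")), kary)
})

test_that("bold set matches the rule and the karyotype shrinks monotonically", {
  cc <- circos_cohort()
  tr <- cc$truth
  m <- build_mutation_matrix(cc$maf)
  prev_genes <- Inf
  for (minp in 1:4) {
    retained <- apply_gene_filters(m, minp, gene_table = tr$gene_table,
                                   chrom_order = tr$chrom_table)
    if (nrow(retained) == 0) break
    k <- build_gene_karyotype(retained, tr$chrom_table)
    lab <- style_labels(k, retained, minp)
    want_bold <- retained$gene[retained$patient_count >= 2 * minp]
    expect_setequal(lab$gene[lab$bold], want_bold)
    expect_lte(nrow(k$slots), prev_genes)
    prev_genes <- nrow(k$slots)
  }
})
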