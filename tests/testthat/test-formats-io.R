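test_that("chrom.sizes and SAM header dialects parse to the same table", {
  two_col <- read_chrom_sizes("chr1\t100\nchr2\t60")
  expect_equal(two_col$chrom, c("chr1", "chr2"))
  expect_equal(two_col$length, c(100L, 60L))

  sam <- read_chrom_sizes(
    "@HD\tVN:1.6\n@SQ\tSN:chr1\tLN:100\n@SQ\tSN:chr2\tLN:60\n@PG\tID:x",
    dialect = "sam_header"
  )
  expect_equal(sam, two_col)
})

test_that("malformed chromosome tables raise classified errors with line numbers", {
  expect_error(read_chrom_sizes("chr1\tNaN"),
               class = "oncotally_parse_error")
  expect_error(read_chrom_sizes("chr1\tNaN"), "line 1")
  expect_error(read_chrom_sizes("chr1\t0"), class = "oncotally_parse_error")
  expect_error(read_chrom_sizes("chr1\t10\twhat"),
               class = "oncotally_parse_error")
  expect_error(read_chrom_sizes("chr1\t10\nchr1\t20"),
               class = "oncotally_validation_error")
  expect_error(read_chrom_sizes("@PG\tID:x", dialect = "sam_header"),
               class = "oncotally_parse_error")
  expect_error(read_chrom_sizes("@SQ\tLN:10", dialect = "sam_header"),
               "SN")
})

maf_text <- paste(
  "#version 2.4",
  paste("Hugo_Symbol", "Chromosome", "Start_Position", "End_Position",
        "Reference_Allele", "Tumor_Seq_Allele2", "Variant_Classification",
        "Variant_Type", "Tumor_Sample_Barcode", "t_depth", sep = "\t"),
  "TP53\tchr17\t7577\t7577\tC\tT\tMissense_Mutation\tSNP\tS1\t88",
  "KMT2D\tchr12\t49420\t49420\tG\tA\tNonsense_Mutation\tSNP\tS2\t120",
  "B2M\tchr15\t45003\t45007\tACGTA\tA\tFrame_Shift_Del\tDEL\tS1\t64",
  sep = "\n"
)

test_that("MAF reader enforces schema, preserves extras and round-trips", {
  maf <- read_maf(maf_text)
  expect_equal(nrow(maf), 3)
  expect_equal(maf$Tumor_Sample_Barcode, c("S1", "S2", "S1"))
  expect_true("t_depth" %in% names(maf)) # extra column preserved
  expect_identical(read_maf(write_maf(maf)), maf)

  # header casing is tolerated
  recased <- sub("Hugo_Symbol", "hugo_symbol", maf_text)
  expect_equal(read_maf(recased)$Hugo_Symbol, maf$Hugo_Symbol)

  # empty data section
  empty <- read_maf(strsplit(maf_text, "\n")[[1]][2])
  expect_equal(nrow(empty), 0)

  expect_error(read_maf("Hugo_Symbol\tChromosome\nTP53\tchr17"),
               class = "oncotally_schema_error")
  bad_class <- sub("Missense_Mutation", "Nonsense", maf_text)
  expect_error(read_maf(bad_class), class = "oncotally_validation_error")
  bad_snp <- sub("C\tT\tMissense", "C\tC\tMissense", maf_text)
  expect_error(read_maf(bad_snp), class = "oncotally_validation_error")
})

test_that("SEG reader handles both IGV variants and converts coordinates", {
  six <- read_seg("S1\t1\t3218610\t4658610\t100\t0.45")
  expect_equal(six$log2_ratio, 0.45)
  expect_equal(six$n_markers, 100L)
  expect_equal(six$start, 3218609L) # half-open internal convention
  expect_equal(six$end, 4658610L)

  five <- read_seg("ID\tchrom\tloc.start\tloc.end\tseg.mean\nS1\t1\t10\t20\t-0.5")
  expect_true(is.na(five$n_markers))
  expect_equal(five$start, 9L)

  expect_identical(read_seg(write_seg(six)), six)
  expect_identical(read_seg(write_seg(five)), five)

  expect_error(read_seg("S1\t1\t10"), class = "oncotally_parse_error")
  expect_error(read_seg("S1\t1\t20\t10\t0.5"),
               class = "oncotally_validation_error")
  overlapping <- "S1\t1\t10\t30\t0.5\nS1\t1\t20\t40\t0.1"
  expect_error(read_seg(overlapping), class = "oncotally_validation_error")
  # same coordinates, different samples: fine
  expect_equal(nrow(read_seg("S1\t1\t10\t30\t0.5\nS2\t1\t20\t40\t0.1")), 2)
})

test_that("VCF sites reader/writer round-trips and validates alleles", {
  sites <- tibble::tibble(
    chrom = c("chr1", "chr2"), pos = c(5L, 9L), id = c(".", "rs1"),
    ref = c("A", "CT"), alt = c("T", "C"), qual = c(".", "50"),
    filter = c("PASS", "germline"), info = c("DP=10", ".")
  )
  lines <- write_vcf_sites(sites, chrom_order = tibble::tibble(
    chrom = c("chr1", "chr2"), length = c(100L, 100L)
  ))
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  expect_true(any(grepl("^##contig=<ID=chr1", lines)))
  expect_identical(read_vcf_sites(lines), sites)

  expect_error(read_vcf_sites("chr1\t5\t.\tA"),
               class = "oncotally_parse_error")
  expect_error(read_vcf_sites("chr1\tx\t.\tA\tT\t.\tPASS\t."),
               class = "oncotally_parse_error")
  expect_error(read_vcf_sites("chr1\t5\t.\tA\tZ\t.\tPASS\t."),
               class = "oncotally_validation_error")
  info <- vcf_info_to_list(c("DP=10;SOMATIC", "."))
  expect_equal(info[[1]][["DP"]], "10")
  expect_true("SOMATIC" %in% names(info[[1]]))
  expect_length(info[[2]], 0)
})

test_that("written VCF is parseable by an independent VCF library", {
  skip_if_not_installed("vcfR")
  sites <- tibble::tibble(
    chrom = c("chr1", "chr1"), pos = c(5L, 42L),
    ref = c("A", "G"), alt = c("T", "C"),
    filter = "PASS", info = c("NCALLERS=2", "NCALLERS=3")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_sites(sites, path, chrom_order = tibble::tibble(
    chrom = "chr1", length = 1000L
  ))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_equal(as.integer(vcfR::getPOS(v)), sites$pos)
  expect_equal(vcfR::getREF(v), sites$ref)
  expect_equal(vcfR::getALT(v), sites$alt)
})

test_that("gene tables and gene lists parse, validate and round-trip", {
  genes <- read_gene_table("chr1\t0\t100\tTP53\nchr2\t50\t80\tB2M")
  expect_equal(genes$symbol, c("TP53", "B2M"))
  expect_equal(genes$start, c(0L, 50L)) # BED stays 0-based
  expect_identical(read_gene_table(write_gene_table(genes)), genes)

  expect_error(read_gene_table("chr1\t0\t100"),
               class = "oncotally_parse_error")
  expect_error(read_gene_table("chr1\t100\t100\tX"),
               class = "oncotally_validation_error")
  expect_error(read_gene_table("chr1\t0\t1\tA\nchr2\t0\t1\tA"),
               class = "oncotally_validation_error")

  expect_equal(read_gene_list("# comment\nTTN\nMUC16\n\nTTN"),
               c("TTN", "MUC16"))
})

test_that("readers preserve record order on randomly generated files", {
  set.seed(42)
  for (i in 1:5) {
    maf <- random_maf(n = 30)
    expect_identical(read_maf(write_maf(maf)), maf)
    n <- 20
    seg <- tibble::tibble(
      sample_id = "S1", chrom = paste0("chr", 1:n),
      start = sample.int(1000, n), end = 0L,
      n_markers = sample.int(50, n),
      log2_ratio = round(rnorm(n), 4)
    ) %>% mutate(end = start + sample.int(500, n))
    expect_identical(read_seg(write_seg(seg)), seg)
  }
})

test_that("GISTIC wide tables pivot to long integer calls", {
  g <- read_gistic("Gene Symbol\tS1\tS2\nREL\t2\t0\nTP53\t-2\t-1")
  expect_equal(nrow(g), 4)
  expect_equal(g$state[g$gene == "REL" & g$patient == "S1"], 2L)
  expect_error(read_gistic("Gene\tS1\nREL\thigh"),
               class = "oncotally_parse_error")
})

test_that("chr prefix normalizer is explicit and exact elsewhere", {
  expect_equal(strip_chr_prefix(c("chr1", "2", "chrX")), c("1", "2", "X"))
})
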