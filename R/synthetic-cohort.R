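#' Describe a synthetic tumor cohort
#'
#' Fixes every parameter of a planted-truth cohort: a small multi-
#' chromosome genome, a gene table laid out with intergenic gaps, driver
#' genes mutated at a per-patient probability, a Poisson passenger load,
#' subgroup marker genes with planted ABC/GCB/U labels, recurrent
#' copy-number regions with a penetrance, and an ensemble of imperfect
#' callers (per-variant sensitivity plus Poisson false positives placed
#' in intergenic space, so truth and noise stay separable). The defaults
#' describe the cohort used throughout the package's examples and tests:
#' 50 patients, 5 chromosomes of 300-700 kb, 200 genes of 3 kb, 8 drivers
#' at probability 0.5, ~35 passengers per patient (about 2000 somatic
#' variants cohort-wide), 3 callers at sensitivity 0.9, noise-free
#' copy-number segments.
#'
#' @param seed Integer seed; the whole truth bundle is deterministic
#'   given this value.
#' @param n_patients Number of tumor/normal pairs to emulate.
#' @param chrom_lengths Named integer vector of chromosome sizes (bp).
#' @param n_genes Total genes placed on the genome.
#' @param gene_length Length of every gene body (bp).
#' @param driver_genes Number of driver genes (taken from the first gene
#'   slots).
#' @param driver_prob Per-patient probability that a driver is mutated.
#' @param passenger_rate Poisson mean of passenger mutations per patient.
#' @param n_abc_markers,n_gcb_markers Number of subgroup marker genes.
#' @param subgroup_probs Probabilities of planting an ABC, GCB or U label
#'   (must sum to 1).
#' @param cnv_regions Tibble `chrom`, `start`, `end`, `state`,
#'   `penetrance` of recurrent copy-number regions; `NULL` for a default
#'   set of five (two amplifications, one gain, one deep and one shallow
#'   deletion).
#' @param callers Tibble `caller`, `sensitivity`, `fp_rate` (Poisson mean
#'   of false-positive calls per patient); `NULL` for three callers at
#'   sensitivity 0.9 and fp_rate 3.
#' @param noise_sd Gaussian sd added to segment log2 means (0 = planted
#'   states are recovered exactly by thresholding).
#' @return A validated `cohort_design` list.
#' @export
cohort_design <- function(seed = 1L,
                          n_patients = 50L,
                          chrom_lengths = c(
                            chr1 = 700000L, chr2 = 600000L, chr3 = 500000L,
                            chr4 = 400000L, chr5 = 300000L
                          ),
                          n_genes = 200L,
                          gene_length = 3000L,
                          driver_genes = 8L,
                          driver_prob = 0.5,
                          passenger_rate = 35,
                          n_abc_markers = 3L,
                          n_gcb_markers = 3L,
                          subgroup_probs = c(ABC = 0.4, GCB = 0.4, U = 0.2),
                          cnv_regions = NULL,
                          callers = NULL,
                          noise_sd = 0) {
  if (is.null(callers)) {
    callers <- tibble::tibble(
      caller = c("caller_a", "caller_b", "caller_c"),
      sensitivity = 0.9,
      fp_rate = 3
    )
  }
  if (is.null(cnv_regions)) {
    cnv_regions <- tibble::tibble(
      chrom = c("chr2", "chr3", "chr1", "chr4", "chr5"),
      start = c(50000L, 100000L, 400000L, 50000L, 100000L),
      end = c(200000L, 220000L, 540000L, 170000L, 200000L),
      state = c(2L, 2L, 1L, -2L, -1L),
      penetrance = 0.4
    )
  }
  design <- list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    chrom_lengths = chrom_lengths, n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    driver_genes = as.integer(driver_genes), driver_prob = driver_prob,
    passenger_rate = passenger_rate,
    n_abc_markers = as.integer(n_abc_markers),
    n_gcb_markers = as.integer(n_gcb_markers),
    subgroup_probs = subgroup_probs, cnv_regions = cnv_regions,
    callers = callers, noise_sd = noise_sd
  )
  validate_cohort_design(design)
  structure(design, class = "cohort_design")
}

validate_cohort_design <- function(d) {
  probs <- c(d$driver_prob, d$subgroup_probs, d$callers$sensitivity,
             d$cnv_regions$penetrance)
  if (any(probs < 0 | probs > 1)) {
    abort_validation("all design probabilities must lie in [0, 1]")
  }
  if (abs(sum(d$subgroup_probs) - 1) > 1e-9) {
    abort_validation("subgroup label probabilities must sum to 1")
  }
  if (anyDuplicated(d$callers$caller)) {
    abort_validation("caller names must be unique")
  }
  if (d$n_patients < 0 || d$n_genes < 1 || d$gene_length < 1) {
    abort_validation("n_patients, n_genes and gene_length must be positive")
  }
  if (d$driver_genes + d$n_abc_markers + d$n_gcb_markers > d$n_genes) {
    abort_validation("more special genes than genes in the design")
  }
  # genes are laid out with one gap-width of intergenic space each side
  per_chrom <- ceiling(d$n_genes / length(d$chrom_lengths))
  if (any(per_chrom * 2 * d$gene_length > d$chrom_lengths)) {
    abort_validation(
      "design infeasible: chromosomes too short for the requested gene table"
    )
  }
  if (!all(d$cnv_regions$chrom %in% names(d$chrom_lengths))) {
    abort_validation("CNV region on a chromosome absent from the genome")
  }
  invisible(d)
}

# deterministic round-robin gene layout: genes evenly spaced with
# intergenic gaps, ensuring planted genes always exist in the gene table
design_gene_table <- function(d) {
  chroms <- names(d$chrom_lengths)
  chrom_of <- rep(chroms, length.out = d$n_genes)
  idx_on <- stats::ave(seq_len(d$n_genes), chrom_of, FUN = seq_along)
  pitch <- vapply(seq_len(d$n_genes), function(i) {
    n_on <- sum(chrom_of == chrom_of[i])
    d$chrom_lengths[[chrom_of[i]]] %/% n_on
  }, numeric(1))
  start <- as.integer((idx_on - 1L) * pitch + pitch %/% 4)
  tibble::tibble(
    symbol = sprintf("GENE%03d", seq_len(d$n_genes)),
    chrom = chrom_of,
    start = start,
    end = start + d$gene_length
  )
}

design_roles <- function(d, genes) {
  n_special <- d$driver_genes + d$n_abc_markers + d$n_gcb_markers
  specials <- genes$symbol[seq_len(n_special)]
  list(
    drivers = specials[seq_len(d$driver_genes)],
    abc = specials[d$driver_genes + seq_len(d$n_abc_markers)],
    gcb = specials[d$driver_genes + d$n_abc_markers +
                     seq_len(d$n_gcb_markers)]
  )
}

random_snv <- function(n, genes, rows) {
  # one SNP per requested row index into the gene table
  g <- genes[rows, , drop = FALSE]
  pos <- g$start + sample.int(g$end[1] - g$start[1], n, replace = TRUE)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1L)
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(
    gene = g$symbol, chrom = g$chrom, pos = as.integer(pos),
    ref = ref, alt = alt
  )
}

non_silent_classes <- function() {
  sev <- severity_ranks()
  sev$classification[sev$non_silent]
}

sample_classification <- function(n, non_silent_only = FALSE) {
  if (non_silent_only) {
    cls <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
             "Splice_Site", "In_Frame_Del")
    p <- c(0.70, 0.12, 0.08, 0.07, 0.03)
  } else {
    cls <- c("Missense_Mutation", "Silent", "Nonsense_Mutation",
             "Splice_Site", "Frame_Shift_Del", "Frame_Shift_Ins",
             "3'UTR", "Intron")
    p <- c(0.55, 0.15, 0.06, 0.05, 0.04, 0.03, 0.06, 0.06)
  }
  sample(cls, n, replace = TRUE, prob = p)
}

#' Generate a planted-truth synthetic cohort
#'
#' Draws the full truth bundle for a [cohort_design()]: the genome and
#' gene table, one somatic SNV list per patient (drivers, subgroup
#' markers consistent with the planted label, passengers confined to
#' non-marker genes), per-patient copy-number region hits, and the
#' planted subgroup labels. Deterministic given the design seed.
#'
#' @param design A `cohort_design`.
#' @return A `cohort_truth` list: `design`, `chrom_table`, `gene_table`,
#'   `variants` (tibble `patient`, `gene`, `chrom`, `pos` 1-based, `ref`,
#'   `alt`, `classification`, `variant_type`), `cn` (tibble `patient`,
#'   `chrom`, `start`, `end`, `state`; 0-based half-open) and `labels`
#'   (tibble `patient`, `subgroup`).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  d <- design
  set.seed(derive_seed(d$seed, 1L))
  chrom_table <- tibble::tibble(
    chrom = names(d$chrom_lengths),
    length = as.integer(unname(d$chrom_lengths))
  )
  genes <- design_gene_table(d)
  roles <- design_roles(d, genes)
  patients <- sprintf("P%03d", seq_len(d$n_patients))
  labels <- if (d$n_patients == 0) character(0) else {
    sample(names(d$subgroup_probs), d$n_patients, replace = TRUE,
           prob = d$subgroup_probs)
  }
  passenger_pool <- setdiff(genes$symbol, c(roles$abc, roles$gcb))
  variant_list <- lapply(seq_len(d$n_patients), function(i) {
    p <- patients[i]
    rows <- integer(0)
    ns_flag <- logical(0)
    # drivers: independent Bernoulli per gene
    hit <- roles$drivers[stats::runif(length(roles$drivers)) < d$driver_prob]
    rows <- c(rows, match(hit, genes$symbol))
    ns_flag <- c(ns_flag, rep(TRUE, length(hit)))
    # markers consistent with the planted label, exclusively
    if (labels[i] != "U") {
      markers <- if (labels[i] == "ABC") roles$abc else roles$gcb
      n_mark <- 1L + stats::rbinom(1L, length(markers) - 1L, 0.3)
      picked <- sample(markers, n_mark)
      rows <- c(rows, match(picked, genes$symbol))
      ns_flag <- c(ns_flag, rep(TRUE, n_mark))
    }
    # passengers: never in marker genes
    n_pass <- stats::rpois(1L, d$passenger_rate)
    if (n_pass > 0) {
      picked <- sample(passenger_pool, n_pass, replace = TRUE)
      rows <- c(rows, match(picked, genes$symbol))
      ns_flag <- c(ns_flag, rep(FALSE, n_pass))
    }
    if (length(rows) == 0) return(NULL)
    snv <- random_snv(length(rows), genes, rows)
    snv$classification <- ifelse(
      ns_flag,
      sample_classification(length(rows), non_silent_only = TRUE),
      sample_classification(length(rows))
    )
    snv$patient <- p
    # unique positions within a patient keep the voting key unambiguous
    snv[!duplicated(snv[c("chrom", "pos")]), ]
  })
  variants <- dplyr::bind_rows(variant_list)
  if (nrow(variants) == 0) {
    variants <- tibble::tibble(
      patient = character(), gene = character(), chrom = character(),
      pos = integer(), ref = character(), alt = character(),
      classification = character(), variant_type = character()
    )
  } else {
    variants$variant_type <- "SNP"
    variants <- variants %>%
      select("patient", "gene", "chrom", "pos", "ref", "alt",
             "classification", "variant_type")
  }
  cn <- tidyr::expand_grid(
    patient = patients,
    d$cnv_regions
  ) %>%
    filter(stats::runif(dplyr::n()) < .data$penetrance) %>%
    select("patient", "chrom", "start", "end", "state")
  structure(
    list(
      design = d, chrom_table = chrom_table, gene_table = genes,
      variants = variants, cn = cn,
      labels = tibble::tibble(
        patient = patients,
        subgroup = factor(labels, levels = c("ABC", "GCB", "U"))
      )
    ),
    class = "cohort_truth"
  )
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d patient(s), %d truth variant(s), %d CNV hit(s)\n",
    x$design$n_patients, nrow(x$variants), nrow(x$cn)
  ))
  invisible(x)
}

#' Emit the truth bundle as a cohort MAF
#'
#' @param truth A `cohort_truth`.
#' @return A MAF tibble (canonical columns; see [read_maf()]).
#' @export
emit_maf <- function(truth) {
  stopifnot(inherits(truth, "cohort_truth"))
  v <- truth$variants
  tibble::tibble(
    Hugo_Symbol = v$gene,
    Chromosome = v$chrom,
    Start_Position = v$pos,
    End_Position = v$pos,
    Reference_Allele = v$ref,
    Tumor_Seq_Allele2 = v$alt,
    Variant_Classification = v$classification,
    Variant_Type = v$variant_type,
    Tumor_Sample_Barcode = v$patient
  )
}

intergenic_positions <- function(truth, chrom, n) {
  # rejection-sample positions outside every gene body so false positives
  # can never collide with truth variants
  genes <- truth$gene_table %>% filter(.data$chrom == !!chrom)
  len <- truth$chrom_table$length[truth$chrom_table$chrom == chrom]
  out <- integer(0)
  while (length(out) < n) {
    cand <- sample.int(len, n - length(out), replace = TRUE)
    in_gene <- vapply(cand, function(p) {
      any(p > genes$start & p <= genes$end)
    }, logical(1))
    out <- c(out, cand[!in_gene])
  }
  out
}

#' Emit per-caller somatic VCF call sets
#'
#' Every truth variant enters caller `c`'s call set independently with
#' probability `sensitivity_c`; false positives are added at intergenic
#' positions with a per-patient Poisson count. Per-caller randomness is
#' seeded from the design seed plus the caller index, so regenerating one
#' caller reproduces it exactly.
#'
#' @param truth A `cohort_truth`.
#' @param design Defaults to the design inside `truth`.
#' @return A tibble `patient`, `caller`, `chrom`, `pos`, `ref`, `alt`,
#'   `filter` (always `PASS`), one row per emitted call.
#' @export
emit_caller_vcfs <- function(truth, design = truth$design) {
  stopifnot(inherits(truth, "cohort_truth"))
  callers <- design$callers
  patients <- truth$labels$patient
  out <- lapply(seq_len(nrow(callers)), function(ci) {
    set.seed(derive_seed(design$seed, 2L, ci))
    cal <- callers[ci, ]
    detected <- truth$variants %>%
      filter(stats::runif(dplyr::n()) < cal$sensitivity) %>%
      select("patient", "chrom", "pos", "ref", "alt")
    fps <- lapply(patients, function(p) {
      n_fp <- stats::rpois(1L, cal$fp_rate)
      if (n_fp == 0) return(NULL)
      chrom <- sort(sample(truth$chrom_table$chrom, n_fp, replace = TRUE,
                           prob = truth$chrom_table$length))
      pos <- unlist(lapply(unique(chrom), function(ch) {
        intergenic_positions(truth, ch, sum(chrom == ch))
      }))
      ref <- sample(c("A", "C", "G", "T"), n_fp, replace = TRUE)
      alt <- vapply(ref, function(r) {
        sample(setdiff(c("A", "C", "G", "T"), r), 1L)
      }, character(1), USE.NAMES = FALSE)
      tibble::tibble(patient = p, chrom = chrom, pos = as.integer(pos),
                     ref = ref, alt = alt)
    })
    dplyr::bind_rows(c(list(detected), fps)) %>%
      mutate(caller = cal$caller, filter = "PASS")
  })
  dplyr::bind_rows(out) %>%
    select("patient", "caller", "chrom", "pos", "ref", "alt", "filter")
}

#' Emit per-patient copy-number segment tables
#'
#' Each chromosome of each patient is tiled with segments: planted CNV
#' regions get a log2 mean representing their state (-2 -> -1.5,
#' -1 -> -0.6, +1 -> +0.6, +2 -> +1.5), the rest of the chromosome is
#' neutral at 0; Gaussian noise of sd `noise_sd` is added to every
#' segment mean. With `noise_sd = 0` thresholding recovers the planted
#' states exactly.
#'
#' @param truth A `cohort_truth`.
#' @param noise_sd Defaults to the design's `noise_sd`.
#' @return A SEG tibble (0-based half-open; see [read_seg()]).
#' @export
emit_seg <- function(truth, noise_sd = truth$design$noise_sd) {
  stopifnot(inherits(truth, "cohort_truth"))
  set.seed(derive_seed(truth$design$seed, 3L))
  state_log2 <- c(`-2` = -1.5, `-1` = -0.6, `0` = 0, `1` = 0.6, `2` = 1.5)
  rows <- list()
  for (p in truth$labels$patient) {
    hits <- truth$cn %>% filter(.data$patient == p)
    for (i in seq_len(nrow(truth$chrom_table))) {
      ch <- truth$chrom_table$chrom[i]
      len <- truth$chrom_table$length[i]
      h <- hits %>% filter(.data$chrom == ch) %>% arrange(.data$start)
      bounds <- unique(c(0L, rbind(h$start, h$end), len))
      bounds <- sort(bounds[bounds >= 0 & bounds <= len])
      seg_start <- bounds[-length(bounds)]
      seg_end <- bounds[-1]
      state <- vapply(seq_along(seg_start), function(j) {
        k <- which(h$start <= seg_start[j] & h$end >= seg_end[j])
        if (length(k) > 0) h$state[k[1]] else 0L
      }, integer(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = p, chrom = ch,
        start = as.integer(seg_start), end = as.integer(seg_end),
        n_markers = pmax(1L, as.integer((seg_end - seg_start) / 1000L)),
        log2_ratio = state_log2[as.character(state)] +
          stats::rnorm(length(state), 0, noise_sd)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a complete synthetic cohort to disk
#'
#' Writes every standard-format file the toolkit consumes — chrom.sizes,
#' gene BED, cohort MAF, per-patient-per-caller VCFs, per-patient SEG —
#' plus `truth_labels.tsv` and `truth_variants.tsv` for evaluation.
#'
#' @param truth A `cohort_truth`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_cohort_files <- function(truth, out_dir) {
  stopifnot(inherits(truth, "cohort_truth"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_chrom_sizes(truth$chrom_table, file.path(out_dir, "genome.chrom.sizes"))
  write_gene_table(truth$gene_table, file.path(out_dir, "genes.bed"))
  write_maf(emit_maf(truth), file.path(out_dir, "cohort.maf"))
  calls <- emit_caller_vcfs(truth)
  vcf_dir <- file.path(out_dir, "vcf")
  dir.create(vcf_dir, showWarnings = FALSE)
  calls %>%
    group_by(.data$patient, .data$caller) %>%
    dplyr::group_walk(function(rows, key) {
      write_vcf_sites(
        rows %>% arrange(match(.data$chrom, truth$chrom_table$chrom),
                         .data$pos),
        file.path(vcf_dir, sprintf("%s.%s.vcf", key$patient, key$caller)),
        chrom_order = truth$chrom_table
      )
    })
  write_seg(emit_seg(truth), file.path(out_dir, "cohort.seg"))
  readr::write_tsv(
    truth$labels %>% mutate(subgroup = as.character(.data$subgroup)),
    file.path(out_dir, "truth_labels.tsv"), progress = FALSE
  )
  readr::write_tsv(truth$variants, file.path(out_dir, "truth_variants.tsv"),
                   progress = FALSE)
  invisible(out_dir)
}
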