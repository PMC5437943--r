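classification_rank <- function(x) {
  sev <- severity_ranks()
  r <- sev$rank[match(x, sev$classification)]
  if (anyNA(r)) {
    abort_validation(sprintf(
      "unknown variant classification '%s'", x[is.na(r)][1]
    ))
  }
  r
}

is_non_silent <- function(x) {
  sev <- severity_ranks()
  ns <- sev$non_silent[match(x, sev$classification)]
  ns & !is.na(ns)
}

#' Build the gene-by-patient mutation matrix from a cohort MAF
#'
#' Tabulates a cohort MAF into the central gene-by-patient structure:
#' every cell collects the classifications observed for that gene in that
#' patient together with the single worst one under [severity_ranks()],
#' and per-gene recurrence is summarized as the number of distinct
#' patients carrying at least one counted mutation. By default only
#' non-silent (protein-altering) mutations count towards recurrence;
#' silent and non-coding records are still stored in the cells.
#'
#' @param maf MAF tibble (see [read_maf()]).
#' @param include_silent Count silent/non-coding records in
#'   `patient_count` and `mutation_count` (default `FALSE`).
#' @param patients Optional explicit cohort roster; defaults to the
#'   distinct sample barcodes in order of appearance. Patients with no
#'   mutations are legal and contribute empty columns.
#' @return A `cohort_matrix` object: list with `genes`, `patients`,
#'   `snv` (tibble `gene`, `patient`, `classes` list-column,
#'   `n_mutations`, `worst`, `worst_rank`), `gene_stats` (tibble `gene`,
#'   `patient_count`, `mutation_count`), `cn` (initially `NULL`) and
#'   `include_silent`.
#' @export
build_mutation_matrix <- function(maf, include_silent = FALSE,
                                  patients = NULL) {
  require_columns(maf, maf_required_columns(), "MAF")
  recs <- tibble::tibble(
    gene = maf$Hugo_Symbol,
    patient = maf$Tumor_Sample_Barcode,
    classification = maf$Variant_Classification,
    rank = classification_rank(maf$Variant_Classification),
    counted = include_silent | is_non_silent(maf$Variant_Classification)
  )
  if (is.null(patients)) {
    patients <- unique(recs$patient)
  } else if (!all(recs$patient %in% patients)) {
    abort_validation("MAF contains sample(s) missing from the roster")
  }
  genes <- unique(recs$gene)
  sev <- severity_ranks()
  snv <- if (nrow(recs) == 0) {
    tibble::tibble(
      gene = character(), patient = character(), classes = list(),
      n_mutations = integer(), worst = character(), worst_rank = integer()
    )
  } else recs %>%
    group_by(.data$gene, .data$patient) %>%
    summarise(
      classes = list(.data$classification),
      n_mutations = n(),
      worst_rank = min(.data$rank),
      .groups = "drop"
    ) %>%
    mutate(
      # representative class: lowest rank; rank ties resolved by the
      # severity-table order so the choice is deterministic
      worst = purrr::map_chr(.data$classes, function(cl) {
        sev$classification[min(match(cl, sev$classification))]
      })
    ) %>%
    select("gene", "patient", "classes", "n_mutations", "worst", "worst_rank")
  gene_stats <- recs %>%
    group_by(.data$gene) %>%
    summarise(
      patient_count = n_distinct(.data$patient[.data$counted]),
      mutation_count = sum(.data$counted),
      .groups = "drop"
    ) %>%
    arrange(match(.data$gene, genes))
  structure(
    list(
      genes = genes, patients = patients, snv = snv,
      gene_stats = gene_stats, cn = NULL,
      include_silent = include_silent
    ),
    class = "cohort_matrix"
  )
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf(
    "Cohort matrix: %d gene(s) x %d patient(s), %d mutated cell(s)%s\n",
    length(x$genes), length(x$patients), nrow(x$snv),
    if (is.null(x$cn)) "" else ", with copy-number states"
  ))
  invisible(x)
}

#' Tidy a cohort matrix into one row per mutated or altered cell
#'
#' @param x A `cohort_matrix`.
#' @param ... Unused.
#' @return Tibble with `gene`, `patient`, `worst`, `n_mutations`,
#'   `cn_state` (0 when no copy-number side is attached).
#' @export
tidy.cohort_matrix <- function(x, ...) {
  snv <- x$snv %>% select("gene", "patient", "worst", "n_mutations")
  cn <- if (is.null(x$cn)) {
    tibble::tibble(gene = character(), patient = character(),
                   cn_state = integer())
  } else {
    x$cn %>%
      filter(.data$state != 0L) %>%
      select("gene", "patient", cn_state = "state")
  }
  dplyr::full_join(snv, cn, by = c("gene", "patient")) %>%
    mutate(
      cn_state = dplyr::coalesce(.data$cn_state, 0L),
      n_mutations = dplyr::coalesce(.data$n_mutations, 0L)
    )
}

#' @rdname tidy.cohort_matrix
#' @export
glance.cohort_matrix <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes),
    n_patients = length(x$patients),
    n_mutated_cells = nrow(x$snv),
    n_mutations = sum(x$snv$n_mutations),
    has_copy_number = !is.null(x$cn)
  )
}

#' Threshold log2 ratios into ordinal copy-number states
#'
#' @param log2_ratio Numeric vector of segment mean log2 ratios.
#' @param thresholds Four increasing cut points `(deep, loss, gain, amp)`
#'   with `deep < loss < 0 < gain < amp`; boundaries are inclusive.
#'   Defaults `c(-1, -0.25, 0.25, 1)`.
#' @return Integer states in -2..2 (see [cn_state_codes()]).
#' @examples
#' cn_state_from_log2(c(-1.3, -0.3, 0, 0.3, 1.3))
#' @export
cn_state_from_log2 <- function(log2_ratio,
                               thresholds = c(-1, -0.25, 0.25, 1)) {
  check_cn_thresholds(thresholds)
  dplyr::case_when(
    log2_ratio <= thresholds[1] ~ -2L,
    log2_ratio <= thresholds[2] ~ -1L,
    log2_ratio >= thresholds[4] ~ 2L,
    log2_ratio >= thresholds[3] ~ 1L,
    TRUE ~ 0L
  )
}

check_cn_thresholds <- function(thresholds) {
  if (length(thresholds) != 4 ||
      !(thresholds[1] < thresholds[2] && thresholds[2] < 0 &&
        0 < thresholds[3] && thresholds[3] < thresholds[4])) {
    abort_validation(
      "thresholds must be four values deep < loss < 0 < gain < amp"
    )
  }
  invisible(thresholds)
}

#' Map copy-number segments to per-gene states
#'
#' Assigns each (gene, patient) the log2 ratio of the segment with the
#' largest overlap against the gene body, thresholded into an ordinal
#' state. Genes untouched by any segment of a patient are neutral. When
#' two segments tie on overlap length the more extreme state wins (then
#' the larger absolute log2 ratio, then the leftmost segment, keeping the
#' result deterministic).
#'
#' @param seg SEG tibble (see [read_seg()]; 0-based half-open).
#' @param genes Gene table (see [read_gene_table()]).
#' @param thresholds See [cn_state_from_log2()].
#' @param patients Optional roster; defaults to the samples in `seg`.
#' @return Tibble `gene`, `patient`, `state` (integer -2..2),
#'   `log2_ratio` (`NA` for uncovered genes), one row per gene-patient
#'   pair.
#' @export
gene_copy_states <- function(seg, genes, thresholds = c(-1, -0.25, 0.25, 1),
                             patients = NULL) {
  validate_seg(seg)
  require_columns(genes, c("symbol", "chrom", "start", "end"), "gene table")
  check_cn_thresholds(thresholds)
  if (is.null(patients)) patients <- unique(seg$sample_id)
  grid <- tidyr::expand_grid(gene = genes$symbol, patient = patients)
  if (nrow(seg) == 0 || nrow(genes) == 0) {
    return(grid %>% mutate(state = 0L, log2_ratio = NA_real_))
  }
  hits <- dplyr::inner_join(
    seg %>% rename(seg_start = "start", seg_end = "end"),
    genes %>% rename(gene = "symbol", g_start = "start", g_end = "end"),
    by = "chrom", relationship = "many-to-many"
  ) %>%
    mutate(overlap = pmin(.data$seg_end, .data$g_end) -
             pmax(.data$seg_start, .data$g_start)) %>%
    filter(.data$overlap > 0) %>%
    mutate(state = cn_state_from_log2(.data$log2_ratio, thresholds)) %>%
    group_by(gene = .data$gene, patient = .data$sample_id) %>%
    arrange(desc(.data$overlap), desc(abs(.data$state)),
            desc(abs(.data$log2_ratio)), .data$seg_start,
            .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    select("gene", "patient", "state", "log2_ratio")
  grid %>%
    left_join(hits, by = c("gene", "patient")) %>%
    mutate(state = dplyr::coalesce(.data$state, 0L))
}

#' Accept GISTIC-style discretized gene-level calls
#'
#' Validates externally produced integer calls (-2..2) and returns them
#' in the same shape as [gene_copy_states()].
#'
#' @param calls Long tibble `gene`, `patient`, `state` (see
#'   [read_gistic()]).
#' @return Tibble `gene`, `patient`, `state` with integer states.
#' @export
accept_gistic_states <- function(calls) {
  require_columns(calls, c("gene", "patient", "state"), "GISTIC calls")
  state <- as.integer(calls$state)
  bad <- which(is.na(state) | state < -2L | state > 2L)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "GISTIC call out of range -2..2 for gene %s, sample %s",
      calls$gene[bad[1]], calls$patient[bad[1]]
    ))
  }
  calls %>% mutate(state = state) %>% select("gene", "patient", "state")
}

#' Attach a copy-number side to a cohort matrix
#'
#' @param matrix A `cohort_matrix`.
#' @param cn Output of [gene_copy_states()] or [accept_gistic_states()].
#' @return The matrix with `cn` set; gene and patient universes extended
#'   to cover the copy-number data.
#' @export
add_copy_number <- function(matrix, cn) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  require_columns(cn, c("gene", "patient", "state"), "copy-number table")
  dup <- cn %>% count(.data$gene, .data$patient) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_validation(sprintf(
      "multiple copy-number states for gene %s, patient %s",
      dup$gene[1], dup$patient[1]
    ))
  }
  matrix$cn <- cn
  matrix$genes <- union(matrix$genes, cn$gene)
  matrix$patients <- union(matrix$patients, cn$patient)
  matrix
}

#' Filter genes by cohort recurrence and blacklist
#'
#' Keeps genes mutated in at least `min_patients` distinct patients and
#' not on the blacklist — the display threshold applied before building
#' gene-centric layouts. When a gene coordinate table is supplied the
#' retained genes are returned in genomic order (chromosome per the
#' chromosome-table order, then start); otherwise they keep the cohort
#' matrix order.
#'
#' @param matrix A `cohort_matrix`.
#' @param min_patients Minimum number of mutated patients (>= 1).
#' @param blacklist Character vector of gene symbols to hide.
#' @param gene_table Optional gene coordinates (see [read_gene_table()]).
#' @param chrom_order Optional chromosome table fixing chromosome order;
#'   defaults to order of appearance in `gene_table`.
#' @return Tibble `gene`, `patient_count`, `mutation_count`, plus
#'   `chrom`, `start`, `end` when coordinates are available, ordered for
#'   display.
#' @export
apply_gene_filters <- function(matrix, min_patients, blacklist = character(),
                               gene_table = NULL, chrom_order = NULL) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  if (min_patients < 1) {
    abort_validation("min_patients must be >= 1")
  }
  kept <- matrix$gene_stats %>%
    filter(.data$patient_count >= min_patients,
           !.data$gene %in% blacklist)
  if (is.null(gene_table)) {
    return(kept %>% arrange(match(.data$gene, matrix$genes)))
  }
  require_columns(gene_table, c("symbol", "chrom", "start", "end"),
                  "gene table")
  missing <- setdiff(kept$gene, gene_table$symbol)
  if (length(missing) > 0) {
    rlang::warn(sprintf(
      "%d retained gene(s) missing from the gene table were dropped: %s",
      length(missing), paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  chrom_levels <- if (is.null(chrom_order)) {
    unique(gene_table$chrom)
  } else {
    chrom_order$chrom
  }
  kept %>%
    dplyr::inner_join(
      gene_table %>% rename(gene = "symbol"), by = "gene"
    ) %>%
    arrange(match(.data$chrom, chrom_levels), .data$start)
}

#' Six-class mutation spectrum per patient
#'
#' Collapses every SNP onto a pyrimidine reference base (purine
#' reference/alternate pairs are reverse-complemented) and counts the six
#' substitution classes `C>A, C>G, C>T, T>A, T>C, T>G` per patient — the
#' per-sample summary used to eyeball mutational processes. Non-SNP
#' records are ignored; SNPs with alleles outside `{A,C,G,T}` are skipped
#' and tallied in the `n_skipped` attribute with a warning.
#'
#' @param maf MAF tibble.
#' @return Tibble `patient`, `class`, `n`, complete over all six classes
#'   for every patient with at least one usable SNP.
#' @export
mutation_spectrum <- function(maf) {
  require_columns(maf, maf_required_columns(), "MAF")
  snp <- maf %>% filter(.data$Variant_Type == "SNP")
  ok <- snp$Reference_Allele %in% c("A", "C", "G", "T") &
    snp$Tumor_Seq_Allele2 %in% c("A", "C", "G", "T") &
    snp$Reference_Allele != snp$Tumor_Seq_Allele2
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    rlang::warn(sprintf(
      "%d SNP record(s) with non-ACGT or identical alleles skipped",
      n_skipped
    ))
  }
  snp <- snp[ok, ]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- snp$Reference_Allele
  alt <- snp$Tumor_Seq_Allele2
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  out <- tibble::tibble(
    patient = snp$Tumor_Sample_Barcode,
    class = factor(paste0(ref, ">", alt), levels = spectrum_classes())
  ) %>%
    count(.data$patient, .data$class, .drop = FALSE, name = "n") %>%
    mutate(class = as.character(.data$class))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Cohort-wide mutation summaries
#'
#' Exact tallies over a cohort MAF: counts per variant classification and
#' per variant type, the per-patient mutation burden, the most
#' recurrently mutated genes, and the gene-cloud weight table (per-gene
#' mutated-patient counts for genes at or above a display threshold, the
#' input to a word-cloud style figure).
#'
#' @param maf MAF tibble.
#' @param top_n How many genes to report in `top_genes` (default 10).
#' @param genecloud_min Minimum mutated-patient count for a gene to enter
#'   the gene-cloud table (default 5).
#' @param include_silent Count silent/non-coding records towards gene
#'   recurrence (default `FALSE`); burden always counts every record.
#' @return A `cohort_summary` list of tibbles: `classification_counts`,
#'   `type_counts`, `burden`, `top_genes`, `genecloud`.
#' @export
summarize_cohort <- function(maf, top_n = 10, genecloud_min = 5,
                             include_silent = FALSE) {
  require_columns(maf, maf_required_columns(), "MAF")
  counted <- include_silent | is_non_silent(maf$Variant_Classification)
  gene_recurrence <- maf[counted, ] %>%
    group_by(gene = .data$Hugo_Symbol) %>%
    summarise(patient_count = n_distinct(.data$Tumor_Sample_Barcode),
              mutation_count = n(), .groups = "drop") %>%
    arrange(desc(.data$patient_count), .data$gene)
  out <- list(
    classification_counts = maf %>%
      count(classification = .data$Variant_Classification,
            sort = TRUE, name = "n"),
    type_counts = maf %>%
      count(variant_type = .data$Variant_Type, sort = TRUE, name = "n"),
    burden = maf %>%
      count(patient = .data$Tumor_Sample_Barcode, name = "n_mutations"),
    top_genes = utils::head(gene_recurrence, top_n),
    genecloud = gene_recurrence %>%
      filter(.data$patient_count >= genecloud_min) %>%
      select("gene", weight = "patient_count")
  )
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "Cohort summary: %d mutation(s) in %d patient(s); top gene: %s\n",
    sum(x$burden$n_mutations), nrow(x$burden),
    if (nrow(x$top_genes) > 0) x$top_genes$gene[1] else "<none>"
  ))
  invisible(x)
}

#' @rdname summarize_cohort
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(
    n_mutations = sum(x$burden$n_mutations),
    n_patients = nrow(x$burden),
    n_genes_in_cloud = nrow(x$genecloud),
    median_burden = stats::median(x$burden$n_mutations)
  )
}
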