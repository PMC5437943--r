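#' Build a gene-centric pseudo-karyotype
#'
#' Instead of genomic coordinates, the circular layout places every
#' retained gene in a unit-width slot, in genomic order along its
#' chromosome; intergenic space and genes below the display threshold are
#' eliminated. Each source chromosome with at least one retained gene
#' becomes a pseudo-chromosome whose length is its retained gene count.
#'
#' @param retained Ordered retained-gene tibble from
#'   [apply_gene_filters()] (must carry `gene`, `chrom`, `start`).
#' @param chrom_order Optional chromosome table; defaults to order of
#'   appearance in `retained`.
#' @return A `gene_karyotype` object: list with `chromosomes` (tibble
#'   `chrom`, `n_genes`) and `slots` (tibble `gene`, `chrom`,
#'   `slot_start`, `slot_end` with `slot_end = slot_start + 1`).
#' @export
build_gene_karyotype <- function(retained, chrom_order = NULL) {
  require_columns(retained, c("gene", "chrom", "start"), "retained genes")
  if (nrow(retained) == 0) {
    abort_validation("cannot build a karyotype from zero retained genes")
  }
  chrom_levels <- if (is.null(chrom_order)) {
    unique(retained$chrom)
  } else {
    intersect(chrom_order$chrom, retained$chrom)
  }
  slots <- retained %>%
    arrange(match(.data$chrom, chrom_levels), .data$start) %>%
    group_by(.data$chrom) %>%
    mutate(slot_start = dplyr::row_number() - 1L,
           slot_end = dplyr::row_number()) %>%
    ungroup() %>%
    select("gene", "chrom", "slot_start", "slot_end")
  chromosomes <- slots %>%
    count(.data$chrom, name = "n_genes") %>%
    arrange(match(.data$chrom, chrom_levels))
  structure(
    list(chromosomes = chromosomes, slots = slots),
    class = "gene_karyotype"
  )
}

#' @export
print.gene_karyotype <- function(x, ...) {
  cat(sprintf(
    "Gene karyotype: %d gene slot(s) on %d pseudo-chromosome(s)\n",
    nrow(x$slots), nrow(x$chromosomes)
  ))
  invisible(x)
}

slot_join <- function(karyotype, tbl, by = "gene") {
  dplyr::inner_join(karyotype$slots, tbl, by = by)
}

#' Per-gene stacked SNV histogram and total-count tracks
#'
#' For every gene slot, a stacked value per variant classification (in
#' fixed severity order, most severe first) plus a scalar total for the
#' circle (scatter) track. Values count distinct mutated patients per
#' class by default, or raw mutation records with `unit = "mutations"`.
#'
#' @param matrix A `cohort_matrix`.
#' @param karyotype A `gene_karyotype`.
#' @param unit `"patients"` (default) or `"mutations"`.
#' @return List with `stacked` (tibble `gene`, `chrom`, `slot_start`,
#'   `slot_end`, `classification`, `value` — zero rows for absent
#'   classes) and `total` (tibble with per-gene `value`).
#' @export
build_snv_track <- function(matrix, karyotype,
                            unit = c("patients", "mutations")) {
  unit <- match.arg(unit)
  stopifnot(inherits(matrix, "cohort_matrix"),
            inherits(karyotype, "gene_karyotype"))
  cells <- matrix$snv %>%
    select("gene", "patient", "classes") %>%
    tidyr::unnest_longer("classes", values_to = "classification")
  per_class <- cells %>%
    group_by(.data$gene, .data$classification) %>%
    summarise(
      value = if (unit == "patients") n_distinct(.data$patient) else n(),
      .groups = "drop"
    )
  sev <- severity_ranks()
  stacked <- slot_join(karyotype, per_class) %>%
    arrange(match(.data$chrom, karyotype$chromosomes$chrom),
            .data$slot_start,
            match(.data$classification, sev$classification))
  total <- slot_join(
    karyotype,
    cells %>%
      group_by(.data$gene) %>%
      summarise(
        value = if (unit == "patients") n_distinct(.data$patient) else n(),
        .groups = "drop"
      )
  ) %>%
    arrange(match(.data$chrom, karyotype$chromosomes$chrom),
            .data$slot_start)
  list(stacked = stacked, total = total)
}

#' Per-gene copy-number summary tracks
#'
#' Three inner tracks per gene slot: the fraction of patients with a
#' gained state (> neutral), the fraction with a lost state (< neutral),
#' and the mean ordinal state across patients. Fractions use the full
#' patient universe of the matrix as denominator, so genes untouched by
#' copy-number events sit at zero.
#'
#' @param matrix A `cohort_matrix` with an attached copy-number side.
#' @param karyotype A `gene_karyotype`.
#' @return Tibble `gene`, `chrom`, `slot_start`, `slot_end`,
#'   `gain_fraction`, `loss_fraction`, `mean_state`.
#' @export
build_cn_tracks <- function(matrix, karyotype) {
  stopifnot(inherits(matrix, "cohort_matrix"),
            inherits(karyotype, "gene_karyotype"))
  n_patients <- length(matrix$patients)
  cn <- if (is.null(matrix$cn)) {
    tibble::tibble(gene = character(), patient = character(),
                   state = integer())
  } else {
    matrix$cn
  }
  per_gene <- cn %>%
    group_by(.data$gene) %>%
    summarise(
      gain_fraction = sum(.data$state > 0L) / n_patients,
      loss_fraction = sum(.data$state < 0L) / n_patients,
      mean_state = sum(.data$state) / n_patients,
      .groups = "drop"
    )
  karyotype$slots %>%
    left_join(per_gene, by = "gene") %>%
    mutate(across(
      c("gain_fraction", "loss_fraction", "mean_state"),
      ~ dplyr::coalesce(.x, 0)
    )) %>%
    arrange(match(.data$chrom, karyotype$chromosomes$chrom),
            .data$slot_start)
}

#' Style the gene label track
#'
#' Every retained gene gets a label. Genes mutated in at least twice the
#' display threshold are flagged bold; genes on the user-supplied
#' highlight list (or overlapping a supplied recurrent-CNV region BED)
#' get the highlight color. The two attributes may co-occur.
#'
#' @param karyotype A `gene_karyotype`.
#' @param gene_stats Tibble with `gene` and `patient_count` (e.g. the
#'   output of [apply_gene_filters()]).
#' @param min_patients The display threshold used for retention.
#' @param highlight Character vector of gene symbols to color.
#' @param regions Optional tibble `chrom`, `start`, `end` of recurrent
#'   CNV regions; genes overlapping any region (by their genomic
#'   coordinates in `gene_stats`) are highlighted too.
#' @return Tibble `gene`, `chrom`, `slot_start`, `slot_end`, `bold`,
#'   `highlight`.
#' @export
style_labels <- function(karyotype, gene_stats, min_patients,
                         highlight = character(), regions = NULL) {
  stopifnot(inherits(karyotype, "gene_karyotype"))
  require_columns(gene_stats, c("gene", "patient_count"), "gene stats")
  extra <- setdiff(highlight, karyotype$slots$gene)
  if (length(extra) > 0) {
    rlang::warn(sprintf(
      "%d highlight gene(s) not retained were ignored: %s",
      length(extra), paste(utils::head(extra, 5), collapse = ", ")
    ))
  }
  region_genes <- character(0)
  if (!is.null(regions) && nrow(regions) > 0) {
    require_columns(regions, c("chrom", "start", "end"), "region table")
    require_columns(gene_stats, c("chrom", "start", "end"),
                    "gene stats with coordinates")
    region_genes <- dplyr::inner_join(
      gene_stats, regions %>% rename(r_start = "start", r_end = "end"),
      by = "chrom", relationship = "many-to-many"
    ) %>%
      filter(.data$start < .data$r_end, .data$r_start < .data$end) %>%
      pull("gene")
  }
  karyotype$slots %>%
    left_join(gene_stats %>% select("gene", "patient_count"), by = "gene") %>%
    mutate(
      bold = .data$patient_count >= 2 * min_patients,
      highlight = .data$gene %in% c(highlight, region_genes)
    ) %>%
    select("gene", "chrom", "slot_start", "slot_end", "bold", "highlight")
}

#' Assemble and serialize a Circos text bundle
#'
#' Produces the full set of Circos-dialect text documents for the
#' gene-centric plot: `karyotype.txt`, the stacked and total SNV tracks,
#' the three copy-number tracks, the styled label track and a minimal
#' `circos.conf` referencing every file exactly once. Output is
#' deterministic: re-emitting the same inputs yields byte-identical
#' documents.
#'
#' @param karyotype A `gene_karyotype`.
#' @param snv Output of [build_snv_track()].
#' @param cn Output of [build_cn_tracks()].
#' @param labels Output of [style_labels()].
#' @return A `circos_bundle`: named list of character vectors (one per
#'   file).
#' @export
build_circos_bundle <- function(karyotype, snv, cn, labels) {
  sev <- severity_ranks()
  chrom_tbl <- karyotype$chromosomes
  kary_lines <- sprintf(
    "chr - %s %s 0 %d grey", chrom_tbl$chrom, chrom_tbl$chrom, chrom_tbl$n_genes
  )
  # stacked histogram: comma-joined per-class values in severity order,
  # zero-filled so every gene line has one value per class
  class_order <- unique(sev$classification)
  stacked_wide <- tidyr::expand_grid(
    karyotype$slots, classification = class_order
  ) %>%
    left_join(
      snv$stacked %>%
        select("gene", "classification", "value"),
      by = c("gene", "classification")
    ) %>%
    mutate(value = dplyr::coalesce(.data$value, 0L)) %>%
    arrange(match(.data$chrom, chrom_tbl$chrom), .data$slot_start,
            match(.data$classification, class_order)) %>%
    group_by(.data$gene, .data$chrom, .data$slot_start, .data$slot_end) %>%
    summarise(values = paste(.data$value, collapse = ","),
              .groups = "drop") %>%
    arrange(match(.data$chrom, chrom_tbl$chrom), .data$slot_start)
  data_line <- function(tbl, value) {
    sprintf("%s %d %d %s", tbl$chrom, tbl$slot_start, tbl$slot_end, value)
  }
  num <- function(x) trimws(formatC(x, format = "g", digits = 10))
  label_opts <- ifelse(
    labels$bold & labels$highlight,
    "label_font=bold,color=red",
    ifelse(labels$bold, "label_font=bold",
           ifelse(labels$highlight, "color=red", "label_font=normal"))
  )
  files <- list(
    karyotype = kary_lines,
    snv_stacked = data_line(stacked_wide, stacked_wide$values),
    snv_total = data_line(snv$total, num(snv$total$value)),
    cn_gain = data_line(cn, num(cn$gain_fraction)),
    cn_loss = data_line(cn, num(cn$loss_fraction)),
    cn_mean = data_line(cn, num(cn$mean_state)),
    labels = paste(
      data_line(labels, labels$gene), label_opts
    )
  )
  track_files <- setdiff(names(files), "karyotype")
  conf <- c(
    "karyotype = karyotype.txt",
    "<plots>",
    unlist(lapply(track_files, function(f) {
      c("<plot>", sprintf("file = %s.txt", f), "</plot>")
    }), use.names = FALSE),
    "</plots>"
  )
  files$circos.conf <- conf
  structure(files, class = "circos_bundle")
}

#' @export
print.circos_bundle <- function(x, ...) {
  cat(sprintf(
    "Circos bundle: %d document(s) (%s)\n",
    length(x), paste(names(x), collapse = ", ")
  ))
  invisible(x)
}

#' Write a Circos bundle to disk
#'
#' @param bundle A `circos_bundle`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written (`karyotype.txt`,
#'   `snv_stacked.txt`, ..., `circos.conf`).
#' @export
write_circos_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "circos_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fname <- ifelse(names(bundle) == "circos.conf",
                  names(bundle), paste0(names(bundle), ".txt"))
  paths <- file.path(out_dir, fname)
  purrr::walk2(bundle, paths, writeLines)
  invisible(paths)
}

#' Gene-centric circular summary of a mutation/copy-number cohort
#'
#' High-level wrapper: filters genes by recurrence and blacklist, builds
#' the pseudo-karyotype, the stacked/total SNV tracks, the three
#' copy-number tracks and the styled labels, and assembles the Circos
#' text bundle.
#'
#' @param maf MAF tibble.
#' @param gene_table Gene coordinates (see [read_gene_table()]).
#' @param min_patients Display threshold (distinct mutated patients).
#' @param seg Optional SEG tibble for copy-number tracks.
#' @param gistic Optional GISTIC long table (alternative to `seg`).
#' @param chrom_order Optional chromosome table.
#' @param blacklist,highlight Optional gene symbol vectors.
#' @param regions Optional recurrent-CNV region tibble.
#' @param include_silent Count silent mutations towards recurrence.
#' @param unit `"patients"` or `"mutations"` for the SNV tracks.
#' @return A `circos_bundle`; the retained gene table is attached as
#'   attribute `retained`.
#' @export
oncocircos <- function(maf, gene_table, min_patients,
                       seg = NULL, gistic = NULL, chrom_order = NULL,
                       blacklist = character(), highlight = character(),
                       regions = NULL, include_silent = FALSE,
                       unit = "patients") {
  matrix <- build_mutation_matrix(maf, include_silent = include_silent)
  if (!is.null(seg)) {
    matrix <- add_copy_number(matrix, gene_copy_states(seg, gene_table))
  } else if (!is.null(gistic)) {
    matrix <- add_copy_number(matrix, accept_gistic_states(gistic))
  }
  retained <- apply_gene_filters(
    matrix, min_patients, blacklist = blacklist,
    gene_table = gene_table, chrom_order = chrom_order
  )
  karyotype <- build_gene_karyotype(retained, chrom_order = chrom_order)
  snv <- build_snv_track(matrix, karyotype, unit = unit)
  cn <- build_cn_tracks(matrix, karyotype)
  labels <- style_labels(karyotype, retained, min_patients,
                         highlight = highlight, regions = regions)
  bundle <- build_circos_bundle(karyotype, snv, cn, labels)
  attr(bundle, "retained") <- retained
  bundle
}
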