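#' Classify patients into molecular subgroups from marker mutations
#'
#' Assigns each patient to the ABC or GCB molecular subgroup using the
#' presence of non-silent mutations in genes known to be restricted to
#' one subgroup. Genes appearing in both marker lists are not unique to
#' either, so they are dropped with a warning before counting. A patient
#' with more mutated ABC-unique markers than GCB-unique markers is
#' labeled ABC, the converse GCB; ties — including patients with no
#' marker mutations at all — are unclassifiable (U).
#'
#' @param matrix A `cohort_matrix`.
#' @param abc_markers,gcb_markers Character vectors of marker gene
#'   symbols; both must be non-empty after removing shared genes.
#' @param include_silent Count silent marker mutations too (default
#'   `FALSE`).
#' @return Tibble `patient`, `n_abc`, `n_gcb`, `subgroup` (factor with
#'   levels ABC, GCB, U), one row per patient in matrix order.
#' @export
classify_subgroups <- function(matrix, abc_markers, gcb_markers,
                               include_silent = FALSE) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  shared <- intersect(abc_markers, gcb_markers)
  if (length(shared) > 0) {
    rlang::warn(sprintf(
      "%d marker gene(s) shared between lists dropped: %s",
      length(shared), paste(shared, collapse = ", ")
    ))
    abc_markers <- setdiff(abc_markers, shared)
    gcb_markers <- setdiff(gcb_markers, shared)
  }
  if (length(abc_markers) == 0 || length(gcb_markers) == 0) {
    abort_validation("both marker sets must be non-empty (after removing shared genes)")
  }
  cells <- matrix$snv
  if (!include_silent) {
    cells <- cells %>%
      mutate(n_ns = purrr::map_int(.data$classes,
                                   ~ sum(is_non_silent(.x)))) %>%
      filter(.data$n_ns > 0)
  }
  counts <- cells %>%
    group_by(.data$patient) %>%
    summarise(
      n_abc = sum(unique(.data$gene) %in% abc_markers),
      n_gcb = sum(unique(.data$gene) %in% gcb_markers),
      .groups = "drop"
    )
  tibble::tibble(patient = matrix$patients) %>%
    left_join(counts, by = "patient") %>%
    mutate(
      n_abc = dplyr::coalesce(.data$n_abc, 0L),
      n_gcb = dplyr::coalesce(.data$n_gcb, 0L),
      subgroup = factor(
        dplyr::case_when(
          .data$n_abc > .data$n_gcb ~ "ABC",
          .data$n_gcb > .data$n_abc ~ "GCB",
          TRUE ~ "U"
        ),
        levels = c("ABC", "GCB", "U")
      )
    )
}

#' Order genes for an oncoprint
#'
#' Descending by the number of mutated patients, ties alphabetical.
#'
#' @param matrix A `cohort_matrix`.
#' @param genes Optional subset to order; defaults to all mutated genes.
#' @return Character vector — a permutation of the requested genes.
#' @export
order_genes <- function(matrix, genes = NULL) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  stats <- matrix$gene_stats
  if (!is.null(genes)) {
    stats <- stats %>% filter(.data$gene %in% genes)
    missing <- setdiff(genes, stats$gene)
    stats <- bind_rows(stats, tibble::tibble(
      gene = missing, patient_count = 0L, mutation_count = 0L
    ))
  }
  stats %>%
    arrange(desc(.data$patient_count), .data$gene) %>%
    pull("gene")
}

memo_sort_patients <- function(matrix, gene_order, patients,
                               include_silent = FALSE) {
  cells <- matrix$snv
  if (!include_silent) {
    cells <- cells %>%
      filter(purrr::map_lgl(.data$classes, ~ any(is_non_silent(.x))))
  }
  cells <- cells %>% filter(.data$gene %in% gene_order)
  # binary mutation vector per patient over the gene ordering, encoded as
  # a fixed-width 0/1 string; lexicographic descent on equal-width strings
  # is exactly the classic mutual-exclusivity ("memo") sort
  key <- vapply(patients, function(p) {
    g <- cells$gene[cells$patient == p]
    paste(as.integer(gene_order %in% g), collapse = "")
  }, character(1))
  patients[order(key, patients, method = "radix",
                 decreasing = c(TRUE, FALSE))]
}

#' Order patients (samples) for an oncoprint
#'
#' `"memo"` sorts patients by lexicographic descent of their binary
#' mutation vector over the gene ordering — the classic
#' mutual-exclusivity waterfall sort. `"subgroup"` first blocks patients
#' as ABC, GCB, U and memo-sorts within each block (the layout used to
#' organize a cohort on its predicted molecular subgroup). `"given"`
#' validates and passes through a caller-supplied order, enabling exact
#' reproduction of any external layout.
#'
#' @param matrix A `cohort_matrix`.
#' @param method `"memo"`, `"subgroup"` or `"given"`.
#' @param gene_order Gene ordering to sort against; defaults to
#'   [order_genes()].
#' @param subgroups Output of [classify_subgroups()] (required for
#'   `method = "subgroup"`).
#' @param given Caller-supplied patient order (required for
#'   `method = "given"`); must be a permutation of the matrix patients.
#' @param include_silent Count silent mutations in the sort vectors.
#' @return Character vector — a permutation of the matrix patients.
#' @export
order_samples <- function(matrix, method = c("memo", "subgroup", "given"),
                          gene_order = NULL, subgroups = NULL, given = NULL,
                          include_silent = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "cohort_matrix"))
  patients <- matrix$patients
  if (method == "given") {
    if (is.null(given) || length(given) != length(patients) ||
        !setequal(given, patients) || anyDuplicated(given)) {
      abort_validation(
        "'given' must be a permutation of the matrix patients"
      )
    }
    return(given)
  }
  if (is.null(gene_order)) gene_order <- order_genes(matrix)
  if (method == "memo") {
    return(memo_sort_patients(matrix, gene_order, patients, include_silent))
  }
  if (is.null(subgroups)) {
    abort_validation("method = 'subgroup' requires a subgroup table")
  }
  require_columns(subgroups, c("patient", "subgroup"), "subgroup table")
  unlist(lapply(c("ABC", "GCB", "U"), function(lab) {
    block <- subgroups$patient[subgroups$subgroup == lab]
    block <- patients[patients %in% block]
    if (length(block) == 0) return(character(0))
    memo_sort_patients(matrix, gene_order, block, include_silent)
  }), use.names = FALSE)
}

#' Build an oncoprint table
#'
#' Assembles the two-dimensional gene-by-patient matrix with its
#' covariates: cells carry the worst-severity mutation classification
#' and/or the copy-number state; the top covariate is the per-patient
#' total mutation burden (and subgroup label when markers are supplied);
#' the side covariates are per-gene recurrence and, optionally,
#' externally supplied per-gene significance values (e.g. driver Q
#' values) read from a two-column table — never computed here.
#'
#' @param matrix A `cohort_matrix`.
#' @param genes Genes to display; defaults to all mutated genes. Ordered
#'   with [order_genes()] unless `order_genes_by = "given"`.
#' @param sample_order,gene_order_method See [order_samples()];
#'   `sample_order` is passed as `method`.
#' @param subgroups Optional output of [classify_subgroups()].
#' @param significance Optional tibble `gene`, `value`.
#' @param given Patient order when `sample_order = "given"`.
#' @param order_genes_by `"frequency"` (default) or `"given"`.
#' @return An `oncoprint_table`: list with `genes`, `patients`, `cells`
#'   (long tibble `gene`, `patient`, `cell` in `class|CNSTATE` notation,
#'   `"."` for empty), `burden`, `subgroups`, `gene_stats`,
#'   `significance`.
#' @export
build_oncoprint <- function(matrix, genes = NULL,
                            sample_order = "memo", subgroups = NULL,
                            significance = NULL, given = NULL,
                            order_genes_by = c("frequency", "given")) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  order_genes_by <- match.arg(order_genes_by)
  if (is.null(genes)) genes <- matrix$genes
  gene_order <- if (order_genes_by == "frequency") {
    order_genes(matrix, genes)
  } else {
    genes
  }
  patient_order <- order_samples(
    matrix, method = sample_order, gene_order = gene_order,
    subgroups = subgroups, given = given
  )
  cn <- matrix$cn
  cells <- tidyr::expand_grid(gene = gene_order, patient = patient_order) %>%
    left_join(matrix$snv %>% select("gene", "patient", "worst"),
              by = c("gene", "patient")) %>%
    left_join(
      if (is.null(cn)) {
        tibble::tibble(gene = character(), patient = character(),
                       state = integer())
      } else {
        cn
      },
      by = c("gene", "patient")
    ) %>%
    mutate(
      state = dplyr::coalesce(.data$state, 0L),
      cell = dplyr::case_when(
        !is.na(.data$worst) & .data$state != 0L ~
          paste0(.data$worst, "|", cn_state_label(.data$state)),
        !is.na(.data$worst) ~ .data$worst,
        .data$state != 0L ~ paste0("|", cn_state_label(.data$state)),
        TRUE ~ "."
      )
    ) %>%
    select("gene", "patient", "cell")
  burden <- matrix$snv %>%
    group_by(.data$patient) %>%
    summarise(n_mutations = sum(.data$n_mutations), .groups = "drop")
  burden <- tibble::tibble(patient = patient_order) %>%
    left_join(burden, by = "patient") %>%
    mutate(n_mutations = dplyr::coalesce(.data$n_mutations, 0L))
  if (!is.null(significance)) {
    require_columns(significance, c("gene", "value"), "significance table")
  }
  structure(
    list(
      genes = gene_order, patients = patient_order, cells = cells,
      burden = burden, subgroups = subgroups,
      gene_stats = matrix$gene_stats %>%
        filter(.data$gene %in% gene_order) %>%
        arrange(match(.data$gene, gene_order)),
      significance = significance
    ),
    class = "oncoprint_table"
  )
}

#' @export
print.oncoprint_table <- function(x, ...) {
  cat(sprintf(
    "Oncoprint: %d gene(s) x %d patient(s)\n",
    length(x$genes), length(x$patients)
  ))
  invisible(x)
}

#' @rdname build_oncoprint
#' @param x An `oncoprint_table`.
#' @param ... Unused.
#' @export
tidy.oncoprint_table <- function(x, ...) {
  x$cells
}

#' Write an oncoprint as a TSV bundle
#'
#' Emits `matrix.tsv` (genes as rows, patients as columns, cells in
#' `classification|CNSTATE` notation with `.` for empty), `burden.tsv`,
#' `gene_counts.tsv`, and — when present — `subgroups.tsv` and
#' `significance.tsv`. Output is deterministic.
#'
#' @param table An `oncoprint_table`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_oncoprint <- function(table, out_dir) {
  stopifnot(inherits(table, "oncoprint_table"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wide <- table$cells %>%
    tidyr::pivot_wider(names_from = "patient", values_from = "cell") %>%
    arrange(match(.data$gene, table$genes))
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(df, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  emit(wide, "matrix.tsv")
  emit(table$burden, "burden.tsv")
  emit(table$gene_stats, "gene_counts.tsv")
  if (!is.null(table$subgroups)) {
    emit(table$subgroups %>%
           mutate(subgroup = as.character(.data$subgroup)),
         "subgroups.tsv")
  }
  if (!is.null(table$significance)) emit(table$significance,
                                         "significance.tsv")
  invisible(paths)
}

#' Plot an oncoprint table
#'
#' Tile plot of the gene-by-patient matrix colored by the worst
#' mutation classification, with copy-number states drawn as an inner
#' tile border fill. Intended as a quick look; publication figures can
#' be rebuilt from the emitted TSVs.
#'
#' @param object An `oncoprint_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oncoprint_table <- function(object, ...) {
  cells <- object$cells %>%
    tidyr::separate_wider_delim(
      "cell", "|", names = c("class", "cn"),
      too_few = "align_start", too_many = "merge"
    ) %>%
    mutate(
      class = dplyr::na_if(.data$class, "."),
      class = dplyr::na_if(.data$class, ""),
      gene = factor(.data$gene, levels = rev(object$genes)),
      patient = factor(.data$patient, levels = object$patients)
    )
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$patient, y = .data$gene)) +
    ggplot2::geom_tile(fill = "grey95", color = "white") +
    ggplot2::geom_tile(
      data = ~ dplyr::filter(.x, !is.na(.data$class)),
      ggplot2::aes(fill = .data$class), color = "white"
    ) +
    ggplot2::geom_point(
      data = ~ dplyr::filter(.x, !is.na(.data$cn) & .data$cn != ""),
      ggplot2::aes(shape = .data$cn), size = 1
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Worst mutation",
                  shape = "CN state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot a six-class mutation spectrum
#'
#' Stacked per-patient bars of the pyrimidine-collapsed substitution
#' classes from [mutation_spectrum()].
#'
#' @param spectrum Output of [mutation_spectrum()].
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  require_columns(spectrum, c("patient", "class", "n"), "spectrum")
  ggplot2::ggplot(
    spectrum,
    ggplot2::aes(x = .data$patient, y = .data$n, fill = .data$class)
  ) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = NULL, y = "Fraction of SNVs", fill = "Class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6)
    )
}
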