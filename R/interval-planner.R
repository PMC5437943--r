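#' Plan whole-chromosome interval groups for scatter/gather parallelization
#'
#' Builds the per-job interval collections used to fan a per-chromosome
#' analysis (typically a somatic variant caller) out across CPUs and merge
#' the results afterwards. Chromosomes are never split — subchromosomal
#' intervals would break intrachromosomal dependences some callers rely
#' on — so the planning problem is grouping whole chromosomes. In
#' `"grouped"` mode large and small chromosomes are packed together by
#' first-fit-decreasing bin packing with bin capacity equal to the longest
#' chromosome: no group can outlast the job that processes the longest
#' chromosome alone, while the number of concurrent jobs shrinks. Pairing
#' a large with a small chromosome is the two-per-group special case of
#' this rule.
#'
#' @param chroms Chromosome table from [read_chrom_sizes()]; its row order
#'   is the canonical order used for tie-breaking and within-group
#'   ordering.
#' @param mode `"grouped"` (first-fit-decreasing packing),
#'   `"per_chromosome"` (one group per chromosome) or `"single"` (all
#'   chromosomes in one group).
#' @return A tibble of class `interval_plan` with one row per chromosome:
#'   `group` (1-based integer), `chrom`, `start` (always 0), `end` (the
#'   chromosome length). The bin capacity is attached as attribute
#'   `capacity`. Groups are numbered by their largest member, descending;
#'   within a group rows follow the chromosome-table order.
#' @examples
#' ct <- read_chrom_sizes("A\t100\nB\t60\nC\t40\nD\t30")
#' plan_intervals(ct, mode = "grouped")
#' @export
plan_intervals <- function(chroms,
                           mode = c("grouped", "per_chromosome", "single")) {
  mode <- match.arg(mode)
  require_columns(chroms, c("chrom", "length"), "chromosome table")
  if (nrow(chroms) == 0) {
    abort_validation("cannot plan intervals for an empty chromosome table")
  }
  if (anyDuplicated(chroms$chrom)) {
    abort_validation("duplicate chromosome names in chromosome table")
  }
  capacity <- max(as.numeric(chroms$length))
  n <- nrow(chroms)
  group <- integer(n)
  if (mode == "single") {
    group[] <- 1L
  } else if (mode == "per_chromosome") {
    group <- seq_len(n)
  } else {
    # first-fit-decreasing; ties in length broken by input order (stable)
    ord <- order(-as.numeric(chroms$length))
    sums <- numeric(0)
    for (i in ord) {
      len <- as.numeric(chroms$length[i])
      fit <- which(sums + len <= capacity)
      if (length(fit) > 0) {
        g <- fit[1]
        sums[g] <- sums[g] + len
      } else {
        sums <- c(sums, len)
        g <- length(sums)
      }
      group[i] <- g
    }
    # renumber groups by largest member descending (FFD opens bins in
    # decreasing item order, so bin index already realizes this; kept
    # explicit for safety)
    k <- length(sums)
    largest <- vapply(seq_len(k), function(g) {
      max(as.numeric(chroms$length)[group == g])
    }, numeric(1))
    group <- match(group, order(-largest))
  }
  plan <- tibble::tibble(
    group = as.integer(group),
    chrom = chroms$chrom,
    start = 0L,
    end = as.integer(chroms$length)
  ) %>%
    arrange(.data$group) # stable: preserves input order within groups
  attr(plan, "capacity") <- capacity
  class(plan) <- c("interval_plan", class(tibble::tibble()))
  plan
}

#' @export
print.interval_plan <- function(x, ...) {
  cat(sprintf(
    "Interval plan: %d chromosome(s) in %d group(s), capacity %s bp\n",
    nrow(x), max(x$group), format(attr(x, "capacity"), big.mark = ",")
  ))
  NextMethod()
}

#' @rdname plan_intervals
#' @param x An `interval_plan`.
#' @param ... Unused.
#' @export
tidy.interval_plan <- function(x, ...) {
  tibble::as_tibble(unclass_plan(x))
}

unclass_plan <- function(x) {
  class(x) <- setdiff(class(x), "interval_plan")
  x
}

#' @rdname plan_intervals
#' @export
glance.interval_plan <- function(x, ...) {
  sums <- tapply(as.numeric(x$end - x$start), x$group, sum)
  tibble::tibble(
    n_chromosomes = nrow(x),
    n_groups = max(x$group),
    capacity = attr(x, "capacity"),
    max_group_bp = max(sums),
    min_group_bp = min(sums),
    load_balance = min(sums) / max(sums)
  )
}

#' Format an interval plan as BED3 documents
#'
#' @param plan An `interval_plan`.
#' @return A named list (`group_000`, `group_001`, ...) of character
#'   vectors, each a BED3 document `chrom<TAB>0<TAB>length`, one per
#'   group. Groups are never empty.
#' @export
format_plan_beds <- function(plan) {
  require_columns(plan, c("group", "chrom", "start", "end"), "interval plan")
  groups <- split(
    paste(plan$chrom, plan$start, plan$end, sep = "\t"), plan$group
  )
  stopifnot(all(lengths(groups) > 0))
  stats::setNames(groups, sprintf("group_%03d", seq_along(groups) - 1L))
}

#' Write an interval plan as a collection of BED files
#'
#' One BED3 file per group, named `group_000.bed`, `group_001.bed`, ...
#'
#' @param plan An `interval_plan`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_plan_beds <- function(plan, out_dir) {
  docs <- format_plan_beds(plan)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, paste0(names(docs), ".bed"))
  purrr::walk2(docs, paths, writeLines)
  invisible(paths)
}

#' Merge and sort per-interval variant caller outputs
#'
#' Gathers the per-group VCFs produced by a scattered run back into one
#' document: records are pooled, sorted by chromosome (in the reference
#' chromosome-table order), position, REF and ALT, and exact duplicates
#' (same site and same INFO) are collapsed to one record. A record whose
#' chromosome is absent from the chromosome table, or two records at the
#' same site with conflicting INFO, indicate a mis-scattered run and raise
#' a validation error.
#'
#' @param vcf_tbls A list of site tibbles (see [read_vcf_sites()]), or a
#'   single tibble.
#' @param chrom_order Chromosome table defining the sort order.
#' @return One site tibble, sorted and deduplicated.
#' @export
merge_variant_outputs <- function(vcf_tbls, chrom_order) {
  if (is.data.frame(vcf_tbls)) vcf_tbls <- list(vcf_tbls)
  require_columns(chrom_order, c("chrom", "length"), "chromosome table")
  all <- dplyr::bind_rows(vcf_tbls)
  if (nrow(all) == 0) return(all)
  unknown <- setdiff(unique(all$chrom), chrom_order$chrom)
  if (length(unknown) > 0) {
    abort_validation(sprintf(
      "record(s) on chromosome(s) absent from the chromosome table: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  if (!"info" %in% names(all)) all$info <- "."
  merged <- all %>%
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .data$info,
             .keep_all = TRUE) %>%
    arrange(match(.data$chrom, chrom_order$chrom), .data$pos,
            .data$ref, .data$alt)
  conflict <- merged %>%
    count(.data$chrom, .data$pos, .data$ref, .data$alt) %>%
    filter(.data$n > 1)
  if (nrow(conflict) > 0) {
    abort_validation(sprintf(
      "conflicting INFO for identical variant %s:%d %s>%s across inputs",
      conflict$chrom[1], conflict$pos[1], conflict$ref[1], conflict$alt[1]
    ))
  }
  merged
}
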