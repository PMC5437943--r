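#' Normalize variant allele representations
#'
#' Different callers may report the same variant with padded alleles.
#' Votes are counted under a trimmed positional key: shared trailing bases
#' are removed first, then shared leading bases (advancing the position),
#' always stopping while both alleles still have at least one base. No
#' reference-FASTA left-alignment is attempted, so the toolkit runs
#' without a genome; the trim resolves the representation differences
#' that matter for SNVs and simple indels.
#'
#' @param keys Tibble with columns `chrom`, `pos`, `ref`, `alt` (extra
#'   columns pass through).
#' @return The tibble with normalized `pos`, `ref`, `alt` (uppercased).
#' @examples
#' normalize_variant_keys(
#'   tibble::tibble(chrom = "chr1", pos = 100L, ref = "AT", alt = "GT")
#' )
#' @export
normalize_variant_keys <- function(keys) {
  require_columns(keys, c("chrom", "pos", "ref", "alt"), "variant key table")
  n <- nrow(keys)
  if (n == 0) return(keys)
  ref <- toupper(keys$ref)
  alt <- toupper(keys$alt)
  pos <- as.integer(keys$pos)
  if (any(!nzchar(ref) | !nzchar(alt) | is.na(ref) | is.na(alt))) {
    abort_validation("ref and alt alleles must be non-empty")
  }
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # trim shared trailing bases
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1L)
      a <- substr(a, 1, nchar(a) - 1L)
    }
    # then shared leading bases, advancing pos
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r))
      a <- substr(a, 2, nchar(a))
      p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  if (any(ref == alt)) {
    i <- which(ref == alt)[1]
    abort_validation(sprintf(
      "ref == alt after normalization at %s:%d (%s)",
      keys$chrom[i], pos[i], ref[i]
    ))
  }
  out <- keys
  out$pos <- pos
  out$ref <- ref
  out$alt <- alt
  out
}

#' Split multiallelic VCF records
#'
#' One row per alternate allele; all other fields (including INFO) are
#' copied verbatim; input order is preserved, with the split alleles in
#' their ALT-field order.
#'
#' @param sites Site tibble (see [read_vcf_sites()]).
#' @return Site tibble with single-allele `alt` values.
#' @export
split_multiallelic <- function(sites) {
  require_columns(sites, c("chrom", "pos", "ref", "alt"), "VCF site table")
  if (any(is.na(sites$alt) | !nzchar(sites$alt))) {
    abort_validation("empty ALT allele")
  }
  out <- tidyr::separate_rows(sites, "alt", sep = ",")
  if (any(!nzchar(out$alt))) {
    abort_validation("empty ALT allele after multiallelic split")
  }
  out
}

#' Combine per-caller site tables into one call table
#'
#' @param results Named list of site tibbles, one per caller; names are
#'   the caller names.
#' @return One tibble with a leading `caller` column.
#' @export
bind_caller_results <- function(results) {
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    abort_validation("every caller result must be named")
  }
  if (anyDuplicated(names(results))) {
    abort_validation(sprintf(
      "duplicate caller name: %s", names(results)[duplicated(names(results))][1]
    ))
  }
  dplyr::bind_rows(results, .id = "caller")
}

#' k-of-n consensus voting over somatic variant calls
#'
#' Counts, for every normalized variant key, how many distinct callers
#' report it, and keeps the keys supported by at least `k` callers — the
#' simple voting scheme used to integrate an ensemble of somatic variant
#' callers. With `k = 1` the result is the union of all call sets; with
#' `k` equal to the number of callers it is their intersection.
#'
#' @param calls Either a tibble with columns `caller`, `chrom`, `pos`,
#'   `ref`, `alt` (and optionally `filter`), or a named list of per-caller
#'   site tibbles (see [bind_caller_results()]).
#' @param k Minimum number of supporting callers, between 1 and the
#'   number of callers. Default 2, the minimal non-trivial consensus.
#' @param pass_only When `TRUE` (default) only records whose FILTER is
#'   `PASS` or `.` contribute votes; records without a `filter` column
#'   all count.
#' @param chrom_order Optional chromosome table fixing the chromosome
#'   sort order of the output; by default chromosomes sort
#'   lexicographically, so the result is invariant to caller order.
#' @param normalize Trim-normalize keys before counting (default `TRUE`).
#' @return Tibble of class `consensus_calls`: `chrom`, `pos`, `ref`,
#'   `alt`, `supporters` (comma-joined sorted caller names), `n_callers`;
#'   sorted by (chromosome order, position, ref, alt).
#' @examples
#' calls <- bind_caller_results(list(
#'   strelka = tibble::tibble(chrom = "chr1", pos = c(1L, 5L),
#'                            ref = "A", alt = "T"),
#'   mutationseq = tibble::tibble(chrom = "chr1", pos = 5L,
#'                                ref = "A", alt = "T")
#' ))
#' consensus_vote(calls, k = 2)
#' @export
consensus_vote <- function(calls, k = 2L, pass_only = TRUE,
                           chrom_order = NULL, normalize = TRUE) {
  ensemble <- NULL
  if (!is.data.frame(calls)) {
    ensemble <- names(calls) # callers with zero calls still count
    calls <- bind_caller_results(calls)
  }
  require_columns(
    calls, c("caller", "chrom", "pos", "ref", "alt"), "call table"
  )
  callers <- if (is.null(ensemble)) unique(calls$caller) else ensemble
  if (length(callers) < 2) {
    abort_validation("an ensemble needs at least 2 callers")
  }
  if (k < 1 || k > length(callers)) {
    abort_validation(sprintf(
      "k = %d out of range: must be between 1 and %d callers",
      k, length(callers)
    ))
  }
  if (pass_only && "filter" %in% names(calls)) {
    calls <- calls %>% filter(.data$filter %in% c("PASS", "."))
  }
  if (normalize) calls <- normalize_variant_keys(calls)
  chrom_levels <- if (is.null(chrom_order)) {
    sort(unique(calls$chrom))
  } else {
    chrom_order$chrom
  }
  unknown <- setdiff(unique(calls$chrom), chrom_levels)
  if (length(unknown) > 0) {
    abort_validation(sprintf(
      "call(s) on chromosome(s) absent from the chromosome table: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  out <- calls %>%
    distinct(.data$caller, .data$chrom, .data$pos, .data$ref, .data$alt) %>%
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) %>%
    summarise(
      supporters = paste(sort(unique(.data$caller)), collapse = ","),
      n_callers = n_distinct(.data$caller),
      .groups = "drop"
    ) %>%
    filter(.data$n_callers >= k) %>%
    arrange(match(.data$chrom, chrom_levels), .data$pos,
            .data$ref, .data$alt)
  class(out) <- c("consensus_calls", class(out))
  attr(out, "k") <- as.integer(k)
  attr(out, "n_ensemble") <- length(callers)
  out
}

#' @rdname consensus_vote
#' @param x A `consensus_calls` tibble.
#' @param ... Unused.
#' @export
glance.consensus_calls <- function(x, ...) {
  tibble::tibble(
    n_variants = nrow(x),
    k = attr(x, "k"),
    n_callers = attr(x, "n_ensemble"),
    mean_support = if (nrow(x) == 0) NA_real_ else mean(x$n_callers)
  )
}

#' Write consensus calls as an annotated sites-only VCF
#'
#' Each record carries two INFO keys: `CALLERS`, the comma-joined sorted
#' names of the supporting callers, and `NCALLERS`, their count.
#'
#' @param consensus Output of [consensus_vote()].
#' @param chrom_order Chromosome table used for `##contig` lines and
#'   record order.
#' @param file Optional path; when `NULL` the VCF lines are returned.
#' @return The VCF text lines, invisibly when written to a file.
#' @export
consensus_to_vcf <- function(consensus, chrom_order, file = NULL) {
  require_columns(
    consensus, c("chrom", "pos", "ref", "alt", "supporters", "n_callers"),
    "consensus table"
  )
  sites <- tibble::tibble(
    chrom = consensus$chrom, pos = consensus$pos,
    ref = consensus$ref, alt = consensus$alt,
    filter = "PASS",
    info = sprintf("CALLERS=%s;NCALLERS=%d",
                   consensus$supporters, consensus$n_callers)
  )
  if (nrow(sites) > 0) {
    sites <- sites %>%
      arrange(match(.data$chrom, chrom_order$chrom), .data$pos,
              .data$ref, .data$alt)
  }
  write_vcf_sites(
    sites, file = file, chrom_order = chrom_order,
    info_header = c(
      paste0("##INFO=<ID=CALLERS,Number=.,Type=String,",
             "Description=\"Supporting caller names\">"),
      paste0("##INFO=<ID=NCALLERS,Number=1,Type=Integer,",
             "Description=\"Number of supporting callers\">")
    )
  )
}
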