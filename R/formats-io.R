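#' Read a chromosome size table
#'
#' Parses either a two-column `chrom.sizes` file (name, length) or the
#' `@SQ` lines of a SAM header (`SN:`/`LN:` tags). The row order of the
#' input is preserved and defines the canonical chromosome sort order used
#' throughout the package (interval planning, VCF merging, gene ordering).
#'
#' @param file Path to a file, or literal text (a string containing
#'   newlines, or a character vector of lines).
#' @param dialect `"two_column"` for `chrom.sizes`, `"sam_header"` for SAM
#'   header text. In `sam_header` mode non-`@SQ` lines are ignored.
#' @return A tibble with columns `chrom` (character) and `length`
#'   (integer), one row per chromosome, in input order.
#' @examples
#' read_chrom_sizes("chr1\t100\nchr2\t60")
#' read_chrom_sizes("@SQ\tSN:chrA\tLN:500\n@PG\tID:x", dialect = "sam_header")
#' @export
read_chrom_sizes <- function(file, dialect = c("two_column", "sam_header")) {
  dialect <- match.arg(dialect)
  lines <- read_lines_any(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort_parse("chromosome size input is empty")
  }
  if (dialect == "two_column") {
    parts <- strsplit(lines, "[ \t]+")
    bad <- which(lengths(parts) != 2L)
    if (length(bad) > 0) {
      abort_parse(sprintf(
        "line %d: expected 2 columns, found %d", bad[1], lengths(parts)[bad[1]]
      ))
    }
    chrom <- vapply(parts, `[[`, character(1), 1L)
    len_chr <- vapply(parts, `[[`, character(1), 2L)
  } else {
    sq <- grepl("^@SQ\\b", lines)
    keep <- lines[sq]
    if (length(keep) == 0) {
      abort_parse("no @SQ lines found in SAM header input")
    }
    tag <- function(line, key, lineno) {
      m <- regmatches(line, regexpr(paste0(key, ":[^\t]+"), line))
      if (length(m) == 0) {
        abort_parse(sprintf("line %d: @SQ line lacks %s: tag", lineno, key))
      }
      sub(paste0("^", key, ":"), "", m)
    }
    linenos <- which(sq)
    chrom <- mapply(tag, keep, "SN", linenos, USE.NAMES = FALSE)
    len_chr <- mapply(tag, keep, "LN", linenos, USE.NAMES = FALSE)
  }
  len <- suppressWarnings(as.numeric(len_chr))
  bad <- which(is.na(len) | len != floor(len) | len < 1)
  if (length(bad) > 0) {
    abort_parse(sprintf(
      "line %d: chromosome length '%s' is not a positive integer",
      bad[1], len_chr[bad[1]]
    ))
  }
  if (anyDuplicated(chrom)) {
    abort_validation(sprintf(
      "duplicate chromosome name: %s", chrom[duplicated(chrom)][1]
    ))
  }
  tibble::tibble(chrom = chrom, length = as.integer(len))
}

#' Write a chromosome size table
#'
#' @param chroms Tibble with `chrom` and `length` columns.
#' @param file Optional path; when `NULL` the lines are returned.
#' @return The text lines, invisibly when written to a file.
#' @export
write_chrom_sizes <- function(chroms, file = NULL) {
  require_columns(chroms, c("chrom", "length"), "chromosome table")
  lines <- paste(chroms$chrom, chroms$length, sep = "\t")
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

as_readr_input <- function(file) {
  if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    return(file)
  }
  I(paste(read_lines_any(file), collapse = "\n"))
}

#' Read a MAF (Mutation Annotation Format) file
#'
#' Reads a GDC-style tab-separated MAF. Only the nine structural columns
#' are required (case-insensitive header match): `Hugo_Symbol`,
#' `Chromosome`, `Start_Position`, `End_Position`, `Reference_Allele`,
#' `Tumor_Seq_Allele2`, `Variant_Classification`, `Variant_Type` and
#' `Tumor_Sample_Barcode`. Any further columns (vcf2maf emits ~100) are
#' preserved untouched for round-tripping. Lines starting with `#` are
#' skipped. Record order is preserved.
#'
#' @param file Path or literal text.
#' @param validate Check classification/type enums and SNP allele
#'   invariants (default `TRUE`).
#' @return A tibble with the canonical columns first (canonical names and
#'   types: positions integer) followed by any extra columns as character.
#' @export
read_maf <- function(file, validate = TRUE) {
  df <- readr::read_tsv(
    as_readr_input(file),
    comment = "#", col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  req <- maf_required_columns()
  idx <- match(tolower(req), tolower(names(df)))
  if (anyNA(idx)) {
    abort_schema(sprintf(
      "MAF is missing required column(s): %s",
      paste(req[is.na(idx)], collapse = ", ")
    ))
  }
  names(df)[idx] <- req
  extra <- setdiff(names(df), req)
  df <- df[, c(req, extra)]
  df$Start_Position <- as.integer(df$Start_Position)
  df$End_Position <- as.integer(df$End_Position)
  maf <- tibble::as_tibble(df)
  if (validate) validate_maf(maf)
  maf
}

validate_maf <- function(maf) {
  require_columns(maf, maf_required_columns(), "MAF")
  bad <- which(!maf$Variant_Classification %in% maf_classifications())
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "row %d: unknown Variant_Classification '%s'",
      bad[1], maf$Variant_Classification[bad[1]]
    ))
  }
  bad <- which(!maf$Variant_Type %in% maf_variant_types())
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "row %d: unknown Variant_Type '%s'", bad[1], maf$Variant_Type[bad[1]]
    ))
  }
  bad <- which(maf$End_Position < maf$Start_Position)
  if (length(bad) > 0) {
    abort_validation(sprintf("row %d: End_Position < Start_Position", bad[1]))
  }
  snp <- maf$Variant_Type == "SNP"
  ok <- maf$Reference_Allele %in% c("A", "C", "G", "T") &
    maf$Tumor_Seq_Allele2 %in% c("A", "C", "G", "T") &
    maf$Reference_Allele != maf$Tumor_Seq_Allele2
  bad <- which(snp & !ok)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "row %d: SNP alleles must be distinct single bases in {A,C,G,T}", bad[1]
    ))
  }
  invisible(maf)
}

#' Write a MAF file
#'
#' @param maf Tibble as returned by [read_maf()].
#' @param file Optional path; when `NULL` the tab-separated lines are
#'   returned.
#' @return The text lines, invisibly when written to a file.
#' @export
write_maf <- function(maf, file = NULL) {
  require_columns(maf, maf_required_columns(), "MAF")
  df <- as.data.frame(maf, check.names = FALSE)
  for (j in seq_along(df)) df[[j]] <- as.character(df[[j]])
  header <- paste(names(df), collapse = "\t")
  body <- if (nrow(df) == 0) character(0) else {
    do.call(paste, c(df, sep = "\t"))
  }
  lines <- c(header, body)
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Read an IGV-style SEG file of copy-number segments
#'
#' Accepts both the 5-column (sample, chrom, start, end, log2 ratio) and
#' 6-column (with marker count) IGV variants; a header line is detected
#' and skipped. On disk the coordinates are 1-based inclusive; the
#' returned tibble uses the package-internal 0-based half-open convention
#' (so `end - start` is the segment length in bp).
#'
#' @param file Path or literal text.
#' @param validate Check that segments of one sample on one chromosome do
#'   not overlap (default `TRUE`).
#' @return A tibble with columns `sample_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `n_markers` (integer, `NA` for 5-column input)
#'   and `log2_ratio`.
#' @export
read_seg <- function(file, validate = TRUE) {
  lines <- read_lines_any(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble::tibble(
      sample_id = character(), chrom = character(),
      start = integer(), end = integer(),
      n_markers = integer(), log2_ratio = double()
    ))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  # header detection: start column fails to parse as a number
  is_header <- function(p) {
    length(p) >= 4 && is.na(suppressWarnings(as.numeric(p[[3]])))
  }
  offset <- 0L
  if (is_header(parts[[1]])) {
    parts <- parts[-1]
    nc <- nc[-1]
    offset <- 1L
    if (length(parts) == 0) {
      return(read_seg(character(0)))
    }
  }
  bad <- which(!nc %in% c(5L, 6L))
  if (length(bad) > 0) {
    abort_parse(sprintf(
      "line %d: expected 5 or 6 tab-separated columns, found %d",
      bad[1] + offset, nc[bad[1]]
    ))
  }
  col <- function(i) vapply(parts, `[[`, character(1), i)
  six <- nc == 6L
  start_chr <- col(3)
  end_chr <- col(4)
  last <- vapply(parts, function(p) p[[length(p)]], character(1))
  nm_chr <- ifelse(six, vapply(parts, `[[`, character(1), 5L), NA_character_)
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad) > 0) {
      abort_parse(sprintf(
        "line %d: %s '%s' is not numeric", bad[1] + offset, what, x[bad[1]]
      ))
    }
    v
  }
  start1 <- num(start_chr, "segment start")
  end1 <- num(end_chr, "segment end")
  if (any(end1 < start1)) {
    abort_validation(sprintf(
      "line %d: segment end < start", which(end1 < start1)[1] + offset
    ))
  }
  seg <- tibble::tibble(
    sample_id = col(1),
    chrom = col(2),
    start = as.integer(start1) - 1L,
    end = as.integer(end1),
    n_markers = as.integer(num(nm_chr, "marker count")),
    log2_ratio = num(last, "log2 ratio")
  )
  if (validate) validate_seg(seg)
  seg
}

validate_seg <- function(seg) {
  require_columns(
    seg, c("sample_id", "chrom", "start", "end", "log2_ratio"), "SEG table"
  )
  ov <- seg %>%
    group_by(.data$sample_id, .data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(
      overlap = any(.data$start[-1] < .data$end[-length(.data$end)]),
      .groups = "drop"
    ) %>%
    filter(.data$overlap)
  if (nrow(ov) > 0) {
    abort_validation(sprintf(
      "overlapping segments for sample %s on %s",
      ov$sample_id[1], ov$chrom[1]
    ))
  }
  invisible(seg)
}

#' Write an IGV-style SEG file
#'
#' Converts the internal 0-based half-open coordinates back to the 1-based
#' inclusive on-disk convention. Emits 6 columns when any `n_markers` is
#' present, 5 otherwise.
#'
#' @param seg Tibble as returned by [read_seg()].
#' @param file Optional path; when `NULL` the lines are returned.
#' @return The text lines, invisibly when written to a file.
#' @export
write_seg <- function(seg, file = NULL) {
  require_columns(
    seg, c("sample_id", "chrom", "start", "end", "log2_ratio"), "SEG table"
  )
  has_nm <- "n_markers" %in% names(seg) && any(!is.na(seg$n_markers))
  header <- if (has_nm) {
    "ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean"
  } else {
    "ID\tchrom\tloc.start\tloc.end\tseg.mean"
  }
  mean_chr <- trimws(formatC(seg$log2_ratio, format = "g", digits = 15))
  body <- if (nrow(seg) == 0) character(0) else if (has_nm) {
    paste(seg$sample_id, seg$chrom, seg$start + 1L, seg$end,
          seg$n_markers, mean_chr, sep = "\t")
  } else {
    paste(seg$sample_id, seg$chrom, seg$start + 1L, seg$end,
          mean_chr, sep = "\t")
  }
  lines <- c(header, body)
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Read a sites-only VCF
#'
#' Parses the eight fixed VCF columns; meta (`##`) and header (`#CHROM`)
#' lines are skipped. ALT may still contain comma-separated alleles — use
#' [split_multiallelic()] to obtain one alternate allele per row. The INFO
#' field is kept as its raw string (`.` for empty); see
#' [vcf_info_to_list()].
#'
#' @param file Path or literal text.
#' @return A tibble with columns `chrom`, `pos` (1-based integer), `id`,
#'   `ref`, `alt`, `qual`, `filter`, `info` in file order.
#' @export
read_vcf_sites <- function(file) {
  lines <- read_lines_any(file)
  data <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(data) == 0) {
    return(tibble::tibble(
      chrom = character(), pos = integer(), id = character(),
      ref = character(), alt = character(), qual = character(),
      filter = character(), info = character()
    ))
  }
  parts <- strsplit(data, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 8L)
  if (length(bad) > 0) {
    abort_parse(sprintf(
      "VCF data line %d: expected >= 8 tab-separated fields, found %d",
      bad[1], lengths(parts)[bad[1]]
    ))
  }
  col <- function(i) vapply(parts, `[[`, character(1), i)
  pos <- suppressWarnings(as.integer(col(2)))
  if (anyNA(pos)) {
    abort_parse(sprintf(
      "VCF data line %d: POS is not an integer", which(is.na(pos))[1]
    ))
  }
  out <- tibble::tibble(
    chrom = col(1), pos = pos, id = col(3),
    ref = toupper(col(4)), alt = toupper(col(5)),
    qual = col(6), filter = col(7), info = col(8)
  )
  ok_allele <- function(x) grepl("^[ACGTN]+(,[ACGTN]+)*$", x)
  bad <- which(!grepl("^[ACGTN]+$", out$ref) | !ok_allele(out$alt))
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "VCF data line %d: REF/ALT must be non-empty strings over {A,C,G,T,N}",
      bad[1]
    ))
  }
  out
}

#' Write a sites-only VCFv4.2 document
#'
#' Emits the meta header (`##fileformat=VCFv4.2`, optional `##contig`
#' lines in the supplied chromosome order, any declared `##INFO` lines),
#' the `#CHROM` header without FORMAT/sample columns, and one line per
#' record.
#'
#' @param sites Tibble as returned by [read_vcf_sites()]; `id`, `qual`,
#'   `filter` and `info` default to `.` when absent.
#' @param file Optional path; when `NULL` the lines are returned.
#' @param chrom_order Optional chromosome table (see [read_chrom_sizes()])
#'   used to emit `##contig` lines.
#' @param info_header Character vector of complete `##INFO=<...>` lines.
#' @return The text lines, invisibly when written to a file.
#' @export
write_vcf_sites <- function(sites, file = NULL, chrom_order = NULL,
                            info_header = character()) {
  require_columns(sites, c("chrom", "pos", "ref", "alt"), "VCF site table")
  get_or <- function(nm, default) {
    if (nm %in% names(sites)) {
      x <- as.character(sites[[nm]])
      ifelse(is.na(x) | x == "", default, x)
    } else {
      rep(default, nrow(sites))
    }
  }
  meta <- c("##fileformat=VCFv4.2", info_header)
  if (!is.null(chrom_order)) {
    meta <- c(meta, sprintf(
      "##contig=<ID=%s,length=%d>", chrom_order$chrom, chrom_order$length
    ))
  }
  header <- "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  body <- if (nrow(sites) == 0) character(0) else {
    paste(sites$chrom, sites$pos, get_or("id", "."), sites$ref, sites$alt,
          get_or("qual", "."), get_or("filter", "."), get_or("info", "."),
          sep = "\t")
  }
  lines <- c(meta, header, body)
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Parse a raw VCF INFO string into a named list
#'
#' @param info Character vector of INFO strings (`.` for empty).
#' @return A list of named character vectors; flag keys get value `""`.
#' @export
vcf_info_to_list <- function(info) {
  lapply(info, function(x) {
    if (is.na(x) || x == "." || x == "") {
      return(stats::setNames(character(0), character(0)))
    }
    kv <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    stats::setNames(
      vapply(kv, function(p) if (length(p) > 1) p[[2]] else "", character(1)),
      vapply(kv, `[[`, character(1), 1L)
    )
  })
}

#' Read a BED-format gene coordinate table
#'
#' Expects at least four columns: chrom, start, end, symbol. BED is
#' 0-based half-open on disk, which matches the package-internal interval
#' convention, so coordinates pass through unchanged.
#'
#' @param file Path or literal text.
#' @return A tibble with columns `symbol`, `chrom`, `start`, `end`.
#' @export
read_gene_table <- function(file) {
  lines <- read_lines_any(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(tibble::tibble(
      symbol = character(), chrom = character(),
      start = integer(), end = integer()
    ))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 4L)
  if (length(bad) > 0) {
    abort_parse(sprintf(
      "line %d: gene BED needs >= 4 columns (chrom, start, end, name)",
      bad[1]
    ))
  }
  col <- function(i) vapply(parts, `[[`, character(1), i)
  start <- suppressWarnings(as.integer(col(2)))
  end <- suppressWarnings(as.integer(col(3)))
  if (anyNA(start) || anyNA(end)) {
    abort_parse(sprintf(
      "line %d: non-integer BED coordinate",
      which(is.na(start) | is.na(end))[1]
    ))
  }
  genes <- tibble::tibble(
    symbol = col(4), chrom = col(1), start = start, end = end
  )
  if (any(genes$end <= genes$start)) {
    abort_validation(sprintf(
      "line %d: gene end must be > start", which(end <= start)[1]
    ))
  }
  if (anyDuplicated(genes$symbol)) {
    abort_validation(sprintf(
      "duplicate gene symbol: %s", genes$symbol[duplicated(genes$symbol)][1]
    ))
  }
  genes
}

#' Write a gene coordinate table as BED4
#'
#' @param genes Tibble as returned by [read_gene_table()].
#' @param file Optional path; when `NULL` the lines are returned.
#' @return The text lines, invisibly when written to a file.
#' @export
write_gene_table <- function(genes, file = NULL) {
  require_columns(genes, c("symbol", "chrom", "start", "end"), "gene table")
  lines <- paste(genes$chrom, genes$start, genes$end, genes$symbol, sep = "\t")
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Read a plain-text gene list
#'
#' One symbol per line; `#` comments and blank lines skipped; surrounding
#' whitespace trimmed; duplicates dropped, first occurrence wins.
#'
#' @param file Path or literal text.
#' @return Character vector of gene symbols in file order.
#' @examples
#' read_gene_list("# artefact-prone\nTTN\nMUC16\n")
#' @export
read_gene_list <- function(file) {
  lines <- trimws(read_lines_any(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Write a plain-text gene list
#'
#' @param genes Character vector of symbols.
#' @param file Optional path; when `NULL` the lines are returned.
#' @return The text lines, invisibly when written to a file.
#' @export
write_gene_list <- function(genes, file = NULL) {
  lines <- as.character(genes)
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Read a GISTIC-style gene-by-sample call table
#'
#' Expects a wide tab-separated table whose first column holds gene
#' symbols and whose remaining columns are samples with integer calls in
#' -2..2 (the `all_thresholded.by_genes` shape).
#'
#' @param file Path or literal text.
#' @return A long tibble with columns `gene`, `patient`, `state`.
#' @export
read_gistic <- function(file) {
  df <- readr::read_tsv(
    as_readr_input(file),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (ncol(df) < 2) {
    abort_schema("GISTIC table needs a gene column plus >= 1 sample column")
  }
  names(df)[1] <- "gene"
  long <- tidyr::pivot_longer(
    df, -"gene", names_to = "patient", values_to = "state"
  )
  state <- suppressWarnings(as.integer(long$state))
  if (anyNA(state)) {
    abort_parse(sprintf(
      "non-integer GISTIC call '%s' for gene %s",
      long$state[is.na(state)][1], long$gene[is.na(state)][1]
    ))
  }
  long$state <- state
  long
}

#' Strip a "chr" prefix from chromosome names
#'
#' Optional normalizer for mixing sources that disagree on the UCSC-style
#' prefix; matching elsewhere in the package is always exact, so apply
#' this explicitly when needed.
#'
#' @param x Character vector of chromosome names.
#' @return `x` with any leading `chr` removed.
#' @examples
#' strip_chr_prefix(c("chr1", "2", "chrX"))
#' @export
strip_chr_prefix <- function(x) sub("^chr", "", x)
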