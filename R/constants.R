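#' Variant classification severity ranking
#'
#' The fixed, VEP-consequence-inspired ordering used to pick one
#' representative mutation per gene-by-patient cell: nonsense, then
#' frameshifts, splice site, nonstop, translation start site, in-frame
#' indels, missense, silent, and finally the non-coding classes. Lower rank
#' means more severe; classes sharing a rank are documented tie groups
#' (the two frameshift classes, the two in-frame classes, and the
#' non-coding group).
#'
#' @return A tibble with columns `classification`, `rank` (integer, 1 =
#'   most severe) and `non_silent` (logical; `TRUE` for protein-altering
#'   classes counted towards per-gene patient recurrence by default).
#' @examples
#' severity_ranks()
#' @export
severity_ranks <- function() {
  tibble::tibble(
    classification = c(
      "Nonsense_Mutation",
      "Frame_Shift_Del", "Frame_Shift_Ins",
      "Splice_Site",
      "Nonstop_Mutation",
      "Translation_Start_Site",
      "In_Frame_Del", "In_Frame_Ins",
      "Missense_Mutation",
      "Silent",
      "3'UTR", "5'UTR", "Intron", "RNA", "IGR"
    ),
    rank = c(1L, 2L, 2L, 3L, 4L, 5L, 6L, 6L, 7L, 8L,
             rep(9L, 5L)),
    non_silent = c(rep(TRUE, 9L), rep(FALSE, 6L))
  )
}

maf_classifications <- function() severity_ranks()$classification

maf_variant_types <- function() c("SNP", "INS", "DEL", "DNP", "TNP")

# Canonical (GDC-style) MAF column names required by the readers; extra
# columns are tolerated and preserved opaquely.
maf_required_columns <- function() {
  c(
    "Hugo_Symbol", "Chromosome", "Start_Position", "End_Position",
    "Reference_Allele", "Tumor_Seq_Allele2",
    "Variant_Classification", "Variant_Type", "Tumor_Sample_Barcode"
  )
}

#' Copy-number state codes
#'
#' Ordinal gene-level copy-number states: -2 deep loss, -1 loss, 0 neutral,
#' +1 gain, +2 high-level amplification — the GISTIC-style discretization.
#'
#' @return Named integer vector mapping state labels to codes.
#' @examples
#' cn_state_codes()
#' @export
cn_state_codes <- function() {
  c(DEEP_LOSS = -2L, LOSS = -1L, NEUTRAL = 0L, GAIN = 1L, AMP = 2L)
}

cn_state_label <- function(code) {
  codes <- cn_state_codes()
  names(codes)[match(as.integer(code), codes)]
}

#' Six pyrimidine-collapsed substitution classes
#'
#' @return Character vector of the six classes in conventional order.
#' @examples
#' spectrum_classes()
#' @export
spectrum_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}
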