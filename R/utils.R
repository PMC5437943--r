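#' @import rlang
#' @importFrom dplyr %>% arrange bind_rows count distinct filter group_by
#'   left_join mutate n n_distinct pull rename row_number select slice
#'   summarise ungroup anti_join semi_join across all_of desc first
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats rbinom rnorm rpois runif setNames
#' @importFrom utils head
NULL

# Classified conditions: every user-facing failure is one of these three
# classes so callers (and the test suite) can distinguish malformed input,
# contract violations and schema problems.
abort_parse <- function(msg, ...) {
  rlang::abort(msg, class = "oncotally_parse_error", ...)
}
abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "oncotally_validation_error", ...)
}
abort_schema <- function(msg, ...) {
  rlang::abort(msg, class = "oncotally_schema_error", ...)
}

# Accept either a file path or literal text (single string with newlines or
# a character vector of lines). Keeps readers testable without temp files.
read_lines_any <- function(x) {
  if (length(x) == 1L && !grepl("[\n\t ]", x) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1L) {
    return(strsplit(x, "\n", fixed = TRUE)[[1]])
  }
  as.character(x)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_schema(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Deterministic seed derivation, kept well below .Machine$integer.max.
derive_seed <- function(seed, stream, index = 0L) {
  base <- as.integer(seed) %% 1000003L
  (base * 1009L + as.integer(stream) * 101L + as.integer(index)) %% 2000000011L
}
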