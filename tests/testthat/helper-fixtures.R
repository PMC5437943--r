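suppressMessages(library(dplyr))

# random chromosome table for planner property tests
random_chrom_table <- function(n = NULL) {
  if (is.null(n)) n <- sample(1:12, 1)
  tibble::tibble(
    chrom = paste0("chr", seq_len(n)),
    length = sample.int(5e6, n) + 10L
  )
}

# exhaustive minimum group count for capacity-bounded partition into
# whole-chromosome groups (independent oracle for FFD near-optimality)
optimal_group_count <- function(lengths, capacity) {
  n <- length(lengths)
  feasible <- vapply(seq_len(2^n - 1), function(mask) {
    sum(lengths[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]) <= capacity
  }, logical(1))
  best <- rep(Inf, 2^n)
  best[1] <- 0
  for (s in seq_len(2^n - 1)) {
    sub <- s # enumerate all non-empty subsets of s
    while (sub > 0) {
      if (feasible[sub]) {
        best[s + 1] <- min(best[s + 1], best[s - sub + 1] + 1)
      }
      sub <- bitwAnd(sub - 1L, s)
    }
  }
  best[2^n]
}

# simple random caller ensembles over a small variant universe
random_ensemble <- function(n_callers = NULL, n_variants = NULL) {
  if (is.null(n_callers)) n_callers <- sample(2:5, 1)
  if (is.null(n_variants)) n_variants <- sample(5:500, 1)
  universe <- tibble::tibble(
    chrom = sample(c("chr1", "chr2", "chr3"), n_variants, replace = TRUE),
    pos = sample.int(1e6, n_variants),
    ref = sample(c("A", "C", "G", "T"), n_variants, replace = TRUE)
  ) %>%
    mutate(alt = vapply(ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, character(1), USE.NAMES = FALSE)) %>%
    distinct(chrom, pos, .keep_all = TRUE)
  calls <- lapply(seq_len(n_callers), function(i) {
    keep <- runif(nrow(universe)) < runif(1, 0.2, 0.9)
    universe[keep, ]
  })
  names(calls) <- paste0("caller", seq_len(n_callers))
  calls
}

# brute-force membership-count voting oracle: for every key seen anywhere,
# count the callers whose set contains it
variant_key_str <- function(tbl) paste(tbl$chrom, tbl$pos, tbl$ref, tbl$alt)
vote_oracle <- function(calls, k) {
  sets <- lapply(calls, function(tbl) unique(variant_key_str(tbl)))
  keys <- unique(unlist(sets, use.names = FALSE))
  support <- rowSums(vapply(sets, function(s) keys %in% s,
                            logical(length(keys))))
  sort(keys[support >= k])
}

# small random MAF for aggregation tests
random_maf <- function(n = 50, n_genes = 8, n_patients = 6) {
  cls <- severity_ranks()$classification
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  tibble::tibble(
    Hugo_Symbol = sample(paste0("G", seq_len(n_genes)), n, replace = TRUE),
    Chromosome = sample(c("chr1", "chr2"), n, replace = TRUE),
    Start_Position = sample.int(1e5, n),
    End_Position = 0L,
    Reference_Allele = ref,
    Tumor_Seq_Allele2 = vapply(ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, character(1), USE.NAMES = FALSE),
    Variant_Classification = sample(cls, n, replace = TRUE),
    Variant_Type = "SNP",
    Tumor_Sample_Barcode = sample(paste0("S", seq_len(n_patients)), n,
                                  replace = TRUE)
  ) %>%
    mutate(End_Position = Start_Position)
}

# per-base segment->gene overlap oracle on a tiny genome
cn_state_oracle <- function(seg, genes, thresholds = c(-1, -0.25, 0.25, 1)) {
  out <- list()
  for (p in unique(seg$sample_id)) {
    sp <- seg[seg$sample_id == p, ]
    for (gi in seq_len(nrow(genes))) {
      g <- genes[gi, ]
      # overlap of every segment with the gene, base by base
      cover <- integer(0)
      ov <- numeric(nrow(sp))
      for (si in seq_len(nrow(sp))) {
        s <- sp[si, ]
        if (s$chrom != g$chrom) next
        bases <- intersect(seq(g$start, g$end - 1), seq(s$start, s$end - 1))
        ov[si] <- length(bases)
      }
      if (all(ov == 0)) {
        state <- 0L
      } else {
        best <- which(ov == max(ov))
        st <- cn_state_from_log2(sp$log2_ratio[best], thresholds)
        pick <- best[order(-abs(st), -abs(sp$log2_ratio[best]),
                           sp$start[best])][1]
        state <- cn_state_from_log2(sp$log2_ratio[pick], thresholds)
      }
      out[[length(out) + 1]] <- tibble::tibble(
        gene = g$symbol, patient = p, state = state
      )
    }
  }
  bind_rows(out)
}

small_design <- function(seed = 11, n_patients = 10, ...) {
  cohort_design(seed = seed, n_patients = n_patients,
                passenger_rate = 8, ...)
}
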