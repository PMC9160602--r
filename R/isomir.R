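#' IsomiR proportion profiles
#'
#' For every miRNA annotation, ranks its member sequences (isomiRs) by the
#' proportion of reads each contributes, pooling normalized values over all
#' samples and both groups. Ties in proportion are broken by lexicographic
#' sequence order.
#'
#' @param counts A normalized sequence count table.
#' @param sheet The matching sample sheet.
#' @return A tibble with columns `annotation`, `sequence`, `proportion`
#'   (sums to 1 within each annotation) and `rank` (1 = most abundant).
#'   Annotations with zero total signal are skipped with a warning.
#' @export
isomir_proportions <- function(counts, sheet) {
  counts <- as_tibble(counts)
  if (nrow(counts) == 0) {
    return(tibble(annotation = character(), sequence = character(),
                  proportion = numeric(), rank = integer()))
  }
  vals <- sample_values(counts, sheet)
  pooled <- tibble(annotation = counts$annotation,
                   sequence = counts$sequence,
                   total = rowSums(vals))
  zero_ann <- pooled |>
    group_by(.data$annotation) |>
    summarise(s = sum(.data$total), .groups = "drop") |>
    filter(.data$s == 0) |>
    pull("annotation")
  if (length(zero_ann) > 0) {
    warn(paste0("annotation(s) with zero total signal skipped: ",
                paste(zero_ann, collapse = ", ")))
  }
  pooled |>
    filter(!.data$annotation %in% zero_ann) |>
    group_by(.data$annotation) |>
    mutate(proportion = .data$total / sum(.data$total)) |>
    arrange(dplyr::desc(.data$proportion), .data$sequence,
            .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    select("annotation", "sequence", "proportion", "rank")
}

#' Flag consensus sequences in isomiR profiles
#'
#' Marks, for each annotation, the isomiR that exactly matches the reference
#' mature (consensus) sequence, after RNA-to-DNA alphabet normalization.
#'
#' @param profiles An isomiR profile tibble from [isomir_proportions()].
#' @param consensus A consensus set from [read_consensus_fasta()].
#' @return `profiles` with a logical `is_consensus` column added.
#' @export
flag_consensus <- function(profiles, consensus) {
  cons <- consensus
  cons$sequence <- normalize_sequence(cons$sequence)
  key <- paste(cons$annotation, cons$sequence, sep = "\r")
  mutate(profiles,
         is_consensus = paste(.data$annotation, .data$sequence,
                              sep = "\r") %in% key)
}

#' Per-annotation consensus proportions
#'
#' The fraction of an annotation's pooled reads carried by its consensus
#' sequence; 0 when the consensus was not observed among the isomiRs.
#'
#' @param profiles A flagged profile tibble from [flag_consensus()].
#' @return A tibble with `annotation` and `consensus_proportion`.
#' @export
consensus_proportions <- function(profiles) {
  if (!"is_consensus" %in% names(profiles)) {
    abort("profiles must be flagged with flag_consensus() first")
  }
  profiles |>
    group_by(.data$annotation) |>
    summarise(consensus_proportion =
                sum(.data$proportion[.data$is_consensus]),
              .groups = "drop")
}

#' Per-isomiR differential expression t-tests
#'
#' Unpaired two-tailed t-tests (Welch by default) comparing normalized
#' expression of every isomiR sequence between the HF and LF groups, followed
#' by Benjamini-Hochberg adjustment applied separately within each
#' annotation's family — the family size is the number of isomiRs of that
#' miRNA, a deliberately permissive exploratory correction.
#'
#' Degenerate sequences with zero variance in both groups get `p = 1` when
#' the group means are equal, and `p = 0` with `degenerate = TRUE` when they
#' differ.
#'
#' @param counts A normalized sequence count table.
#' @param sheet The matching sample sheet (>= 2 samples per group).
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#'   Default `FALSE`.
#' @param q FDR level used for the `significant` flag, default 0.05
#'   (`q_value <= q`).
#' @return A tibble with `sequence`, `annotation`, `mean_hf`, `mean_lf`, `t`,
#'   `p`, `q_value`, `significant`, `degenerate`.
#' @export
isomir_ttest <- function(counts, sheet, var_equal = FALSE, q = 0.05) {
  counts <- as_tibble(counts)
  if (any(group_sizes(sheet) < 2)) abort("need >= 2 samples per group")
  vals <- sample_values(counts, sheet)
  hf <- vals[, sheet$group == "HF", drop = FALSE]
  lf <- vals[, sheet$group == "LF", drop = FALSE]
  one <- function(i) {
    xh <- hf[i, ]; xl <- lf[i, ]
    if (sd(xh) == 0 && sd(xl) == 0) {
      if (mean(xh) == mean(xl)) {
        c(t = 0, p = 1, degenerate = 0)
      } else {
        c(t = sign(mean(xh) - mean(xl)) * Inf, p = 0, degenerate = 1)
      }
    } else {
      tt <- t.test(xh, xl, var.equal = var_equal)
      c(t = unname(tt$statistic), p = tt$p.value, degenerate = 0)
    }
  }
  stats <- t(vapply(seq_len(nrow(counts)), one, numeric(3)))
  out <- tibble(
    sequence = counts$sequence,
    annotation = counts$annotation,
    mean_hf = rowMeans(hf),
    mean_lf = rowMeans(lf),
    t = stats[, "t"],
    p = stats[, "p"],
    degenerate = stats[, "degenerate"] == 1
  )
  out |>
    group_by(.data$annotation) |>
    mutate(q_value = p.adjust(.data$p, method = "BH")) |>
    ungroup() |>
    mutate(significant = .data$q_value <= q) |>
    select("sequence", "annotation", "mean_hf", "mean_lf", "t", "p",
           "q_value", "significant", "degenerate")
}
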