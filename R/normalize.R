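#' Counts-per-million normalization
#'
#' Scales every sample column so the values sum to one million: the minimal
#' sequencing-depth correction. The divisor is the per-sample total over all
#' rows of the supplied table, so restricting the table to one biotype before
#' calling changes the divisor scope.
#'
#' @param counts A sequence count table (see [read_sequence_counts()]) or any
#'   table whose sample columns match the sheet.
#' @param sheet The matching sample sheet.
#' @return The same table with sample columns rescaled to CPM.
#' @examples
#' sheet <- validate_sample_sheet(
#'   data.frame(sample_id = c("a", "b"), group = c("HF", "LF")))
#' tbl <- data.frame(sequence = c("ACGT", "ACGG"),
#'                   annotation = c("m1", "m1"), a = c(10, 90), b = c(1, 9))
#' normalize_cpm(tbl, sheet)
#' @export
normalize_cpm <- function(counts, sheet) {
  counts <- as_tibble(counts)
  totals <- colSums(counts[, sheet$sample_id, drop = FALSE])
  zero <- sheet$sample_id[totals == 0]
  if (length(zero) > 0) {
    abort(paste0("sample(s) with zero total count: ",
                 paste(zero, collapse = ", ")))
  }
  for (s in sheet$sample_id) {
    counts[[s]] <- counts[[s]] / totals[[s]] * 1e6
  }
  counts
}

#' Normalized, miRNA-restricted, annotation-collapsed expression matrix
#'
#' Convenience composition of the standard preprocessing: CPM-normalize over
#' the whole table (so the divisor is the full library), restrict to rows of
#' biotype `"miRNA"` when a `biotype` column is present, and collapse by
#' annotation. The result is the input to [filter_expression()] and
#' [run_diffcorr()].
#'
#' @inheritParams normalize_cpm
#' @return A tibble with one row per miRNA annotation and one CPM column per
#'   sample.
#' @export
mirna_matrix <- function(counts, sheet) {
  norm <- normalize_cpm(counts, sheet)
  if ("biotype" %in% names(norm)) {
    norm <- filter(norm, .data$biotype == "miRNA")
  }
  collapse_by_annotation(norm, sheet)
}

#' Collapse a sequence-level table by miRNA annotation
#'
#' Sums values of all member sequences (isomiRs) of each annotation, per
#' sample, producing the miRNA-level expression matrix used by the
#' correlation analysis. Collapsing is linear, so it commutes with CPM
#' normalization.
#'
#' @inheritParams normalize_cpm
#' @return A tibble with one row per `annotation` and one value column per
#'   sample, in first-appearance annotation order.
#' @export
collapse_by_annotation <- function(counts, sheet) {
  counts <- as_tibble(counts)
  if (nrow(counts) == 0) {
    out <- tibble(annotation = character())
    for (s in sheet$sample_id) out[[s]] <- numeric()
    return(out)
  }
  counts |>
    group_by(annotation = factor(.data$annotation,
                                 levels = unique(counts$annotation))) |>
    summarise(across(all_of(sheet$sample_id), sum), .groups = "drop") |>
    mutate(annotation = as.character(.data$annotation))
}
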