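#' Expression-level filtering of the miRNA matrix
#'
#' Removes weakly and sporadically expressed miRNAs before pairwise
#' correlation: a row is retained when its mean normalized count across all
#' samples (both groups pooled) is at least `min_mean` AND it has at most
#' `max_zero_samples` samples with a zero value. The defaults encode the
#' rule "mean read counts < 100, or lacking reads in two or more samples,
#' are excluded".
#'
#' @param mat A collapsed miRNA matrix (see [collapse_by_annotation()]).
#' @param sheet The matching sample sheet.
#' @param min_mean Minimum mean normalized count, default 100; rows strictly
#'   below are excluded.
#' @param max_zero_samples Maximum tolerated number of zero-value samples,
#'   default 1; rows with more are excluded.
#' @return The filtered matrix, with a `filter_report` attribute retrievable
#'   via [filter_report()].
#' @export
filter_expression <- function(mat, sheet, min_mean = 100, max_zero_samples = 1) {
  mat <- as_tibble(mat)
  if (length(sheet$sample_id) < 1) abort("at least one sample required")
  vals <- sample_values(mat, sheet)
  means <- rowMeans(vals)
  n_zero <- rowSums(vals == 0)
  low_mean <- means < min_mean
  missing <- n_zero > max_zero_samples
  keep <- !low_mean & !missing
  out <- mat[keep, , drop = FALSE]
  report <- tibble(
    n_input = nrow(mat),
    n_excluded_low_mean = sum(low_mean),
    n_excluded_missingness = sum(missing),
    n_excluded = sum(!keep),
    n_retained = sum(keep)
  )
  attr(report, "retained_annotations") <- out$annotation
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the filter report of a filtered matrix
#'
#' @param mat A matrix returned by [filter_expression()].
#' @return A one-row tibble with input/excluded/retained counts; the retained
#'   annotation names are in its `retained_annotations` attribute.
#' @export
filter_report <- function(mat) {
  rep <- attr(mat, "filter_report")
  if (is.null(rep)) abort("no filter report attached; run filter_expression()")
  rep
}

#' Small-RNA biotype composition
#'
#' Summarises what fraction of annotated reads each small-RNA class (miRNA,
#' piRNA, tRNA fragment, ...) contributes, per sample and overall. Rows
#' without a biotype label are assigned `"other"` with a warning.
#'
#' @param counts A sequence count table carrying a `biotype` column.
#' @param sheet The matching sample sheet.
#' @return A long tibble with columns `biotype`, `sample_id` (the pooled
#'   summary uses `"overall"`), and `proportion`; proportions sum to 1 within
#'   each `sample_id`.
#' @export
biotype_composition <- function(counts, sheet) {
  counts <- as_tibble(counts)
  if (nrow(counts) == 0) {
    return(tibble(biotype = character(), sample_id = character(),
                  proportion = numeric()))
  }
  if (!"biotype" %in% names(counts)) {
    warn("no biotype column; labelling all rows 'other'")
    counts$biotype <- "other"
  } else if (anyNA(counts$biotype) || any(!nzchar(counts$biotype))) {
    warn("unlabelled rows assigned biotype 'other'")
    counts$biotype[is.na(counts$biotype) | !nzchar(counts$biotype)] <- "other"
  }
  long <- counts |>
    select(all_of(c("biotype", sheet$sample_id))) |>
    tidyr::pivot_longer(all_of(sheet$sample_id), names_to = "sample_id",
                        values_to = "value") |>
    group_by(.data$biotype, .data$sample_id) |>
    summarise(value = sum(.data$value), .groups = "drop")
  per_sample <- long |>
    group_by(.data$sample_id) |>
    mutate(proportion = .data$value / sum(.data$value)) |>
    ungroup()
  overall <- long |>
    group_by(.data$biotype) |>
    summarise(value = sum(.data$value), .groups = "drop") |>
    mutate(sample_id = "overall", proportion = .data$value / sum(.data$value))
  bind_rows(per_sample, overall) |>
    select("biotype", "sample_id", "proportion") |>
    arrange(.data$sample_id, dplyr::desc(.data$proportion))
}
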