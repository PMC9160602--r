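#' Read and validate a sample sheet
#'
#' The sample sheet describes the sequenced animals: one row per sample with a
#' unique `sample_id`, a fertility `group` (`"HF"` for high fertility, `"LF"`
#' for low fertility; matched case-insensitively), and optionally the
#' sire conception rate `scr` (herd-relative percentage points).
#'
#' @param path Path to a comma- or tab-delimited file with a header containing
#'   at least `sample_id` and `group` columns; an `scr` column is kept when
#'   present.
#' @return A tibble with columns `sample_id` (character), `group` (factor with
#'   levels `HF`, `LF`) and, if supplied, `scr` (numeric).
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,group,scr", "b1,HF,2.1", "b2,lf,-2.7"), path)
#' read_sample_sheet(path)
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("sample sheet not found: ", path))
  }
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           trim_ws = TRUE)
  validate_sample_sheet(raw)
}

#' Validate an in-memory sample sheet
#'
#' @param sheet A data frame with `sample_id`, `group` and optionally `scr`.
#' @return A validated tibble (see [read_sample_sheet()]).
#' @export
validate_sample_sheet <- function(sheet) {
  sheet <- as_tibble(sheet)
  missing_cols <- setdiff(c("sample_id", "group"), names(sheet))
  if (length(missing_cols) > 0) {
    abort(paste0("sample sheet is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  sheet$sample_id <- as.character(sheet$sample_id)
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sample id(s): ", paste(unique(dup), collapse = ", ")))
  }
  grp <- toupper(trimws(as.character(sheet$group)))
  bad <- setdiff(unique(grp), c("HF", "LF"))
  if (length(bad) > 0) {
    abort(paste0("unknown group label(s): ", paste(bad, collapse = ", "),
                 " (expected HF or LF)"))
  }
  sheet$group <- factor(grp, levels = c("HF", "LF"))
  if (any(table(factor(grp, levels = c("HF", "LF"))) == 0)) {
    abort("both fertility groups (HF and LF) must be represented")
  }
  if ("scr" %in% names(sheet)) {
    sheet$scr <- as.numeric(sheet$scr)
  }
  keep <- intersect(c("sample_id", "group", "scr"), names(sheet))
  sheet[keep]
}

group_sizes <- function(sheet) {
  c(n_hf = sum(sheet$group == "HF"), n_lf = sum(sheet$group == "LF"))
}

sample_values <- function(tbl, sheet) {
  as.matrix(tbl[, sheet$sample_id, drop = FALSE])
}
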