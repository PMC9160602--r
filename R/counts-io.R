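#' Read a sequence-level (isomiR) count table
#'
#' Reads the non-collapsed small-RNA count table: one row per observed
#' (sequence, annotation) combination and one integer count column per
#' sample. This is the shape produced by annotation tools that report every
#' distinct sequence assigned to a miRNA. Sequences may use U or T; they are
#' stored internally in the DNA alphabet (U converted to T). Sample columns
#' are reordered to match the sample sheet.
#'
#' @param path Path to a tab-delimited file with header columns `sequence`,
#'   `annotation`, then one column per sample id. An optional `biotype`
#'   column is kept when present.
#' @param sheet A sample sheet from [read_sample_sheet()].
#' @return A tibble with columns `sequence`, `annotation`, (`biotype`,) then
#'   one numeric column per sample in sheet order.
#' @export
read_sequence_counts <- function(path, sheet) {
  if (!file.exists(path)) {
    abort(paste0("count table not found: ", path))
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  validate_sequence_counts(raw, sheet)
}

#' Validate an in-memory sequence count table against a sample sheet
#'
#' @param tbl Data frame with `sequence`, `annotation`, optional `biotype`,
#'   and one count column per sample.
#' @inheritParams read_sequence_counts
#' @return A validated tibble with sample columns in sheet order.
#' @export
validate_sequence_counts <- function(tbl, sheet) {
  tbl <- as_tibble(tbl)
  meta_cols <- intersect(c("sequence", "annotation", "biotype"), names(tbl))
  if (!all(c("sequence", "annotation") %in% meta_cols)) {
    abort("count table must have 'sequence' and 'annotation' columns")
  }
  missing_samples <- setdiff(sheet$sample_id, names(tbl))
  if (length(missing_samples) > 0) {
    abort(paste0("count table is missing sample column(s): ",
                 paste(missing_samples, collapse = ", ")))
  }
  extra <- setdiff(names(tbl), c(meta_cols, sheet$sample_id))
  if (length(extra) > 0) {
    abort(paste0("count table has unknown column(s): ",
                 paste(extra, collapse = ", ")))
  }
  tbl$sequence <- normalize_sequence(tbl$sequence)
  key <- paste(tbl$sequence, tbl$annotation, sep = "\r")
  if (anyDuplicated(key)) {
    abort("duplicate (sequence, annotation) rows in count table")
  }
  vals <- as.matrix(tbl[, sheet$sample_id, drop = FALSE])
  if (!is.numeric(vals)) abort("sample columns must be numeric counts")
  if (anyNA(vals)) abort("sample columns contain missing values")
  if (any(vals < 0)) abort("negative counts are not allowed")
  if (any(vals != floor(vals))) abort("counts must be integers")
  tbl[c(meta_cols, sheet$sample_id)]
}

# Uppercase and map RNA to DNA alphabet; validate characters.
normalize_sequence <- function(x) {
  x <- chartr("U", "T", toupper(as.character(x)))
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(paste0("invalid sequence character(s) in: ",
                 paste(head(x[bad], 3), collapse = ", ")))
  }
  x
}

#' Read a mature-miRNA consensus FASTA
#'
#' Builds the map from miRNA annotation name to its reference (consensus)
#' mature sequence, e.g. from miRBase. The first whitespace-delimited token of
#' each FASTA header is taken as the annotation name. U is converted to T so
#' consensus sequences compare directly with count-table sequences.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `annotation` and `sequence` (DNA alphabet).
#'   Duplicate identical entries are silently deduplicated; duplicate names
#'   with differing sequences are an error.
#' @export
read_consensus_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("consensus FASTA not found: ", path))
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) {
    return(tibble(annotation = character(), sequence = character()))
  }
  ann <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  out <- tibble(annotation = ann,
                sequence = normalize_sequence(as.character(seqs)))
  if (any(!nzchar(out$sequence))) abort("empty consensus sequence in FASTA")
  out <- distinct(out)
  if (anyDuplicated(out$annotation)) {
    dup <- unique(out$annotation[duplicated(out$annotation)])
    abort(paste0("conflicting consensus sequences for: ",
                 paste(dup, collapse = ", ")))
  }
  out
}

#' Filter a FASTQ file on read length and mean base quality
#'
#' Optional pre-annotation quality control: keeps reads strictly longer than
#' `min_len` nucleotides whose mean Phred score is strictly greater than
#' `min_mean_q`, mirroring a "lengths above 18 nt and Phred scores above 30"
#' rule with strict inequalities.
#'
#' @param path Input FASTQ path.
#' @param out Output FASTQ path for retained reads.
#' @param min_len Minimum length bound (reads of exactly this length are
#'   dropped). Default 18.
#' @param min_mean_q Mean Phred bound (reads with mean exactly this value are
#'   dropped). Default 30.
#' @return Invisibly, a tibble with `n_input`, `n_retained`,
#'   `n_dropped_length`, `n_dropped_quality` (a read failing both rules counts
#'   under length).
#' @export
filter_fastq <- function(path, out, min_len = 18, min_mean_q = 30) {
  if (!file.exists(path)) abort(paste0("FASTQ not found: ", path))
  reads <- tryCatch(
    # the parser's "metadata columns dropped" note is irrelevant here
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) {
      idx <- diagnose_fastq(path)
      if (!is.na(idx)) {
        abort(paste0("malformed FASTQ record at index ", idx, ": ",
                     conditionMessage(e)))
      }
      abort(paste0("malformed FASTQ: ", conditionMessage(e)))
    })
  lens <- Biostrings::width(reads)
  qmeans <- vapply(as(Biostrings::quality(reads), "IntegerList"),
                   function(q) mean(q), numeric(1))
  long_enough <- lens > min_len
  good_quality <- qmeans > min_mean_q
  keep <- long_enough & good_quality
  kept <- reads[keep]
  dna <- Biostrings::DNAStringSet(as.character(kept))
  names(dna) <- names(kept)
  Biostrings::writeXStringSet(dna, filepath = out, format = "fastq",
                              qualities = Biostrings::quality(kept))
  invisible(tibble(
    n_input = length(reads),
    n_retained = sum(keep),
    n_dropped_length = sum(!long_enough),
    n_dropped_quality = sum(long_enough & !good_quality)
  ))
}

# Locate the first structurally invalid FASTQ record (1-based index), NA if
# the file looks structurally fine.
diagnose_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n_rec <- ceiling(length(lines) / 4)
  for (i in seq_len(n_rec)) {
    block <- lines[(4 * (i - 1) + 1):min(4 * i, length(lines))]
    if (length(block) < 4 ||
        !startsWith(block[1], "@") ||
        !startsWith(block[3], "+") ||
        nchar(block[2]) != nchar(block[4])) {
      return(i)
    }
  }
  NA_integer_
}

#' Write a table as TSV
#'
#' Thin wrapper used for all tabular outputs (UTF-8, `.` decimal separator,
#' header row).
#'
#' @param tbl A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mirdcor_tsv <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}
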