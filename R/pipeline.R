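#' Run the full analysis pipeline and write a results directory
#'
#' End-to-end orchestration: read (or accept in-memory) inputs, CPM
#' normalization, annotation collapsing, expression filtering, the
#' differential-correlation funnel, isomiR profiling and differential tests,
#' optional consensus flagging and shared-target analysis. All stage outputs
#' are written as TSV into `out_dir` together with a machine-readable
#' `funnel_report.tsv`. The run is deterministic given its inputs and
#' thresholds (no randomness is involved).
#'
#' @param counts Path to a sequence count TSV, or the table itself.
#' @param samples Path to a sample sheet, or the sheet itself.
#' @param out_dir Output directory, created if needed.
#' @param consensus Optional path to a mature-miRNA FASTA (or a consensus
#'   tibble) for isomiR consensus flagging.
#' @param interactions Optional path to a miRNA-gene interaction TSV (or
#'   tibble); enables shared-target counting over significant pairs.
#' @param context Optional path to a context gene list (or tibble); shared
#'   targets are additionally filtered to this context.
#' @param min_mean,max_zero_samples Expression filter thresholds
#'   (see [filter_expression()]).
#' @param alpha,fdr,orientation,log2_expr,bh_family,max_exact Passed to
#'   [run_diffcorr()].
#' @param min_pairs Threshold for [co_target_count()] (default 1).
#' @param quiet Suppress INFO log lines on standard error.
#' @return Invisibly, a list with `diffcorr` (the [run_diffcorr()] object),
#'   `filtered`, `profiles`, `isomir_tests`, `funnel`, and (when requested)
#'   `co_targets`.
#' @export
run_pipeline <- function(counts, samples, out_dir,
                         consensus = NULL, interactions = NULL,
                         context = NULL,
                         min_mean = 100, max_zero_samples = 1,
                         alpha = 0.05, fdr = 0.05,
                         orientation = "lex", log2_expr = FALSE,
                         bh_family = "candidates", max_exact = 9,
                         min_pairs = 1, quiet = FALSE) {
  log_info <- function(...) {
    if (!quiet) message("INFO [mirdcor] ", sprintf(...))
  }
  sheet <- if (is.character(samples)) read_sample_sheet(samples) else
    validate_sample_sheet(samples)
  tbl <- if (is.character(counts)) read_sequence_counts(counts, sheet) else
    validate_sequence_counts(counts, sheet)
  log_info("loaded %d sequences x %d samples (%d HF, %d LF)",
           nrow(tbl), nrow(sheet), sum(sheet$group == "HF"),
           sum(sheet$group == "LF"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  norm <- normalize_cpm(tbl, sheet)
  norm_mirna <- if ("biotype" %in% names(norm)) {
    filter(norm, .data$biotype == "miRNA")
  } else norm
  mat <- collapse_by_annotation(norm_mirna, sheet)
  log_info("collapsed to %d miRNA annotations", nrow(mat))
  if ("biotype" %in% names(norm)) {
    write_mirdcor_tsv(biotype_composition(tbl, sheet),
                      file.path(out_dir, "biotype_composition.tsv"))
  }
  filtered <- filter_expression(mat, sheet, min_mean = min_mean,
                                max_zero_samples = max_zero_samples)
  frep <- filter_report(filtered)
  log_info("expression filter retained %d / %d annotations",
           frep$n_retained, frep$n_input)
  write_mirdcor_tsv(filtered, file.path(out_dir, "mirna_matrix.tsv"))
  write_mirdcor_tsv(frep, file.path(out_dir, "filter_report.tsv"))

  dc <- run_diffcorr(filtered, sheet, alpha = alpha, fdr = fdr,
                     orientation = orientation, log2_expr = log2_expr,
                     bh_family = bh_family, max_exact = max_exact)
  funnel <- glance(dc)
  log_info(paste0("funnel: %d pairs -> %d dual-gate -> %d candidates -> ",
                  "%d significant (%d CH, %d CL)"),
           funnel$n_pairs, funnel$n_dual_gate, funnel$n_candidates,
           funnel$n_significant, funnel$n_ch, funnel$n_cl)
  write_mirdcor_tsv(as_tibble(dc), file.path(out_dir, "diffcorr_all.tsv"))
  write_mirdcor_tsv(tidy(dc), file.path(out_dir, "diffcorr_significant.tsv"))
  write_mirdcor_tsv(funnel, file.path(out_dir, "funnel_report.tsv"))

  profiles <- isomir_proportions(norm_mirna, sheet)
  if (!is.null(consensus)) {
    cons <- if (is.character(consensus)) read_consensus_fasta(consensus) else
      as_tibble(consensus)
    profiles <- flag_consensus(profiles, cons)
    write_mirdcor_tsv(consensus_proportions(profiles),
                      file.path(out_dir, "consensus_proportions.tsv"))
  }
  write_mirdcor_tsv(profiles, file.path(out_dir, "isomir_profiles.tsv"))
  tests <- isomir_ttest(norm_mirna, sheet, q = fdr)
  write_mirdcor_tsv(tests, file.path(out_dir, "isomir_tests.tsv"))
  log_info("isomiR tests: %d sequences, %d significant at q <= %.2f",
           nrow(tests), sum(tests$significant), fdr)

  out <- list(diffcorr = dc, filtered = filtered, profiles = profiles,
              isomir_tests = tests, funnel = funnel)
  if (!is.null(interactions)) {
    itab <- if (is.character(interactions)) read_interactions(interactions)
      else as_tibble(interactions)
    ct <- co_target_count(tidy(dc), itab, min_pairs = min_pairs)
    if (!is.null(context)) {
      ctx <- if (is.character(context)) read_context_list(context) else
        as_tibble(context)
      ct <- filter(ct, .data$gene %in% filter_by_context(.data$gene, ctx))
    }
    write_mirdcor_tsv(ct, file.path(out_dir, "co_targets.tsv"))
    out$co_targets <- ct
    log_info("co-target analysis: %d genes at min_pairs = %d",
             nrow(ct), min_pairs)
  }
  invisible(out)
}
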