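#' Plot the differential-correlation landscape
#'
#' Scatter of within-group Spearman correlations, one point per pair:
#' HF correlation on the x axis, LF on the y axis. Significant pairs are
#' colored by CH/CL class; sign-reversal quadrants (off-diagonal) are where
#' differentially correlated pairs live.
#'
#' @param object A `diffcorr` object from [run_diffcorr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diffcorr
#' @export
autoplot.diffcorr <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(status = if_else(.data$significant,
                            as.character(.data$class), "not significant"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho_hf, y = .data$rho_lf)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status,
                                     alpha = .data$significant)) +
    ggplot2::scale_colour_manual(values = c(
      CH = "#D55E00", CL = "#0072B2", `not significant` = "grey70")) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.4),
                                guide = "none") +
    ggplot2::labs(x = "Spearman rho (high fertility)",
                  y = "Spearman rho (low fertility)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of one miRNA pair with per-group regression lines
#'
#' Visualises the sign reversal behind a CH or CL call: expression of one
#' miRNA against the other, per sample, with an ordinary least-squares line
#' per fertility group.
#'
#' @param mat A miRNA matrix (`annotation` + sample columns).
#' @param sheet The matching sample sheet.
#' @param mirna_a,mirna_b Annotation names; `mirna_a` is the y axis
#'   (the model response).
#' @return A ggplot object.
#' @export
plot_pair <- function(mat, sheet, mirna_a, mirna_b) {
  mat <- as_tibble(mat)
  for (m in c(mirna_a, mirna_b)) {
    if (!m %in% mat$annotation) abort(paste0("annotation not found: ", m))
  }
  X <- sample_values(mat, sheet)
  rownames(X) <- mat$annotation
  df <- tibble(sample_id = sheet$sample_id, group = sheet$group,
               a = X[mirna_a, ], b = X[mirna_b, ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$a,
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::scale_colour_manual(values = c(HF = "#D55E00", LF = "#0072B2")) +
    ggplot2::labs(x = paste(mirna_b, "(normalized expression)"),
                  y = paste(mirna_a, "(normalized expression)"),
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' Bar plot of an annotation's isomiR proportion profile
#'
#' Ranked isomiR proportions for one miRNA; the consensus sequence (when
#' flagged) is highlighted, echoing the common observation that the dominant
#' isomiR need not be the reference sequence.
#'
#' @param profiles A profile tibble from [isomir_proportions()], optionally
#'   flagged by [flag_consensus()].
#' @param annotation The miRNA to plot.
#' @param top Show at most this many isomiRs (default 10).
#' @return A ggplot object.
#' @export
plot_isomir_profile <- function(profiles, annotation, top = 10) {
  df <- filter(profiles, .data$annotation == !!annotation) |>
    arrange(.data$rank) |>
    head(top)
  if (nrow(df) == 0) abort(paste0("annotation not found: ", annotation))
  if (!"is_consensus" %in% names(df)) df$is_consensus <- FALSE
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$rank),
                                   y = .data$proportion,
                                   fill = .data$is_consensus)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40",
                                          `TRUE` = "#D55E00"),
                               labels = c(`FALSE` = "isomiR",
                                          `TRUE` = "consensus")) +
    ggplot2::labs(x = "isomiR rank", y = "proportion of reads",
                  fill = NULL, title = annotation) +
    ggplot2::theme_minimal()
}
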