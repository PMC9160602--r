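#' Enumerate all unordered miRNA pairs
#'
#' @param annotations Character vector of unique miRNA names.
#' @return A tibble with columns `mirna_a`, `mirna_b`, each pair
#'   lexicographically ordered (`mirna_a < mirna_b`), `M (M - 1) / 2` rows.
#' @examples
#' enumerate_pairs(c("miR-1", "miR-2", "miR-3"))
#' @export
enumerate_pairs <- function(annotations) {
  annotations <- as.character(annotations)
  if (anyDuplicated(annotations)) abort("annotation names must be unique")
  M <- length(annotations)
  if (M < 2) {
    return(tibble(mirna_a = character(), mirna_b = character()))
  }
  idx <- which(upper.tri(diag(M)), arr.ind = TRUE)
  a <- annotations[idx[, 1]]
  b <- annotations[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  tibble(mirna_a = a, mirna_b = b) |> arrange(.data$mirna_a, .data$mirna_b)
}

#' Within-group Spearman correlations for every miRNA pair
#'
#' Computes, for each unordered pair of rows of the expression matrix, the
#' Spearman correlation and two-sided p-value separately within the HF and LF
#' sample groups (exact permutation p at small tie-free sample sizes, see
#' [spearman_exact()]). Pairs involving a miRNA that is constant within
#' either group have an undefined correlation and are flagged.
#'
#' @param mat A filtered miRNA matrix (`annotation` + sample columns).
#' @param sheet The matching sample sheet.
#' @param max_exact Passed to the Spearman engine.
#' @return A tibble with columns `mirna_a`, `mirna_b`, `rho_hf`, `p_hf`,
#'   `rho_lf`, `p_lf`, `undefined`.
#' @export
pair_correlations <- function(mat, sheet, max_exact = 9) {
  mat <- as_tibble(mat)
  if (anyDuplicated(mat$annotation)) abort("annotation names must be unique")
  ann <- mat$annotation
  X <- sample_values(mat, sheet)
  hf <- spearman_all_pairs(X[, sheet$group == "HF", drop = FALSE], max_exact)
  lf <- spearman_all_pairs(X[, sheet$group == "LF", drop = FALSE], max_exact)
  a <- ann[hf$i]; b <- ann[hf$j]
  swap <- a > b
  rec <- tibble(
    mirna_a = ifelse(swap, b, a),
    mirna_b = ifelse(swap, a, b),
    rho_hf = hf$rho, p_hf = hf$p,
    rho_lf = lf$rho, p_lf = lf$p,
    undefined = hf$undefined | lf$undefined
  )
  arrange(rec, .data$mirna_a, .data$mirna_b)
}

#' Dual significance gate on within-group correlations
#'
#' Retains pairs whose Spearman correlation is significant (two-sided
#' `p < alpha`) in both fertility groups independently.
#'
#' @param records A pair-correlation tibble from [pair_correlations()].
#' @param alpha Per-group significance level, default 0.05 (strict `<`).
#' @return The retained subset.
#' @export
dual_gate <- function(records, alpha = 0.05) {
  filter(records, !is.na(.data$p_hf), !is.na(.data$p_lf),
         .data$p_hf < alpha, .data$p_lf < alpha)
}

#' Fit the group-interaction linear model for one oriented miRNA pair
#'
#' Fits, by ordinary least squares,
#' `y = beta0 + beta1 * x + beta2 * LOW + beta3 * LOW * x`,
#' where `LOW` is 1 for low-fertility samples and 0 for high-fertility
#' samples. `beta1` is the HF slope of the response miRNA on the predictor
#' miRNA; `beta3` is the LF-minus-HF slope difference, so a significant
#' `beta3` indicates group-specific slopes. `(beta0, beta1)` equal the
#' HF-only fit and `(beta0 + beta2, beta1 + beta3)` the LF-only fit.
#'
#' @param y Response miRNA expression vector (all samples).
#' @param x Predictor miRNA expression vector.
#' @param low 0/1 indicator vector (1 = low-fertility sample).
#' @return An object of class `interaction_fit`: a list with `coefficients`
#'   (tibble of term, estimate, std.error, statistic, p.value), `df.residual`
#'   (`n - 4`), and `sigma`. Supports [tidy()] and [glance()].
#' @export
fit_interaction <- function(y, x, low) {
  n <- length(y)
  if (length(x) != n || length(low) != n) abort("y, x, low lengths differ")
  if (!all(low %in% c(0, 1))) abort("low must be a 0/1 indicator")
  if (n < 6 || sum(low == 0) < 3 || sum(low == 1) < 3) {
    abort("need >= 6 samples with >= 3 per group")
  }
  low <- as.numeric(low)
  fit <- lm(y ~ x + low + x:low)
  if (anyNA(coef(fit))) {
    abort("rank-deficient design: predictor is collinear within a group")
  }
  cf <- summary(fit)$coefficients
  out <- structure(list(
    coefficients = tibble(
      term = c("beta0", "beta1", "beta2", "beta3"),
      estimate = unname(cf[, 1]),
      std.error = unname(cf[, 2]),
      statistic = unname(cf[, 3]),
      p.value = unname(cf[, 4])
    ),
    df.residual = fit$df.residual,
    sigma = summary(fit)$sigma,
    n = n
  ), class = "interaction_fit")
  out
}

#' @method tidy interaction_fit
#' @export
tidy.interaction_fit <- function(x, ...) x$coefficients

#' @method glance interaction_fit
#' @export
glance.interaction_fit <- function(x, ...) {
  tibble(sigma = x$sigma, df.residual = x$df.residual, nobs = x$n)
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat("Group-interaction OLS fit (", x$n, " samples, df = ",
      x$df.residual, ")\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Select candidate pairs with significant slope and slope difference
#'
#' Retains fits in which both `beta1` (the HF slope) and `beta3` (the
#' LF-minus-HF slope difference) are significant, i.e. pairs showing a real
#' and group-dependent relationship.
#'
#' @param fits A tibble carrying columns `p1` and `p3`.
#' @param alpha Significance level, default 0.05 (strict `<`).
#' @return The retained subset.
#' @export
select_candidates <- function(fits, alpha = 0.05) {
  filter(fits, .data$p1 < alpha, .data$p3 < alpha)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values with rejection flags at level `q`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level, default 0.05; reject when adjusted `p <= q`.
#' @return A tibble with columns `p`, `q_value`, `reject`, in input order.
#' @export
bh_adjust <- function(p, q = 0.05) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must be in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  tibble(p = p, q_value = adj, reject = adj <= q)
}

#' Classify a differentially correlated pair by its sign pattern
#'
#' `CH` ("cooperative in high fertility"): positive Spearman correlation in
#' the HF group and negative in the LF group. `CL`: the mirror pattern.
#' Any other pattern (including a correlation of exactly zero) is
#' `DISCORDANT`.
#'
#' @param rho_hf,rho_lf Numeric vectors of within-group correlations.
#' @return A factor with levels `CH`, `CL`, `DISCORDANT`.
#' @export
classify_pair <- function(rho_hf, rho_lf) {
  if (any(rho_hf == 0 | rho_lf == 0, na.rm = TRUE)) {
    warn("correlation of exactly 0: classified DISCORDANT")
  }
  cls <- dplyr::case_when(
    rho_hf > 0 & rho_lf < 0 ~ "CH",
    rho_hf < 0 & rho_lf > 0 ~ "CL",
    TRUE ~ "DISCORDANT"
  )
  factor(cls, levels = c("CH", "CL", "DISCORDANT"))
}

#' Run the full differential-correlation analysis
#'
#' The staged funnel: enumerate all unordered miRNA pairs; compute
#' within-group Spearman correlations and retain pairs significant in both
#' groups ([dual_gate()]); fit the group-interaction model per surviving pair
#' ([fit_interaction()]); retain pairs with significant `beta1` and `beta3`
#' ([select_candidates()]); apply Benjamini-Hochberg control to the `beta3`
#' p-values of that candidate family; classify rejected pairs as CH or CL by
#' their correlation sign pattern.
#'
#' @param mat A filtered miRNA matrix (`annotation` + sample columns).
#' @param sheet The matching sample sheet (>= 3 samples per group; >= 4 per
#'   group for the correlation stage).
#' @param alpha Per-test significance level for the dual gate and the
#'   candidate selection, default 0.05.
#' @param fdr FDR level for the BH stage, default 0.05.
#' @param orientation `"lex"` (default): the lexicographically first miRNA of
#'   a pair is the model response. `"both"`: fit both orientations and
#'   require the candidate condition in each; reported coefficients are from
#'   the lexicographic orientation.
#' @param log2_expr Model expression on the `log2(value + 1)` scale in the
#'   interaction fit (Spearman stages are rank-based and unaffected).
#'   Default `FALSE`.
#' @param bh_family `"candidates"` (default): adjust the `beta3` p-values of
#'   the pairs passing [select_candidates()]. `"survivors"`: adjust across
#'   all dual-gate survivors instead (candidate selection is then applied
#'   after adjustment, on the same unadjusted rule).
#' @param max_exact Largest tie-free group size for exact Spearman p-values.
#' @return A `diffcorr` object: a tibble with one row per defined pair
#'   (`mirna_a`, `mirna_b`, `rho_hf`, `p_hf`, `rho_lf`, `p_lf`, stage flags
#'   `passed_dual_gate`, `is_candidate`, the fitted `beta0..beta3`,
#'   `se1`, `se3`, `p1`, `p3`, `q_value`, `significant`, `class`) with the
#'   stage-count funnel in its attributes. Use [glance()] for the funnel and
#'   [tidy()] for the significant pairs.
#' @export
run_diffcorr <- function(mat, sheet, alpha = 0.05, fdr = 0.05,
                         orientation = c("lex", "both"),
                         log2_expr = FALSE,
                         bh_family = c("candidates", "survivors"),
                         max_exact = 9) {
  orientation <- match.arg(orientation)
  bh_family <- match.arg(bh_family)
  mat <- as_tibble(mat)
  rec <- pair_correlations(mat, sheet, max_exact = max_exact)
  n_pairs <- nrow(rec)
  n_undefined <- sum(rec$undefined)
  rec <- filter(rec, !.data$undefined)
  rec$passed_dual_gate <- rec$p_hf < alpha & rec$p_lf < alpha

  expr <- sample_values(mat, sheet)
  rownames(expr) <- mat$annotation
  if (log2_expr) expr <- log2(expr + 1)
  low <- as.numeric(sheet$group == "LF")

  fit_cols <- c("beta0", "beta1", "beta2", "beta3", "se1", "se3", "p1", "p3")
  for (cl in fit_cols) rec[[cl]] <- NA_real_
  surv <- which(rec$passed_dual_gate)
  both_ok <- rep(TRUE, nrow(rec))
  for (k in surv) {
    a <- rec$mirna_a[k]; b <- rec$mirna_b[k]
    f <- fit_interaction(expr[a, ], expr[b, ], low)
    est <- f$coefficients
    rec$beta0[k] <- est$estimate[1]; rec$beta1[k] <- est$estimate[2]
    rec$beta2[k] <- est$estimate[3]; rec$beta3[k] <- est$estimate[4]
    rec$se1[k] <- est$std.error[2]; rec$se3[k] <- est$std.error[4]
    rec$p1[k] <- est$p.value[2]; rec$p3[k] <- est$p.value[4]
    if (orientation == "both") {
      g <- fit_interaction(expr[b, ], expr[a, ], low)
      both_ok[k] <- g$coefficients$p.value[2] < alpha &&
        g$coefficients$p.value[4] < alpha
    }
  }
  rec$is_candidate <- rec$passed_dual_gate &
    !is.na(rec$p1) & rec$p1 < alpha &
    !is.na(rec$p3) & rec$p3 < alpha & both_ok

  rec$q_value <- NA_real_
  rec$significant <- FALSE
  family_idx <- if (bh_family == "candidates") {
    which(rec$is_candidate)
  } else {
    which(rec$passed_dual_gate)
  }
  if (length(family_idx) > 0) {
    adj <- bh_adjust(rec$p3[family_idx], q = fdr)
    rec$q_value[family_idx] <- adj$q_value
    rec$significant[family_idx] <- adj$reject & rec$is_candidate[family_idx]
  }
  rec$class <- suppressWarnings(classify_pair(rec$rho_hf, rec$rho_lf))

  funnel <- tibble(
    n_mirna = nrow(mat),
    n_pairs = n_pairs,
    n_undefined = n_undefined,
    n_dual_gate = sum(rec$passed_dual_gate),
    n_candidates = sum(rec$is_candidate),
    n_significant = sum(rec$significant),
    n_ch = sum(rec$significant & rec$class == "CH"),
    n_cl = sum(rec$significant & rec$class == "CL")
  )
  structure(rec,
            class = c("diffcorr", class(rec)),
            funnel = funnel,
            alpha = alpha, fdr = fdr,
            orientation = orientation, bh_family = bh_family)
}

#' Significant differentially correlated pairs
#'
#' @param x A `diffcorr` object from [run_diffcorr()].
#' @param ... Unused.
#' @return Tibble of BH-significant pairs with correlations, model estimates,
#'   `q_value` and CH/CL class.
#' @method tidy diffcorr
#' @export
tidy.diffcorr <- function(x, ...) {
  out <- as_tibble(x)[x$significant, , drop = FALSE]
  select(out, "mirna_a", "mirna_b", "rho_hf", "p_hf", "rho_lf", "p_lf",
         "beta1", "beta3", "p1", "p3", "q_value", "class")
}

#' Stage-count funnel of a differential-correlation run
#'
#' @param x A `diffcorr` object.
#' @param ... Unused.
#' @return One-row tibble: miRNAs, pairs, undefined pairs, dual-gate
#'   survivors, candidates, BH-significant pairs, CH and CL counts.
#' @method glance diffcorr
#' @export
glance.diffcorr <- function(x, ...) attr(x, "funnel")

#' @export
print.diffcorr <- function(x, ...) {
  f <- attr(x, "funnel")
  cat("Differential-correlation analysis: ", f$n_mirna, " miRNAs, ",
      f$n_pairs, " pairs -> ", f$n_dual_gate, " dual-gate -> ",
      f$n_candidates, " candidates -> ", f$n_significant,
      " significant (", f$n_ch, " CH, ", f$n_cl, " CL)\n", sep = "")
  NextMethod()
}
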