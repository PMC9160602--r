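#' Configuration for the synthetic sperm small-RNA count generator
#'
#' The generator emulates the study design the pipeline targets: 7
#' high-fertility and 6 low-fertility bulls, a few hundred miRNA annotations
#' each split into isomiRs, negative-binomial count marginals, and optional
#' planted miRNA pairs whose between-miRNA rank correlation has a chosen
#' value in each fertility group (possibly of opposite sign).
#'
#' Counts arise from a Gaussian copula: per group, a latent standard-normal
#' vector per sample with identity correlation except 2x2 blocks at the
#' planted pairs, pushed through the standard-normal CDF and then the
#' negative-binomial quantile with miRNA-specific mean times a per-sample
#' depth factor. Each miRNA's count is then split into isomiR counts by a
#' multinomial whose proportions are drawn once per miRNA from a Dirichlet.
#'
#' @param n_hf,n_lf Samples per fertility group (defaults 7 and 6).
#' @param n_mirna Number of miRNA annotations (default 250).
#' @param isomirs_per_mirna Integer range (length-2) of isomiRs per miRNA,
#'   default `c(1, 8)`.
#' @param depth Expected library size in reads (default 1e6).
#' @param dispersion Negative-binomial size parameter (default 10; larger is
#'   closer to Poisson).
#' @param abundance_logmean,abundance_logsd Log-normal parameters of the
#'   relative miRNA baseline abundances (defaults 5 and 1.5, spanning
#'   several orders of magnitude).
#' @param depth_logsd Log-normal sd of the per-sample depth factor
#'   (default 0.2).
#' @param dirichlet_alpha Concentration of the isomiR proportion Dirichlet
#'   (default 0.5: skewed profiles with a dominant isomiR).
#' @param mirna_fraction Expected fraction of library reads that are miRNA
#'   (default 0.18, the minority share miRNAs hold in sperm libraries); the
#'   rest is a background of other small-RNA biotypes (tRNA, piRNA, rRNA,
#'   other) which keeps the per-sample library total — the CPM divisor —
#'   stable, as in real data.
#' @param n_background Number of background (non-miRNA) sequences
#'   (default 1000); set to 0 to simulate a miRNA-only table.
#' @param background_logsd Log-normal sd of background abundances (default
#'   1: a milder spread than the miRNA layer, so the library total is an
#'   average over many loci and stays proportional to sequencing depth, as
#'   in real libraries).
#' @param planted_pairs Data frame with columns `index_a`, `index_b`,
#'   `rho_hf`, `rho_lf` (latent-scale correlations, `|rho| < 1`); indices
#'   must be disjoint across pairs. `NULL` for a null configuration.
#' @param seed Integer seed; the whole draw is reproducible from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_hf = 7, n_lf = 6, n_mirna = 250,
                       isomirs_per_mirna = c(1, 8),
                       depth = 1e6, dispersion = 10,
                       abundance_logmean = 5, abundance_logsd = 1.5,
                       depth_logsd = 0.2, dirichlet_alpha = 0.5,
                       mirna_fraction = 0.18, n_background = 1000,
                       background_logsd = 1, planted_pairs = NULL, seed = 1) {
  cfg <- list(n_hf = n_hf, n_lf = n_lf, n_mirna = n_mirna,
              isomirs_per_mirna = as.integer(isomirs_per_mirna),
              depth = depth, dispersion = dispersion,
              abundance_logmean = abundance_logmean,
              abundance_logsd = abundance_logsd,
              depth_logsd = depth_logsd,
              dirichlet_alpha = dirichlet_alpha,
              mirna_fraction = mirna_fraction,
              n_background = as.integer(n_background),
              background_logsd = background_logsd,
              planted_pairs = planted_pairs,
              seed = as.integer(seed))
  if (n_hf < 1 || n_lf < 1 || n_mirna < 1) abort("sizes must be positive")
  if (length(cfg$isomirs_per_mirna) != 2 ||
      any(cfg$isomirs_per_mirna < 1) ||
      cfg$isomirs_per_mirna[1] > cfg$isomirs_per_mirna[2]) {
    abort("isomirs_per_mirna must be an increasing positive range")
  }
  if (depth <= 0 || dispersion <= 0 || abundance_logsd <= 0 ||
      depth_logsd < 0 || dirichlet_alpha <= 0 || background_logsd <= 0) {
    abort("count parameters must be positive")
  }
  if (mirna_fraction <= 0 || mirna_fraction > 1 ||
      (mirna_fraction < 1 && n_background < 1)) {
    abort("mirna_fraction must be in (0, 1]; a fraction < 1 needs background rows")
  }
  if (!is.null(planted_pairs)) {
    pp <- as_tibble(planted_pairs)
    need <- c("index_a", "index_b", "rho_hf", "rho_lf")
    if (!all(need %in% names(pp))) {
      abort("planted_pairs needs columns index_a, index_b, rho_hf, rho_lf")
    }
    idx <- c(pp$index_a, pp$index_b)
    if (any(idx < 1 | idx > n_mirna)) abort("planted index out of range")
    if (anyDuplicated(idx)) {
      abort("planted pair blocks overlap: indices must be disjoint")
    }
    if (any(abs(c(pp$rho_hf, pp$rho_lf)) >= 1)) {
      abort("planted correlations must satisfy |rho| < 1")
    }
    cfg$planted_pairs <- pp
  }
  structure(cfg, class = "sim_config")
}

# Dirichlet draw via normalized gammas.
rdirichlet1 <- function(k, alpha) {
  g <- rgamma(k, shape = alpha)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

# Latent Gaussian matrix (n_mirna x n_samples) with planted 2x2 blocks.
latent_matrix <- function(n_mirna, n_samples, planted, rho_col) {
  Z <- matrix(rnorm(n_mirna * n_samples), n_mirna, n_samples)
  if (!is.null(planted)) {
    for (k in seq_len(nrow(planted))) {
      a <- planted$index_a[k]; b <- planted$index_b[k]
      rho <- planted[[rho_col]][k]
      Z[b, ] <- rho * Z[a, ] + sqrt(1 - rho^2) * Z[b, ]
    }
  }
  Z
}

random_sequences <- function(n, len_range = c(20, 24)) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    lens <- sample(seq(len_range[1], len_range[2]), need, replace = TRUE)
    fresh <- vapply(lens, function(l) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, fresh))
  }
  out[seq_len(n)]
}

#' Simulate a sequence-level count table with planted structure
#'
#' Draws a full synthetic dataset (see [sim_config()] for the model): a
#' sequence-level count table, the matching sample sheet, a consensus set
#' (the first generated isomiR of each miRNA), and the ground truth needed
#' to score recovery. The draw is byte-reproducible from `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_data` with elements `counts` (tibble:
#'   `sequence`, `annotation`, `biotype`, sample columns), `sheet`,
#'   `consensus` (tibble: `annotation`, `sequence`), and `truth` (class
#'   `sim_truth`: planted pairs with expected CH/CL class, per-miRNA mean
#'   abundances, per-isomiR true proportions, and the config).
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) abort("config must come from sim_config()")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(config$seed)

  M <- config$n_mirna
  ann <- sprintf("syn-miR-%04d", seq_len(M))
  rel <- rlnorm(M, config$abundance_logmean, config$abundance_logsd)
  mu <- rel / sum(rel) * config$depth * config$mirna_fraction

  n_all <- config$n_hf + config$n_lf
  sheet <- validate_sample_sheet(tibble(
    sample_id = c(sprintf("hf%02d", seq_len(config$n_hf)),
                  sprintf("lf%02d", seq_len(config$n_lf))),
    group = c(rep("HF", config$n_hf), rep("LF", config$n_lf)),
    scr = round(c(pmax(rnorm(config$n_hf, 2.0, 0.4), 1.0),
                  pmin(rnorm(config$n_lf, -2.7, 0.8), -1.0)), 2)
  ))
  sf <- rlnorm(n_all, 0, config$depth_logsd)

  Zh <- latent_matrix(M, config$n_hf, config$planted_pairs, "rho_hf")
  Zl <- latent_matrix(M, config$n_lf, config$planted_pairs, "rho_lf")
  Z <- cbind(Zh, Zl)
  mirna_counts <- matrix(0, M, n_all)
  for (s in seq_len(n_all)) {
    mirna_counts[, s] <- qnbinom(pnorm(Z[, s]), size = config$dispersion,
                                 mu = mu * sf[s])
  }

  k_iso <- sample(seq(config$isomirs_per_mirna[1],
                      config$isomirs_per_mirna[2]),
                  M, replace = TRUE)
  seqs <- random_sequences(sum(k_iso))
  seq_split <- split(seqs, rep(seq_len(M), k_iso))
  props <- lapply(k_iso, rdirichlet1, alpha = config$dirichlet_alpha)

  rows <- vector("list", M)
  for (i in seq_len(M)) {
    k <- k_iso[i]
    cnt <- matrix(0, k, n_all)
    for (s in seq_len(n_all)) {
      cnt[, s] <- rmultinom(1, size = mirna_counts[i, s], prob = props[[i]])
    }
    cnt <- as.data.frame(cnt)
    names(cnt) <- sheet$sample_id
    rows[[i]] <- bind_cols(
      tibble(sequence = seq_split[[i]], annotation = ann[i],
             biotype = "miRNA"),
      cnt)
  }
  counts <- bind_rows(rows)

  # Background small-RNA biotypes: the majority of a sperm library's reads.
  # They carry no planted structure; their role is compositional realism and
  # a stable per-sample total for CPM normalization.
  use_bg <- config$mirna_fraction < 1 && config$n_background > 0
  if (use_bg) {
    n_bg <- config$n_background
    bg_shares <- c(tRNA = 0.335, piRNA = 0.273, rRNA = 0.142, other = 0.068)
    bg_shares <- bg_shares / sum(bg_shares)
    bg_biotype <- sample(names(bg_shares), n_bg, replace = TRUE,
                         prob = bg_shares)
    bg_rel <- rlnorm(n_bg, config$abundance_logmean, config$background_logsd)
    bg_mu <- bg_rel / sum(bg_rel) * config$depth * (1 - config$mirna_fraction)
    bg_seqs <- random_sequences(n_bg, len_range = c(18, 35))
    bg_cnt <- matrix(0, n_bg, n_all)
    for (s in seq_len(n_all)) {
      bg_cnt[, s] <- qnbinom(pnorm(rnorm(n_bg)), size = config$dispersion,
                             mu = bg_mu * sf[s])
    }
    bg_cnt <- as.data.frame(bg_cnt)
    names(bg_cnt) <- sheet$sample_id
    bg_rows <- bind_cols(
      tibble(sequence = bg_seqs,
             annotation = sprintf("syn-%s-%04d", bg_biotype, seq_len(n_bg)),
             biotype = bg_biotype),
      bg_cnt)
    counts <- bind_rows(counts, bg_rows)
  }

  consensus <- tibble(annotation = ann,
                      sequence = vapply(seq_split, `[[`, character(1), 1L))
  planted <- config$planted_pairs
  planted_truth <- if (is.null(planted)) {
    tibble(mirna_a = character(), mirna_b = character(),
           rho_hf = numeric(), rho_lf = numeric(),
           expected_class = factor(character(),
                                   levels = c("CH", "CL", "DISCORDANT")))
  } else {
    a <- ann[planted$index_a]; b <- ann[planted$index_b]
    swap <- a > b
    tibble(mirna_a = ifelse(swap, b, a), mirna_b = ifelse(swap, a, b),
           rho_hf = planted$rho_hf, rho_lf = planted$rho_lf,
           expected_class = classify_pair(planted$rho_hf, planted$rho_lf))
  }
  truth <- structure(list(
    planted = planted_truth,
    mirna = tibble(annotation = ann, mu = mu, n_isomir = k_iso),
    isomirs = tibble(annotation = rep(ann, k_iso),
                     sequence = unlist(seq_split),
                     proportion = unlist(props),
                     is_consensus = unlist(lapply(k_iso, function(k)
                       seq_len(k) == 1))),
    config = config
  ), class = "sim_truth")

  structure(list(counts = counts, sheet = sheet, consensus = consensus,
                 truth = truth),
            class = "sim_data")
}

#' Score recovery of planted differential correlations
#'
#' A planted pair counts as a true positive when it appears in the final
#' BH-significant set with its expected CH/CL class; a planted pair detected
#' with the wrong class counts as both a false positive and a false
#' negative. Also reports dual-gate and final pass rates separately for
#' planted and unplanted pairs, the per-stage null leakage of the funnel.
#'
#' @param truth A `sim_truth` object.
#' @param result A `diffcorr` object from [run_diffcorr()] on the simulated
#'   data.
#' @return A one-row tibble: `n_planted`, `tp`, `fp`, `fn`, `sensitivity`,
#'   `planted_dual_rate`, `unplanted_dual_rate`, `planted_final_rate`,
#'   `unplanted_final_rate`.
#' @export
evaluate_recovery <- function(truth, result) {
  if (!inherits(truth, "sim_truth")) abort("truth must be a sim_truth object")
  rec <- as_tibble(result)
  res_ann <- unique(c(rec$mirna_a, rec$mirna_b))
  truth_ann <- truth$mirna$annotation
  if (nrow(rec) > 0 && length(intersect(res_ann, truth_ann)) == 0) {
    abort("annotation namespaces of truth and results do not match")
  }
  key <- function(a, b) paste(a, b, sep = "\r")
  planted_key <- key(truth$planted$mirna_a, truth$planted$mirna_b)
  expected <- setNames(as.character(truth$planted$expected_class), planted_key)
  rec_key <- key(rec$mirna_a, rec$mirna_b)
  is_planted <- rec_key %in% planted_key

  sig <- rec$significant
  correct_class <- sig & is_planted &
    as.character(rec$class) == expected[rec_key]
  tp <- sum(correct_class)
  fp <- sum(sig & !correct_class)
  n_planted <- nrow(truth$planted)
  fn <- n_planted - tp
  rate <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  tibble(
    n_planted = n_planted,
    tp = tp, fp = fp, fn = fn,
    sensitivity = if (n_planted > 0) tp / n_planted else NA_real_,
    planted_dual_rate = rate(rec$passed_dual_gate[is_planted]),
    unplanted_dual_rate = rate(rec$passed_dual_gate[!is_planted]),
    planted_final_rate = rate(sig[is_planted]),
    unplanted_final_rate = rate(sig[!is_planted])
  )
}

#' Write a simulated dataset to disk
#'
#' Emits `counts.tsv`, `samples.tsv`, `consensus.fasta` and a flat
#' `truth.json` sidecar into a directory.
#'
#' @param sim A `sim_data` object from [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_data <- function(sim, dir) {
  if (!inherits(sim, "sim_data")) abort("sim must come from simulate_counts()")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mirdcor_tsv(sim$counts, file.path(dir, "counts.tsv"))
  write_mirdcor_tsv(sim$sheet, file.path(dir, "samples.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(sim$consensus$sequence,
                                      sim$consensus$annotation)),
    file.path(dir, "consensus.fasta"))
  truth <- sim$truth
  jsonlite::write_json(
    list(planted = truth$planted, mirna = truth$mirna,
         isomirs = truth$isomirs,
         config = unclass(truth$config)[setdiff(names(truth$config),
                                                "planted_pairs")]),
    file.path(dir, "truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
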