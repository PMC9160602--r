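test_that("configuration validation rejects infeasible setups", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(planted_pairs = data.frame(
    index_a = c(1, 2), index_b = c(2, 3), rho_hf = 0.5, rho_lf = -0.5)),
    "overlap")
  expect_error(sim_config(planted_pairs = data.frame(
    index_a = 1, index_b = 2, rho_hf = 1, rho_lf = -0.5)), "rho")
  expect_error(sim_config(n_mirna = 5, planted_pairs = data.frame(
    index_a = 1, index_b = 9, rho_hf = 0.5, rho_lf = 0.5)), "range")
  expect_error(sim_config(dispersion = -1), "positive")
})

test_that("the same seed reproduces the dataset byte for byte", {
  cfg <- sim_config(n_mirna = 20, seed = 5,
                    planted_pairs = planted_grid(2, 0.9, -0.9))
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$sheet, s2$sheet)
  expect_identical(s1$truth$isomirs, s2$truth$isomirs)
  s3 <- simulate_counts(sim_config(n_mirna = 20, seed = 6,
                                   planted_pairs = planted_grid(2, 0.9, -0.9)))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("structure of the simulated table matches its truth", {
  sim <- simulate_counts(sim_config(n_mirna = 15, seed = 8))
  sheet <- sim$sheet
  expect_equal(sum(sheet$group == "HF"), 7)
  expect_equal(sum(sheet$group == "LF"), 6)
  expect_true(all(sheet$scr[sheet$group == "HF"] >= 1))
  expect_true(all(sheet$scr[sheet$group == "LF"] <= -1))

  mir <- sim$counts[sim$counts$biotype == "miRNA", ]
  expect_equal(sort(unique(mir$annotation)), sort(sim$truth$mirna$annotation))
  expect_equal(nrow(mir), sum(sim$truth$mirna$n_isomir))
  # consensus is a member sequence of its annotation
  joined <- merge(sim$consensus, mir, by = c("annotation", "sequence"))
  expect_equal(nrow(joined), 15)
  # isomiR truth proportions sum to 1 per annotation
  sums <- tapply(sim$truth$isomirs$proportion,
                 sim$truth$isomirs$annotation, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("marginal means and biotype composition track the configuration", {
  cfg <- sim_config(n_mirna = 40, seed = 13, depth_logsd = 0,
                    isomirs_per_mirna = c(1, 3))
  sim <- simulate_counts(cfg)
  mir_counts <- collapse_by_annotation(
    sim$counts[sim$counts$biotype == "miRNA", ], sim$sheet)
  X <- as.matrix(mir_counts[, sim$sheet$sample_id])
  mu <- sim$truth$mirna$mu[match(mir_counts$annotation,
                                 sim$truth$mirna$annotation)]
  # pooled relative error of realized means vs configured means
  rel_err <- abs(rowMeans(X) - mu) / mu
  expect_lt(stats::median(rel_err[mu > 100]), 0.25)
  # miRNA share of the library near the configured fraction
  share <- sum(X) / sum(sim$counts[, sim$sheet$sample_id])
  expect_equal(share, 0.18, tolerance = 0.35)
})

test_that("planted copula correlation transfers its sign to the counts", {
  hits <- 0; trials <- 0
  for (seed in 1:30) {
    sim <- simulate_counts(sim_config(
      n_mirna = 12, seed = seed, isomirs_per_mirna = c(1, 2),
      planted_pairs = planted_grid(3, 0.95, -0.95)))
    mat <- mirna_matrix(sim$counts, sim$sheet)
    rec <- pair_correlations(mat, sim$sheet)
    key <- paste(sim$truth$planted$mirna_a, sim$truth$planted$mirna_b)
    pl <- rec[paste(rec$mirna_a, rec$mirna_b) %in% key, ]
    hits <- hits + sum(pl$rho_hf > 0) + sum(pl$rho_lf < 0)
    trials <- trials + 2 * nrow(pl)
  }
  expect_gte(hits / trials, 0.97)
})

test_that("without planted pairs the correlations center at zero", {
  sim <- simulate_counts(sim_config(n_mirna = 40, seed = 17))
  mat <- mirna_matrix(sim$counts, sim$sheet)
  rec <- pair_correlations(mat, sim$sheet)
  ok <- !rec$undefined
  expect_lt(abs(mean(rec$rho_hf[ok])), 0.08)
  expect_lt(abs(mean(rec$rho_lf[ok])), 0.08)
})

test_that("isomiR proportions are recovered from the counts", {
  sim <- simulate_counts(sim_config(n_mirna = 25, seed = 19,
                                    isomirs_per_mirna = c(2, 6)))
  norm <- normalize_cpm(sim$counts, sim$sheet)
  prof <- isomir_proportions(norm[norm$biotype == "miRNA", ], sim$sheet)
  truth <- sim$truth$isomirs
  m <- merge(prof, truth, by = c("annotation", "sequence"),
             suffixes = c("", "_true"))
  keep <- m$annotation %in%
    sim$truth$mirna$annotation[sim$truth$mirna$mu > 200]
  expect_equal(nrow(m), nrow(truth))
  expect_lt(max(abs(m$proportion - m$proportion_true)[keep]), 0.15)
  expect_lt(mean(abs(m$proportion - m$proportion_true)[keep]), 0.02)
})

test_that("recovery scoring counts TP, FP, FN and class flips correctly", {
  sim <- simulate_counts(sim_config(n_mirna = 10, seed = 23,
                                    planted_pairs = planted_grid(2, 0.9, -0.9)))
  dc <- run_sim_pipeline(sim)
  rec <- tibble::as_tibble(dc)

  # fabricate result states around the real record scaffold
  key <- paste(rec$mirna_a, rec$mirna_b)
  pkey <- paste(sim$truth$planted$mirna_a, sim$truth$planted$mirna_b)

  # all planted detected with correct class, nothing else
  rec2 <- rec
  rec2$significant <- key %in% pkey
  rec2$class <- factor(ifelse(key %in% pkey, "CH", "DISCORDANT"),
                       levels = levels(rec$class))
  out <- evaluate_recovery(sim$truth, rec2)
  expect_equal(out$tp, 2); expect_equal(out$fp, 0)
  expect_equal(out$sensitivity, 1)

  # empty result: sensitivity 0
  rec3 <- rec; rec3$significant <- FALSE
  out3 <- evaluate_recovery(sim$truth, rec3)
  expect_equal(out3$tp, 0); expect_equal(out3$fn, 2)

  # planted pair detected with flipped class: FP and FN, never TP
  rec4 <- rec2
  rec4$class[key %in% pkey] <- "CL"
  out4 <- evaluate_recovery(sim$truth, rec4)
  expect_equal(out4$tp, 0); expect_equal(out4$fp, 2); expect_equal(out4$fn, 2)

  # namespace mismatch errors
  bad <- rec; bad$mirna_a <- sub("syn-miR", "other", bad$mirna_a)
  bad$mirna_b <- sub("syn-miR", "other", bad$mirna_b)
  expect_error(evaluate_recovery(sim$truth, bad), "namespace")
})

test_that("simulated data round-trips through the on-disk form", {
  dir <- withr::local_tempdir()
  sim <- simulate_counts(sim_config(n_mirna = 8, seed = 29))
  write_sim_data(sim, dir)
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  counts <- read_sequence_counts(file.path(dir, "counts.tsv"), sheet)
  cons <- read_consensus_fasta(file.path(dir, "consensus.fasta"))
  expect_equal(as.data.frame(sheet), as.data.frame(sim$sheet))
  expect_equal(as.data.frame(counts)[, names(sim$counts)],
               as.data.frame(sim$counts))
  expect_equal(nrow(cons), 8)
  expect_true(file.exists(file.path(dir, "truth.json")))
})
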