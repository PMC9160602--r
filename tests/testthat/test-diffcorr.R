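test_that("pair enumeration is complete, ordered and self-pair free", {
  expect_equal(nrow(enumerate_pairs(c("a", "b"))), 1)

  ann <- paste0("m", 1:5)
  pairs <- enumerate_pairs(ann)
  # brute-force double loop oracle
  oracle <- list()
  for (i in seq_along(ann)) for (j in seq_along(ann)) {
    if (ann[i] < ann[j]) oracle[[length(oracle) + 1]] <- c(ann[i], ann[j])
  }
  expect_equal(nrow(pairs), length(oracle))
  expect_equal(nrow(pairs), 10)
  expect_true(all(pairs$mirna_a < pairs$mirna_b))

  for (M in c(2, 10, 50)) {
    expect_equal(nrow(enumerate_pairs(paste0("x", seq_len(M)))),
                 M * (M - 1) / 2)
  }
  expect_error(enumerate_pairs(c("a", "a")), "unique")
})

test_that("dual gate requires strict per-group significance", {
  rec <- tibble::tibble(
    mirna_a = c("a", "a", "a"), mirna_b = c("b", "c", "d"),
    rho_hf = 0.9, p_hf = c(0.04, 0.04, 0.051),
    rho_lf = -0.9, p_lf = c(0.04, 0.05, 0.01))
  kept <- dual_gate(rec)
  expect_equal(kept$mirna_b, "b")  # p = 0.05 exactly is dropped
  expect_equal(nrow(dual_gate(rec[0, ])), 0)
})

test_that("interaction model equals independent per-group fits", {
  set.seed(31)
  low <- c(rep(0, 7), rep(1, 6))
  for (rep in 1:25) {
    x <- rnorm(13, sd = 2)
    y <- 1 + 0.5 * x + low * (2 - 1.5 * x) + rnorm(13)
    fit <- fit_interaction(y, x, low)
    est <- tidy(fit)$estimate

    hf <- ols_oracle(y[low == 0], cbind(1, x[low == 0]))
    lf <- ols_oracle(y[low == 1], cbind(1, x[low == 1]))
    expect_equal(est[1:2], hf$beta, tolerance = 1e-8)
    expect_equal(est[1:2] + est[3:4], lf$beta, tolerance = 1e-8)

    # full-design normal equations oracle with pooled residual variance
    X <- cbind(1, x, low, low * x)
    full <- ols_oracle(y, X)
    expect_equal(est, full$beta, tolerance = 1e-10)
    expect_equal(tidy(fit)$std.error, full$se, tolerance = 1e-10)
    expect_equal(glance(fit)$df.residual, 13 - 4)
    # t * se = beta exactly
    expect_equal(tidy(fit)$statistic * tidy(fit)$std.error, est)
  }
})

test_that("noiseless slope reversal is recovered exactly", {
  low <- c(rep(0, 7), rep(1, 6))
  x <- c(1:7, 1:6)
  y <- ifelse(low == 0, 1 + 2 * x, 1 - 2 * x)
  # a zero-residual fit makes summary() warn; the estimates stay exact
  fit <- suppressWarnings(fit_interaction(y, x, low))
  est <- tidy(fit)$estimate
  expect_equal(est, c(1, 2, 0, -4), tolerance = 1e-10)
  expect_equal(glance(fit)$sigma, 0, tolerance = 1e-8)

  # LF data an exact duplicate of the HF data: group terms vanish and the
  # shared coefficients equal the single-group fit
  set.seed(61)
  xh <- rnorm(6); yh <- 1 + 2 * xh + rnorm(6, sd = 0.3)
  fit2 <- fit_interaction(c(yh, yh), c(xh, xh), rep(c(0, 1), each = 6))
  expect_equal(tidy(fit2)$estimate[3:4], c(0, 0), tolerance = 1e-8)
  solo <- ols_oracle(yh, cbind(1, xh))
  expect_equal(tidy(fit2)$estimate[1:2], solo$beta, tolerance = 1e-8)

  # constant x within a group makes the design rank-deficient
  x3 <- c(1:7, rep(2, 6))
  expect_error(fit_interaction(rnorm(13), x3, low), "rank-deficient")
  expect_error(fit_interaction(rnorm(6), rnorm(6), c(0, 0, 0, 0, 1, 1)),
               ">= 3 per group")
})

test_that("candidate selection demands both slope terms significant", {
  fits <- tibble::tibble(p1 = c(0.01, 0.01, 0.2, 0.04),
                         p3 = c(0.2, 0.01, 0.01, 0.05))
  expect_equal(nrow(select_candidates(fits)), 1)
  expect_equal(which(fits$p1 < 0.05 & fits$p3 < 0.05), 2)
})

test_that("BH adjustment matches the step-up definition", {
  got <- bh_adjust(c(0.01, 0.02, 0.03))
  expect_equal(got$q_value, c(0.03, 0.03, 0.03))
  expect_true(all(got$reject))

  expect_equal(bh_adjust(0.04)$q_value, 0.04)  # m = 1 identity
  expect_equal(sum(bh_adjust(c(0.5, 0.9))$reject), 0)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(41)
  for (rep in 1:200) {
    m <- sample(1:200, 1)
    p <- runif(m)^sample(1:3, 1)
    got <- bh_adjust(p)
    expect_equal(got$q_value, bh_oracle(p))
    expect_equal(got$reject, bh_oracle(p) <= 0.05)
  }
  # adjusted values are monotone along the sorted p-values
  p <- runif(50)
  q <- bh_adjust(p)$q_value
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("sign-pattern classification is exhaustive and exclusive", {
  expect_equal(as.character(classify_pair(0.8, -0.7)), "CH")
  expect_equal(as.character(classify_pair(-0.8, 0.7)), "CL")
  expect_equal(as.character(classify_pair(0.8, 0.7)), "DISCORDANT")
  expect_equal(as.character(classify_pair(-0.8, -0.7)), "DISCORDANT")
  expect_warning(cls <- classify_pair(0, 0.5), "exactly 0")
  expect_equal(as.character(cls), "DISCORDANT")

  set.seed(51)
  r1 <- runif(500, -1, 1); r2 <- runif(500, -1, 1)
  cls <- classify_pair(r1, r2)
  expect_true(all(!is.na(cls)))
  expect_equal(sum(cls == "CH") + sum(cls == "CL") +
                 sum(cls == "DISCORDANT"), 500)
  expect_true(all((cls == "CH") == (r1 > 0 & r2 < 0)))
  expect_true(all((cls == "CL") == (r1 < 0 & r2 > 0)))
})

test_that("a planted perfect reversal survives every funnel stage", {
  sheet <- make_sheet(7, 6)
  hf <- sheet$group == "HF"
  # two miRNAs in perfect positive rank agreement in HF and perfect rank
  # reversal in LF; monotone but not exactly linear, so the OLS fit keeps a
  # nonzero residual and finite t statistics
  a <- c(1:7 * 10, 1:6 * 10)
  b <- c(3.1, 6.5, 9.2, 12.9, 15.1, 18.4, 21.0,
         12.2, 10.1, 8.4, 6.0, 3.9, 1.7)
  mat <- tibble::tibble(annotation = c("miR-a", "miR-b"))
  for (k in seq_along(sheet$sample_id)) {
    mat[[sheet$sample_id[k]]] <- c(a[k], b[k])
  }
  dc <- run_diffcorr(mat, sheet)
  f <- glance(dc)
  expect_equal(f$n_pairs, 1)
  expect_equal(f$n_dual_gate, 1)
  expect_equal(f$n_candidates, 1)
  expect_equal(f$n_significant, 1)
  expect_equal(f$n_ch, 1)
  out <- tidy(dc)
  expect_equal(out$rho_hf, 1)
  expect_equal(out$rho_lf, -1)
  expect_equal(as.character(out$class), "CH")
  # exact two-sided p for a perfect ranking
  expect_equal(out$p_hf, 2 / factorial(7))
  expect_equal(out$p_lf, 2 / factorial(6))
})

test_that("funnel counts are internally consistent on simulated data", {
  sim <- simulate_counts(sim_config(
    n_mirna = 40, seed = 99,
    planted_pairs = planted_grid(5, 0.95, -0.95)))
  dc <- run_sim_pipeline(sim)
  f <- glance(dc)
  expect_true(f$n_dual_gate <= f$n_pairs)
  expect_true(f$n_candidates <= f$n_dual_gate)
  expect_true(f$n_significant <= f$n_candidates)
  expect_equal(f$n_ch + f$n_cl, f$n_significant)
  rec <- tibble::as_tibble(dc)
  expect_equal(sum(rec$passed_dual_gate), f$n_dual_gate)
  expect_equal(sum(rec$is_candidate), f$n_candidates)
  # q-values only inside the BH family
  expect_true(all(is.na(rec$q_value[!rec$is_candidate])))
})

test_that("orientation and BH-family options behave as documented", {
  sim <- simulate_counts(sim_config(
    n_mirna = 30, seed = 123,
    planted_pairs = planted_grid(4, 0.95, -0.95)))
  lex <- run_sim_pipeline(sim)
  both <- run_sim_pipeline(sim, orientation = "both")
  surv <- run_sim_pipeline(sim, bh_family = "survivors")
  # requiring both orientations can only shrink the candidate set
  expect_true(glance(both)$n_candidates <= glance(lex)$n_candidates)
  # whichever family is adjusted, rejections stay within the candidate set
  expect_true(glance(surv)$n_significant <= glance(surv)$n_candidates)
  srec <- tibble::as_tibble(surv)
  expect_true(all(!is.na(srec$q_value[srec$passed_dual_gate])))
})
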