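# Shared fixtures and independent oracles for the test suite.
# Oracles here are deliberately written from first principles, on different
# code paths than the package internals they check.

make_sheet <- function(n_hf = 7, n_lf = 6) {
  validate_sample_sheet(data.frame(
    sample_id = c(sprintf("h%d", seq_len(n_hf)), sprintf("l%d", seq_len(n_lf))),
    group = c(rep("HF", n_hf), rep("LF", n_lf))
  ))
}

# Tiny sequence-level table: k sequences per annotation, fixed counts.
make_counts <- function(sheet, annotations = c("miR-a", "miR-b"),
                        k = 2, base = 100) {
  rows <- list()
  seq_pool <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 8)), 1,
                    paste, collapse = "")
  i <- 0
  for (ann in annotations) {
    for (j in seq_len(k)) {
      i <- i + 1
      rows[[i]] <- data.frame(sequence = paste0("ACGTACGTACGT", seq_pool[i]),
                              annotation = ann)
      for (s in sheet$sample_id) rows[[i]][[s]] <- base * i
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

# Permutation enumeration by iterative insertion (independent of the
# package's recursive generator).
perms_oracle <- function(n) {
  out <- matrix(1L, 1, 1)
  for (k in 2:n) {
    grown <- matrix(0L, nrow(out) * k, k)
    r <- 0
    for (i in seq_len(nrow(out))) {
      for (pos in seq_len(k)) {
        r <- r + 1
        grown[r, ] <- append(out[i, ], k, after = pos - 1)
      }
    }
    out <- grown
  }
  out
}

# Brute-force two-sided exact Spearman p: proportion of all n! pairings with
# |rho| at least the observed (up to numeric tolerance).
spearman_p_oracle <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  P <- perms_oracle(n)
  rhos <- apply(P, 1, function(p) stats::cor(rx, ry[p]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# Step-up BH definition applied literally: p~(i) = min_{j>=i} m p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# OLS by explicit normal equations, with classical standard errors.
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  list(beta = as.numeric(beta), se = as.numeric(se), df = df,
       sigma = sqrt(s2))
}

# Welch t from the textbook formula.
welch_oracle <- function(a, b) {
  v1 <- stats::var(a) / length(a)
  v2 <- stats::var(b) / length(b)
  tt <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  list(t = tt, p = p)
}

# Planted-pair configuration used across simulation tests.
planted_grid <- function(n_pairs, rho_hf, rho_lf) {
  data.frame(index_a = seq(1, 2 * n_pairs - 1, 2),
             index_b = seq(2, 2 * n_pairs, 2),
             rho_hf = rho_hf, rho_lf = rho_lf)
}

run_sim_pipeline <- function(sim, ...) {
  mat <- mirna_matrix(sim$counts, sim$sheet)
  filt <- filter_expression(mat, sim$sheet)
  run_diffcorr(filt, sim$sheet, ...)
}
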