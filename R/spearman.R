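# Exact small-sample Spearman correlation test.
#
# With group sizes of 6 and 7 animals the large-sample approximations to the
# Spearman null are unreliable, so for tie-free vectors of length n <= 9 the
# two-sided p-value is computed from the exact permutation null distribution
# of S = sum of squared rank differences, enumerated once per n and cached.
# S is integer-valued for tie-free data, so all comparisons are exact integer
# arithmetic. With ties (average ranks) the classical t approximation with
# n - 2 degrees of freedom is used instead.

.spearman_cache <- new.env(parent = emptyenv())

# All permutations of 1..n as an n!-row matrix (n <= 9).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (i in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, i] <- n
    block[, -i] <- sub
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# Counts of each value of S = sum (rank_x - rank_y)^2 over the n! equally
# likely rank pairings; index k holds the count for S = k - 1.
spearman_S_counts <- function(n) {
  key <- paste0("n", n)
  if (!is.null(.spearman_cache[[key]])) return(.spearman_cache[[key]])
  perms <- all_permutations(n)
  S <- rowSums((perms - rep(seq_len(n), each = nrow(perms)))^2)
  max_S <- n * (n^2 - 1) / 3
  counts <- tabulate(S + 1L, nbins = max_S + 1L)
  .spearman_cache[[key]] <- counts
  counts
}

# Exact two-sided p for observed S at sample size n (tie-free ranks).
# |rho| >= |rho_obs| is equivalent to S <= s* or S >= 2D - s* where
# D = (n^3 - n)/6 and s* = min(S_obs, 2D - S_obs).
spearman_p_from_S <- function(S_obs, n) {
  counts <- spearman_S_counts(n)
  D <- (n^3 - n) / 6
  s_star <- min(S_obs, 2 * D - S_obs)
  total <- sum(counts)
  lower <- sum(counts[seq_len(s_star + 1L)])
  upper <- sum(counts[(2 * D - s_star + 1L):length(counts)])
  # the two tails meet at S = D when rho_obs = 0; count that point once
  overlap <- if (s_star == D) counts[D + 1L] else 0L
  (lower + upper - overlap) / total
}

#' Spearman correlation with exact permutation p-value
#'
#' Computes the Spearman rank correlation between two vectors and a two-sided
#' p-value. For tie-free data with `n <= max_exact` observations the p-value
#' is exact, computed by full enumeration of the permutation null
#' distribution; otherwise the t approximation with `n - 2` degrees of
#' freedom is used.
#'
#' @param x,y Numeric vectors of equal length `n >= 4`, each with at least
#'   two distinct values.
#' @param max_exact Largest `n` for which the exact null is enumerated
#'   (default 9; `9! = 362880` pairings).
#' @return A list with elements `rho`, `p`, `n`, and `exact` (logical: was
#'   the permutation null used).
#' @examples
#' spearman_exact(1:6, c(2, 1, 3, 4, 5, 6))
#' @export
spearman_exact <- function(x, y, max_exact = 9) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 4) abort("need at least 4 observations")
  if (anyNA(x) || anyNA(y)) abort("missing values not allowed")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("constant vector: Spearman correlation undefined")
  }
  rx <- rank(x)
  ry <- rank(y)
  tie_free <- !anyDuplicated(rx) && !anyDuplicated(ry)
  rho <- cor(rx, ry)
  if (tie_free && n <= max_exact) {
    S <- sum((rx - ry)^2)
    list(rho = rho, p = spearman_p_from_S(as.integer(round(S)), n),
         n = n, exact = TRUE)
  } else {
    list(rho = rho, p = spearman_p_approx(rho, n), n = n, exact = FALSE)
  }
}

# Two-sided t approximation, df = n - 2; |rho| = 1 gives p = 0.
spearman_p_approx <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tstat), df = n - 2)
}

# Spearman rho and p for every row pair of a values matrix (rows = miRNAs,
# columns = samples of one group). Exact p where both rows are tie-free and
# n <= max_exact; t approximation otherwise. Rows flagged in `undefined`
# (constant within the group) yield NA.
spearman_all_pairs <- function(X, max_exact = 9) {
  n <- ncol(X)
  M <- nrow(X)
  ranks <- t(apply(X, 1, rank))
  if (M == 0 || n < 4) abort("need >= 4 samples and >= 1 row")
  constant <- apply(X, 1, function(v) length(unique(v)) < 2)
  tie_free <- !constant & apply(ranks, 1, function(r) !anyDuplicated(r))
  rho_mat <- suppressWarnings(cor(t(ranks)))
  idx <- which(upper.tri(rho_mat), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  rho <- rho_mat[idx]
  p <- rep(NA_real_, length(rho))
  undef <- constant[i] | constant[j]
  exact_ok <- !undef & tie_free[i] & tie_free[j] & n <= max_exact
  if (any(exact_ok)) {
    D <- (n^3 - n) / 6
    S_obs <- as.integer(round((1 - rho[exact_ok]) * D))
    counts <- spearman_S_counts(n)
    total <- sum(counts)
    cum <- cumsum(counts)
    s_star <- pmin(S_obs, 2L * D - S_obs)
    overlap <- ifelse(s_star == D, counts[D + 1L], 0L)
    p[exact_ok] <-
      (cum[s_star + 1L] + (total - cum[2L * D - s_star]) - overlap) / total
  }
  approx_ok <- !undef & !exact_ok
  if (any(approx_ok)) {
    p[approx_ok] <- vapply(rho[approx_ok], spearman_p_approx, numeric(1), n = n)
  }
  rho[undef] <- NA_real_
  tibble(i = i, j = j, rho = rho, p = p, undefined = undef,
         exact = exact_ok)
}
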