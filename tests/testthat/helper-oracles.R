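# Independent oracles used across tests. These stay deliberately naive
# (explicit loops, normal equations) so they cannot share code paths with
# the implementation they check.

# AUC by exhaustive positive-negative pair counting, ties credited 0.5.
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cnt <- 0
  for (p in pos) for (q in neg) cnt <- cnt + (p > q) + 0.5 * (p == q)
  cnt / (length(pos) * length(neg))
}

# Ordinary least squares via the explicit normal equations.
normal_equation_fit <- function(X, y) {
  as.vector(solve(t(X) %*% X, t(X) %*% y))
}

# Plain two-sample t-test on log2 values, computed longhand.
longhand_t_p <- function(x, y, welch = FALSE) {
  lx <- log2(x); ly <- log2(y)
  n1 <- length(lx); n2 <- length(ly)
  v1 <- var(lx); v2 <- var(ly)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  tt <- (mean(lx) - mean(ly)) / sqrt(se2)
  2 * pt(-abs(tt), df)
}

# Adjusted Rand index between two hard partitions.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Small two-arm screening study used by several epiarray/screening tests.
make_screen_sim <- function(n_genes = 400, planted = planted_signals(30, 15, 10),
                            noise = 0.1, seed = 101) {
  simulate_epiarray(study_design(doses = 6.5), n_genes = n_genes,
                    planted = planted, noise_sd_log2 = noise, seed = seed)
}
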