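# qPCR arithmetic: amounts, MeRIP enrichment, ddCt, SELECT curves, Dunnett.

test_that("relative amount and MeRIP enrichment follow the stated formulas", {
  expect_equal(relative_amount(0), 1)
  expect_equal(relative_amount(24) * 2, relative_amount(23))
  expect_equal(relative_amount(-3, 1.9) / relative_amount(0, 1.9), 1.9^3)
  expect_error(relative_amount(20, efficiency = 2.5), "efficiency")
  # worked example: 2 ug IP vs 500 ng input, 3 cycles earlier in input
  expect_equal(merip_enrichment(24, 27, 2000, 500), 2)
  expect_equal(merip_enrichment(25, 25, 500, 500), 1)
  # two-step independent recomputation on a random table
  set.seed(12)
  ct_ip <- runif(20, 18, 30); ct_in <- runif(20, 18, 30)
  mi <- runif(20, 500, 4000); mn <- runif(20, 100, 1000)
  direct <- merip_enrichment(ct_ip, ct_in, mi, mn)
  two_step <- (relative_amount(ct_ip) / mi) / (relative_amount(ct_in) / mn)
  expect_equal(direct, two_step, tolerance = 1e-12)
  # monotone in ct_ip; mass-scale invariant
  expect_true(all(diff(merip_enrichment(seq(30, 20), 25, 2000, 500)) > 0))
  expect_equal(merip_enrichment(24, 27, 2000, 500),
               merip_enrichment(24, 27, 2000 * 3.7, 500 * 3.7))
})

test_that("relative m6A level self-normalizes and propagates error", {
  expect_equal(relative_m6a_level(c(1, 1, 1), c(1, 1, 1))$fold, 1)
  expect_equal(relative_m6a_level(c(2, 2, 2), c(1, 1, 1))$fold, 2)
  r <- relative_m6a_level(c(2, 3, 4), c(1, 1.5, 0.5))
  m_g <- mean(c(2, 3, 4)); m_c <- mean(c(1, 1.5, 0.5))
  se_g <- sd(c(2, 3, 4)) / sqrt(3); se_c <- sd(c(1, 1.5, 0.5)) / sqrt(3)
  expect_equal(r$se, (m_g / m_c) * sqrt((se_g / m_g)^2 + (se_c / m_c)^2))
  expect_error(relative_m6a_level(1, 0), "control mean")
})

test_that("simulated MeRIP fold changes are recovered on average", {
  set.seed(41)
  folds <- replicate(200, {
    ct <- simulate_ct_data(c(control = 1, hot = 3), type = "merip", n_rep = 5,
                           ct_sd = 0.1, seed = sample.int(1e6, 1))
    enr <- merip_workflow(ct)
    relative_m6a_level(enr$enrichment[enr$group_id == "hot"],
                       enr$enrichment[enr$group_id == "control"])$fold
  })
  expect_gt(mean(folds), 2.8)
  expect_lt(mean(folds), 3.2)
})

test_that("primer feasibility gates on the signal-to-background ratio", {
  expect_true(primer_feasibility(4, 1)$pass)      # boundary inclusive
  expect_false(primer_feasibility(1, 1)$pass)
  expect_error(primer_feasibility(-1, 1), "positive")
  set.seed(4)
  ip <- runif(30, 0.5, 20); igg <- runif(30, 0.5, 5)
  expect_identical(primer_feasibility(ip, igg)$pass, ip / igg >= 4)
})

test_that("ddCt equals the amount-ratio formulation", {
  expect_equal(relative_expression_ddct(20, 18, 20, 18), 1)
  expect_equal(relative_expression_ddct(19, 18, 20, 18), 2)
  set.seed(9)
  for (i in 1:20) {
    cts <- runif(4, 15, 30)
    ratio <- (relative_amount(cts[1]) / relative_amount(cts[2])) /
      (relative_amount(cts[3]) / relative_amount(cts[4]))
    expect_equal(relative_expression_ddct(cts[1], cts[2], cts[3], cts[4]),
                 ratio, tolerance = 1e-12)
  }
  expect_error(relative_expression_ddct(Inf, 1, 1, 1), "finite")
})

test_that("SELECT curve fitting matches least squares and inverts exactly", {
  # noiseless line r = 0.1 + 0.9 f encoded as Ct shifts
  fr <- c(0, 0.25, 0.5, 0.75, 1)
  ct100 <- 24
  cts <- ct100 + log2(0.1 + 0.9 * fr)
  curve <- fit_select_curve(fr, cts)
  expect_equal(curve$slope, 0.9, tolerance = 1e-9)
  expect_equal(curve$intercept, 0.1, tolerance = 1e-9)
  expect_equal(curve$r2, 1, tolerance = 1e-9)
  # the 100% standard's own relative product is 1
  expect_equal(2^(cts[fr == 1] - curve$ct_ref_100), 1)
  expect_equal(estimate_select_fraction(ct100, curve)$fraction, 1)
  # r = intercept -> fraction 0
  ct0 <- ct100 + log2(curve$intercept)
  expect_equal(estimate_select_fraction(ct0, curve)$fraction, 0,
               tolerance = 1e-9)
  # noisy coefficients equal the closed-form covariance/variance solution
  set.seed(5)
  ctsn <- cts + rnorm(5, 0, 0.2)
  cn <- fit_select_curve(fr, ctsn)
  r <- 2^(ctsn - mean(ctsn[fr == 1]))
  slope_hat <- cov(fr, r) / var(fr)
  expect_equal(cn$slope, slope_hat, tolerance = 1e-10)
  expect_equal(cn$intercept, mean(r) - slope_hat * mean(fr), tolerance = 1e-10)
  expect_error(fit_select_curve(c(1, 1, 1), c(20, 21, 22)), "distinct")
  expect_error(fit_select_curve(c(0, 0.5, 0.9), c(20, 21, 22)), "100")
  # inverse property over a noiseless grid, both normalization modes
  for (mode in c("ct", "abundance")) {
    cts_m <- if (mode == "ct") ct100 + log2(0.1 + 0.9 * fr) else
      ct100 - log2(0.1 + 0.9 * fr)
    cm <- fit_select_curve(fr, cts_m, mode = mode)
    est <- estimate_select_fraction(cts_m, cm)$fraction
    expect_equal(est, fr, tolerance = 1e-9)
  }
})

test_that("noisy SELECT fractions are recovered without bias", {
  set.seed(71)
  est <- replicate(300, {
    cts <- simulate_ct_data(c(g = 0.5), type = "select", n_rep = 3,
                            ct_sd = 0.1, seed = sample.int(1e6, 1))
    select_workflow(cts)$estimates$fraction
  })
  expect_lt(abs(mean(est) - 0.5), 0.02)
})

test_that("Dunnett adjustment dominates raw p and calibrates correctly", {
  set.seed(61)
  g <- split(rnorm(24), rep(1:4, each = 6))
  res <- anova_dunnett(g, 1, n_mc = 5e4, seed = 2)
  expect_true(all(res$comparisons$p_adj >= res$comparisons$p_raw))
  expect_true(all(res$comparisons$p_adj >= 0 & res$comparisons$p_adj <= 1))
  # overwhelming effect: adjusted p below 0.001
  g2 <- g; g2[[3]] <- g2[[3]] + 10
  res2 <- anova_dunnett(g2, 1, n_mc = 5e4, seed = 2)
  expect_lt(res2$comparisons$p_adj[res2$comparisons$group == 3], 0.001)
  expect_lt(res2$f_p_value, 1e-6)
  # two-group degeneracy: matches the pooled t-test within MC error
  x <- rnorm(8); y <- rnorm(8, 0.7)
  res3 <- anova_dunnett(list(x, y), 1, n_mc = 2e5, seed = 7)
  expect_equal(res3$comparisons$p_adj,
               t.test(y, x, var.equal = TRUE)$p.value, tolerance = 0.01)
  expect_error(anova_dunnett(g, 9), "control_index")
})

test_that("Dunnett adjusted p agrees with the multivariate-t reference", {
  skip_if_not_installed("multcomp")
  set.seed(91)
  y <- c(rnorm(5, 0), rnorm(5, 0.8), rnorm(5, 0.3), rnorm(5, -0.4))
  fac <- factor(rep(c("ctrl", "a", "b", "c"), each = 5),
                levels = c("ctrl", "a", "b", "c"))
  res <- anova_dunnett(split(y, rep(1:4, each = 5)), 1, n_mc = 2e5, seed = 3)
  fit <- multcomp::glht(stats::aov(y ~ fac),
                        linfct = multcomp::mcp(fac = "Dunnett"))
  ref <- summary(fit)$test$pvalues
  expect_equal(res$comparisons$p_adj, as.vector(ref), tolerance = 0.02)
})
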