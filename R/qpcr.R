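# qPCR-side arithmetic: MeRIP-qPCR enrichment and relative m6A level,
# delta-delta-Ct expression, SELECT standard curves and single-base m6A
# fraction estimation, and control-referenced group testing (ANOVA +
# Monte-Carlo Dunnett).

#' Relative template amount from a Ct value
#'
#' Standard qPCR quantification primitive: `amount = efficiency^(-ct)`,
#' strictly decreasing in Ct (one cycle earlier means `efficiency` times
#' more template at perfect doubling).
#'
#' @param ct Quantification cycle (vectorized).
#' @param efficiency Amplification efficiency per cycle, in (1, 2].
#' @return Relative amounts.
#' @export
relative_amount <- function(ct, efficiency = 2) {
  if (efficiency <= 1 || efficiency > 2) stop("efficiency must be in (1, 2]")
  efficiency^(-ct)
}

#' MeRIP-qPCR IP enrichment ratio
#'
#' The enrichment of a transcript region in the m6A immunoprecipitate is the
#' ratio of its amount in the IP fraction to its amount in the input
#' fraction, after rescaling both to the same RNA mass:
#' `efficiency^(ct_input - ct_ip) * mass_input_ng / mass_ip_ng`.
#' Defaults reflect a 2 ug IP against a 500 ng input.
#'
#' @param ct_ip,ct_input Ct values of the IP and input reactions
#'   (vectorized).
#' @param mass_ip_ng,mass_input_ng RNA masses (ng) the two reactions were
#'   generated from.
#' @param efficiency Amplification efficiency, in (1, 2].
#' @return Enrichment ratios (dimensionless).
#' @export
merip_enrichment <- function(ct_ip, ct_input, mass_ip_ng = 2000,
                             mass_input_ng = 500, efficiency = 2) {
  if (any(mass_ip_ng <= 0) || any(mass_input_ng <= 0)) {
    stop("RNA masses must be positive")
  }
  nl <- c(length(ct_ip), length(ct_input))
  if (nl[1] != nl[2] && min(nl) != 1L) {
    stop("every IP record needs a paired input record")
  }
  efficiency^(ct_input - ct_ip) * (mass_input_ng / mass_ip_ng)
}

#' Relative m6A level of a group against its unirradiated control
#'
#' The fold change of mean enrichment: `mean(group) / mean(control)`. The
#' standard error is propagated by the delta method for a ratio of
#' independent means: `fold * sqrt(se_g^2/mean_g^2 + se_c^2/mean_c^2)`.
#'
#' @param group_enrichments,control_enrichments Positive enrichment values
#'   (replicates) of the exposed group and of the control group.
#' @return List with `fold`, `se`, and the group means.
#' @export
relative_m6a_level <- function(group_enrichments, control_enrichments) {
  if (length(group_enrichments) < 1 || length(control_enrichments) < 1) {
    stop("need at least one value per group")
  }
  mg <- mean(group_enrichments); mc <- mean(control_enrichments)
  if (mc == 0) stop("control mean is zero")
  fold <- mg / mc
  se_g <- if (length(group_enrichments) > 1) {
    stats::sd(group_enrichments) / sqrt(length(group_enrichments))
  } else 0
  se_c <- if (length(control_enrichments) > 1) {
    stats::sd(control_enrichments) / sqrt(length(control_enrichments))
  } else 0
  se <- abs(fold) * sqrt((se_g / mg)^2 + (se_c / mc)^2)
  list(fold = fold, se = se, group_mean = mg, control_mean = mc)
}

#' Primer feasibility: m6A signal over IgG background
#'
#' A MeRIP primer pair is usable when its anti-m6A IP enrichment stands
#' clearly above the nonspecific IgG background; the gate is
#' `ip / igg >= min_signal_ratio` (boundary inclusive).
#'
#' @param ip_enrichment,igg_enrichment Positive enrichment ratios of the
#'   anti-m6A and IgG immunoprecipitations (vectorized).
#' @param min_signal_ratio Minimum acceptable signal-to-background ratio.
#' @return Data frame with `ratio` and logical `pass`.
#' @export
primer_feasibility <- function(ip_enrichment, igg_enrichment,
                               min_signal_ratio = 4) {
  if (any(ip_enrichment <= 0) || any(igg_enrichment <= 0)) {
    stop("enrichments must be positive")
  }
  ratio <- ip_enrichment / igg_enrichment
  data.frame(ratio = ratio, pass = ratio >= min_signal_ratio)
}

#' Relative expression by the delta-delta-Ct method
#'
#' `efficiency^(-ddct)` with
#' `ddct = (ct_target_s - ct_ref_s) - (ct_target_c - ct_ref_c)`: target Ct
#' normalized to the reference gene within sample and control, then the
#' sample normalized to the control condition.
#'
#' @param ct_target_s,ct_ref_s Sample Cts of target and reference gene.
#' @param ct_target_c,ct_ref_c Control Cts of target and reference gene.
#' @param efficiency Amplification efficiency, in (1, 2].
#' @return Fold change of target expression relative to control.
#' @export
relative_expression_ddct <- function(ct_target_s, ct_ref_s, ct_target_c,
                                     ct_ref_c, efficiency = 2) {
  if (any(!is.finite(c(ct_target_s, ct_ref_s, ct_target_c, ct_ref_c)))) {
    stop("all Ct values must be finite")
  }
  ddct <- (ct_target_s - ct_ref_s) - (ct_target_c - ct_ref_c)
  relative_amount(ddct, efficiency)
}

#' Fit a SELECT single-base m6A standard curve
#'
#' SELECT product formation is suppressed by m6A at the interrogated base;
#' across standards of known m6A fraction, the relative product
#' `r = 2^(ct - ct_ref_100)` (each standard's signal referenced to the 100
#' percent m6A standard) is linear in the fraction. An ordinary
#' least-squares line `r = intercept + slope * fraction` is fitted; the 100
#' percent standard has `r = 1` by construction (up to replicate noise). A
#' `mode = "abundance"` flag instead uses product abundance
#' `r = 2^(-(ct - ct_ref_100))`, the alternative reading of the
#' normalization; both give a linear calibration with opposite slope signs.
#'
#' @param fractions m6A fractions of the standards, in `[0, 1]`, at least 3
#'   distinct values including 1.0.
#' @param cts Ct values, same length.
#' @param mode `"ct"` (default, r = 2^(Ct - Ct100)) or `"abundance"`
#'   (r = 2^-(Ct - Ct100)).
#' @return List of class `select_curve`: `slope`, `intercept`, `r2`,
#'   `ct_ref_100`, `mode`.
#' @export
fit_select_curve <- function(fractions, cts, mode = c("ct", "abundance")) {
  mode <- match.arg(mode)
  if (length(fractions) != length(cts)) stop("fractions and cts differ in length")
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  if (length(unique(fractions)) < 3) stop("need >= 3 distinct fractions")
  if (!any(fractions == 1)) stop("the 100% m6A standard (fraction 1.0) is required")
  ct_ref_100 <- mean(cts[fractions == 1])
  r <- if (mode == "ct") 2^(cts - ct_ref_100) else 2^(-(cts - ct_ref_100))
  fit <- stats::lm(r ~ fractions)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((r - mean(r))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, ct_ref_100 = ct_ref_100, mode = mode),
            class = "select_curve")
}

#' Estimate a single-base m6A fraction from a SELECT Ct
#'
#' Inverts the standard curve: the sample's relative product
#' `r = 2^(ct_sample - ct_ref_100)` (or the abundance form, per the curve's
#' mode) is mapped to `(r - intercept) / slope`, clamped to `[0, 1]` with an
#' out-of-range flag.
#'
#' @param ct_sample Sample Ct value(s).
#' @param curve A `select_curve` from [fit_select_curve()].
#' @return Data frame with `fraction` (clamped) , `raw_fraction`, and
#'   logical `out_of_range`.
#' @export
estimate_select_fraction <- function(ct_sample, curve) {
  stopifnot(inherits(curve, "select_curve"))
  if (curve$slope == 0) stop("zero slope: curve cannot be inverted")
  d <- ct_sample - curve$ct_ref_100
  r <- if (curve$mode == "ct") 2^d else 2^(-d)
  raw <- (r - curve$intercept) / curve$slope
  data.frame(fraction = pmin(1, pmax(0, raw)), raw_fraction = raw,
             out_of_range = raw < 0 | raw > 1)
}

#' SELECT workflow over a simulated or measured Ct table
#'
#' Fits the standard curve from the `group_id == "standard"` records (their
#' true fractions in `std_fraction`) and estimates the fraction of every
#' other group from its mean Ct.
#'
#' @param ct_records Ct table in the `ct` schema with a `std_fraction`
#'   column, as produced by [simulate_ct_data()] with `type = "select"`.
#' @param mode Normalization mode passed to [fit_select_curve()].
#' @return List with the fitted `curve` and a data frame `estimates`
#'   (`group_id`, `fraction`).
#' @export
select_workflow <- function(ct_records, mode = "ct") {
  std <- ct_records[ct_records$group_id == "standard", ]
  if (!nrow(std)) stop("no standard records (group_id == 'standard')")
  curve <- fit_select_curve(std$std_fraction, std$ct, mode = mode)
  smp <- ct_records[ct_records$group_id != "standard", ]
  groups <- unique(smp$group_id)
  est <- vapply(groups, function(g) {
    estimate_select_fraction(mean(smp$ct[smp$group_id == g]), curve)$fraction
  }, numeric(1))
  list(curve = curve,
       estimates = data.frame(group_id = groups, fraction = est,
                              stringsAsFactors = FALSE))
}

#' MeRIP enrichment per group from a Ct table
#'
#' Pairs IP and input records within each group (matched by replicate order)
#' and computes mass-normalized enrichments.
#'
#' @param ct_records Ct table in the `ct` schema with `fraction` values
#'   `"IP"` and `"input"`.
#' @param efficiency Amplification efficiency.
#' @return Data frame `group_id`, `replicate`, `enrichment`.
#' @export
merip_workflow <- function(ct_records, efficiency = 2) {
  groups <- unique(ct_records$group_id)
  out <- lapply(groups, function(g) {
    ip <- ct_records[ct_records$group_id == g & ct_records$fraction == "IP", ]
    inp <- ct_records[ct_records$group_id == g & ct_records$fraction == "input", ]
    if (nrow(ip) == 0 || nrow(ip) != nrow(inp)) {
      stop("group ", g, ": IP and input records do not pair up")
    }
    data.frame(group_id = g, replicate = seq_len(nrow(ip)),
               enrichment = merip_enrichment(ip$ct, inp$ct,
                                             mass_ip_ng = ip$rna_mass_ng,
                                             mass_input_ng = inp$rna_mass_ng,
                                             efficiency = efficiency),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-way ANOVA with Monte-Carlo Dunnett many-to-one comparisons
#'
#' Overall F-test across groups, followed by Dunnett-style adjusted
#' p-values for each group against the control: for every non-control group
#' the usual pooled-variance t statistic versus control is computed, and its
#' adjusted p-value is the null probability that the maximum absolute
#' statistic over all comparisons exceeds the observed one. That null
#' distribution is simulated (`n_mc` draws) exactly under the common-variance
#' normal model with the study's group sizes, which reproduces the
#' correlation induced by the shared control and pooled variance, balanced
#' or not.
#'
#' @param groups List of numeric vectors (>= 2 groups, >= 2 replicates each).
#' @param control_index Index of the control group in `groups` (default 1).
#' @param n_mc Monte-Carlo draws for the max-|t| null (default 1e5).
#' @param seed Integer seed for the Monte-Carlo draw.
#' @return List of class `group_comparison`: `means`, `sds`, `n`,
#'   `f_p_value`, `comparisons` (data frame with `t`, `p_raw`, `p_adj`),
#'   `n_mc`, `seed`.
#' @export
anova_dunnett <- function(groups, control_index = 1, n_mc = 1e5, seed = 1L) {
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups")
  if (control_index < 1 || control_index > k) stop("control_index out of range")
  n <- lengths(groups)
  if (any(n < 2)) stop("need >= 2 replicates per group")
  y <- unlist(groups)
  fac <- factor(rep(seq_len(k), n))
  fit <- stats::lm(y ~ fac)
  f_p <- stats::anova(fit)[["Pr(>F)"]][1]

  means <- vapply(groups, mean, numeric(1))
  sds <- vapply(groups, stats::sd, numeric(1))
  nu <- sum(n) - k
  sp2 <- sum((n - 1) * sds^2) / nu
  others <- setdiff(seq_len(k), control_index)
  tstat <- (means[others] - means[control_index]) /
    sqrt(sp2 * (1 / n[others] + 1 / n[control_index]))
  p_raw <- 2 * stats::pt(-abs(tstat), nu)

  # Null max-|t|: group means ~ N(0, 1/n_i), pooled variance ~ chi2_nu / nu,
  # with the control mean and the variance shared across comparisons.
  set.seed(seed)
  zc <- stats::rnorm(n_mc, 0, sqrt(1 / n[control_index]))
  v <- stats::rchisq(n_mc, nu) / nu
  maxt <- rep(0, n_mc)
  for (i in others) {
    zi <- stats::rnorm(n_mc, 0, sqrt(1 / n[i]))
    ti <- (zi - zc) / sqrt(v * (1 / n[i] + 1 / n[control_index]))
    maxt <- pmax(maxt, abs(ti))
  }
  p_adj <- vapply(abs(tstat), function(tt) mean(maxt >= tt), numeric(1))
  p_adj <- pmax(p_adj, p_raw)  # adjusted never below raw

  structure(list(means = means, sds = sds, n = n, f_p_value = f_p,
                 comparisons = data.frame(group = others, t = unname(tstat),
                                          p_raw = unname(p_raw),
                                          p_adj = unname(p_adj)),
                 n_mc = n_mc, seed = as.integer(seed)),
            class = "group_comparison")
}
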