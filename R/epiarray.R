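# Two-channel m6A epiarray quantification: spike-in normalization, per-gene
# modification level / quantity, and differential methylation calls.

#' Spike-in normalization of a two-channel array sample
#'
#' Centers each channel's log2 intensities on the spike-in control probes:
#' every log2 intensity is shifted by minus the mean log2 spike-in intensity
#' of that channel (equivalently, linear intensities are divided by the
#' spike-ins' geometric mean). After normalization the mean log2 spike-in
#' intensity of each channel is zero, and within-channel rank order is
#' unchanged.
#'
#' @param ip_intensity,sup_intensity Positive linear intensities of the IP
#'   (Cy5 role) and Sup (Cy3 role) channels, one value per probe.
#' @param is_spikein Logical vector flagging spike-in probes.
#' @return List with normalized `ip_intensity` and `sup_intensity`.
#' @export
normalize_spikein <- function(ip_intensity, sup_intensity, is_spikein) {
  if (!any(is_spikein)) stop("no spike-in probes: normalization undefined")
  if (any(ip_intensity <= 0) || any(sup_intensity <= 0)) {
    stop("intensities must be strictly positive")
  }
  shift_ip <- mean(log2(ip_intensity[is_spikein]))
  shift_sup <- mean(log2(sup_intensity[is_spikein]))
  list(ip_intensity = ip_intensity / 2^shift_ip,
       sup_intensity = sup_intensity / 2^shift_sup)
}

#' Spike-in normalize every sample of an epiarray simulation or matrix pair
#'
#' @param sim An `epiarray_sim` object (see [simulate_epiarray()]).
#' @return The object with `ip` and `sup` replaced by normalized intensities
#'   and a `normalized = TRUE` flag.
#' @export
normalize_epiarray <- function(sim) {
  stopifnot(inherits(sim, "epiarray_sim"))
  if (isTRUE(sim$normalized)) return(sim)
  spk <- sim$probes$is_spikein
  for (j in seq_len(ncol(sim$ip))) {
    nrm <- normalize_spikein(sim$ip[, j], sim$sup[, j], spk)
    sim$ip[, j] <- nrm$ip_intensity
    sim$sup[, j] <- nrm$sup_intensity
  }
  sim$normalized <- TRUE
  sim
}

#' m6A modification level (percentage) from normalized channel intensities
#'
#' The modification level is the IP share of the total signal,
#' `100 * ip / (ip + sup)`: the percentage of a transcript's signal carried
#' by the methylated (immunoprecipitated) fraction. By construction the
#' level and the unmodified share sum to 100.
#'
#' @param ip,sup Non-negative normalized linear intensities (vectorized);
#'   at least one of each pair must be positive.
#' @return Percentages in `[0, 100]`.
#' @export
compute_m6a_level <- function(ip, sup) {
  if (any(ip < 0) || any(sup < 0)) stop("intensities must be non-negative")
  if (any(ip + sup == 0)) stop("ip and sup both zero: level undefined")
  100 * ip / (ip + sup)
}

#' m6A quantity from the normalized IP intensity
#'
#' The modification amount is the normalized linear IP intensity itself,
#' kept as a named quantity for reporting alongside the percentage level.
#'
#' @param ip_normalized Positive normalized linear IP intensity (vectorized).
#' @return The same values, validated.
#' @export
compute_m6a_quantity <- function(ip_normalized) {
  if (any(ip_normalized <= 0)) stop("normalized IP intensity must be positive")
  ip_normalized
}

#' Per-gene m6A level and quantity matrices from a raw array study
#'
#' Runs spike-in normalization on every sample, computes probe-level
#' modification levels and quantities, and averages probes per gene
#' (spike-ins excluded).
#'
#' @param sim An `epiarray_sim` object, raw or already normalized.
#' @return List of class `m6a_matrix`: `level` and `quantity` gene-by-sample
#'   matrices and the `samples` annotation data frame.
#' @export
m6a_level_matrix <- function(sim) {
  sim <- normalize_epiarray(sim)
  keep <- !sim$probes$is_spikein
  lev <- compute_m6a_level(sim$ip[keep, , drop = FALSE],
                           sim$sup[keep, , drop = FALSE])
  qty <- compute_m6a_quantity(sim$ip[keep, , drop = FALSE])
  gene <- sim$probes$gene_id[keep]
  if (anyDuplicated(gene)) {
    cnt <- table(gene)
    lev <- rowsum(lev, gene)
    qty <- rowsum(qty, gene)
    lev <- lev / as.vector(cnt[rownames(lev)])
    qty <- qty / as.vector(cnt[rownames(qty)])
  } else {
    rownames(lev) <- rownames(qty) <- gene
  }
  structure(list(level = lev, quantity = qty, samples = sim$samples),
            class = "m6a_matrix")
}

# Vectorized two-sample t-test on the rows of two matrices (log2 scale).
# Returns t, df, p; handles the degenerate zero-variance cases explicitly.
.row_t_test <- function(x, y, welch = FALSE) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  }
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & m1 == m2
    ne <- degen & m1 != m2
    p[eq] <- 1
    if (any(ne)) {
      p[ne] <- 0
      warning("zero within-group variance with unequal means: p set to 0")
    }
    t[eq] <- 0; t[ne] <- Inf * sign((m1 - m2)[ne])
  }
  list(t = t, df = df, p = p)
}

#' Differential m6A methylation between an exposed and a control group
#'
#' Fold change is the ratio of group means on the linear modification-level
#' scale; significance is an unpaired two-sided t-test on log2-transformed
#' levels (Student pooled-variance by default, Welch optionally). A gene is
#' called `hyper` when fold change exceeds `fc_hi` and p < `alpha`, `hypo`
#' when fold change is below `fc_lo` and p < `alpha` (strict inequalities),
#' otherwise `ns`. No multiple-testing correction is applied to the calls;
#' a Benjamini-Hochberg FDR column is reported for information.
#'
#' @param levels_exposed,levels_control Gene-by-replicate matrices (or
#'   vectors for a single gene) of positive m6A levels; >= 2 replicates per
#'   group.
#' @param fc_hi,fc_lo Fold-change call thresholds (defaults 2 and 0.5).
#' @param alpha Significance threshold on the raw p-value (default 0.01).
#' @param welch Use the Welch (unequal-variance) test instead of Student.
#' @return Data frame with `gene_id`, `log2_fc`, `p_value`, `bh_fdr`,
#'   `status`.
#' @export
differential_m6a <- function(levels_exposed, levels_control, fc_hi = 2,
                             fc_lo = 0.5, alpha = 0.01, welch = FALSE) {
  if (is.null(dim(levels_exposed))) levels_exposed <- t(as.matrix(levels_exposed))
  if (is.null(dim(levels_control))) levels_control <- t(as.matrix(levels_control))
  if (ncol(levels_exposed) < 2 || ncol(levels_control) < 2) {
    stop("need >= 2 replicates per group")
  }
  if (nrow(levels_exposed) != nrow(levels_control)) {
    stop("gene sets of the two groups differ")
  }
  if (any(levels_exposed <= 0) || any(levels_control <= 0)) {
    stop("m6A levels must be strictly positive")
  }
  fc <- rowMeans(levels_exposed) / rowMeans(levels_control)
  tt <- .row_t_test(log2(levels_exposed), log2(levels_control), welch = welch)
  status <- rep("ns", length(fc))
  status[fc > fc_hi & tt$p < alpha] <- "hyper"
  status[fc < fc_lo & tt$p < alpha] <- "hypo"
  ids <- rownames(levels_exposed)
  if (is.null(ids)) ids <- sprintf("gene%05d", seq_along(fc))
  data.frame(gene_id = ids, log2_fc = log2(fc), p_value = tt$p,
             bh_fdr = stats::p.adjust(tt$p, "BH"), status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential m6A calls at every timepoint of a study
#'
#' At each timepoint, compares the exposed group (a single non-zero dose,
#' chosen by `exposed_dose` or unambiguously present) against the dose-0
#' sham group of the same timepoint.
#'
#' @param mat An `m6a_matrix` from [m6a_level_matrix()].
#' @param exposed_dose Dose (Gy) of the exposed arm; defaults to the single
#'   non-zero dose of the design (error if several are present).
#' @inheritParams differential_m6a
#' @return Named list of differential-call data frames, one per timepoint
#'   (names are the timepoints in days).
#' @export
differential_by_timepoint <- function(mat, exposed_dose = NULL, fc_hi = 2,
                                      fc_lo = 0.5, alpha = 0.01,
                                      welch = FALSE) {
  stopifnot(inherits(mat, "m6a_matrix"))
  smp <- mat$samples
  nz <- sort(unique(smp$dose_gy[smp$dose_gy > 0]))
  if (is.null(exposed_dose)) {
    if (length(nz) != 1L) {
      stop("several exposed doses present; give exposed_dose explicitly")
    }
    exposed_dose <- nz
  }
  tps <- sort(unique(smp$tpi_days))
  out <- lapply(tps, function(tp) {
    e <- smp$sample_id[smp$tpi_days == tp & smp$dose_gy == exposed_dose]
    c0 <- smp$sample_id[smp$tpi_days == tp & smp$dose_gy == 0]
    if (length(e) < 2 || length(c0) < 2) {
      stop(sprintf("timepoint %g lacks replicates in exposed or sham group", tp))
    }
    differential_m6a(mat$level[, e, drop = FALSE],
                     mat$level[, c0, drop = FALSE],
                     fc_hi = fc_hi, fc_lo = fc_lo, alpha = alpha,
                     welch = welch)
  })
  names(out) <- as.character(tps)
  out
}
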