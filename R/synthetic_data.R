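#' @keywords internal
"_PACKAGE"

# ---- study design -----------------------------------------------------------

#' Define an irradiation study design
#'
#' A design is the grid of absorbed doses (Gy) and sampling times post
#' irradiation (days) with a fixed number of biological replicates per
#' (dose, time) group. The default mirrors a mouse total-body-irradiation
#' time-course: gamma-ray doses 0.2--6.5 Gy plus sham controls, sampled at
#' days 1, 3, 7, 14 and 28 with n = 5 animals per group. An optional
#' high-dose arm adds a 10 Gy group restricted to days 1 and 3 (animals at
#' that dose do not survive to later timepoints).
#'
#' @param doses Numeric vector of non-negative doses in Gy, distinct.
#' @param timepoints Numeric vector of positive times post irradiation, days.
#' @param replicates_per_group Positive integer, biological replicates per
#'   (dose, timepoint) group.
#' @param include_sham If `TRUE` (default) a dose-0 sham group is present at
#'   every timepoint.
#' @param high_dose_arm If `TRUE`, add a 10 Gy arm at days 1 and 3 only.
#' @return An object of class `study_design`: a list with the validated
#'   fields plus `groups`, a data frame with one row per (dose, timepoint)
#'   group actually present.
#' @export
study_design <- function(doses = c(0.2, 0.5, 1, 2, 4, 6.5),
                         timepoints = c(1, 3, 7, 14, 28),
                         replicates_per_group = 5L,
                         include_sham = TRUE,
                         high_dose_arm = FALSE) {
  doses <- as.numeric(doses)
  if (any(doses < 0)) stop("doses must be non-negative (Gy)")
  if (include_sham && !any(doses == 0)) doses <- c(0, doses)
  doses <- sort(unique(doses))
  if (anyDuplicated(doses)) stop("doses must be distinct")
  timepoints <- sort(as.numeric(timepoints))
  if (length(timepoints) < 1L || any(timepoints <= 0)) {
    stop("timepoints must be positive (days)")
  }
  replicates_per_group <- as.integer(replicates_per_group)
  if (replicates_per_group < 1L) stop("replicates_per_group must be >= 1")

  groups <- expand.grid(dose_gy = doses, tpi_days = timepoints,
                        KEEP.OUT.ATTRS = FALSE)
  if (high_dose_arm) {
    extra <- expand.grid(dose_gy = 10, tpi_days = intersect(c(1, 3), timepoints),
                         KEEP.OUT.ATTRS = FALSE)
    groups <- rbind(groups, extra)
  }
  groups <- groups[order(groups$tpi_days, groups$dose_gy), , drop = FALSE]
  rownames(groups) <- NULL
  structure(
    list(doses = doses, timepoints = timepoints,
         replicates_per_group = replicates_per_group,
         include_sham = include_sham, high_dose_arm = high_dose_arm,
         groups = groups),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Irradiation study design\n")
  cat("  doses (Gy):     ", paste(x$doses, collapse = ", "),
      if (x$high_dose_arm) " (+10 Gy arm, days 1 and 3)" else "", "\n", sep = "")
  cat("  timepoints (d): ", paste(x$timepoints, collapse = ", "), "\n", sep = "")
  cat("  replicates:     ", x$replicates_per_group, " per group; ",
      nrow(x$groups), " groups\n", sep = "")
  invisible(x)
}

# ---- response surface -------------------------------------------------------

#' Parameters of the dose--time m6A response surface
#'
#' The simulated m6A response (fold change over sham) follows a Hill curve in
#' dose multiplied by a log-normal kernel in time:
#' \deqn{f(d, t) = b + A \frac{d^h}{d^h + K^h}
#'   \exp\left(-\frac{(\ln t/t_{peak})^2}{2 w^2}\right)}
#' so the response saturates at `baseline + amplitude` for large doses at the
#' peak time, equals `baseline` at dose 0 for every time, and is unimodal on a
#' log-spaced day grid. Defaults emulate an Ncoa4-like marker: a day-14 peak
#' with a detectable day-1 response and roughly six-fold saturation.
#'
#' @param amplitude Maximal fold elevation over baseline (A >= 0).
#' @param half_dose Dose of half-maximal response, Gy (K > 0).
#' @param hill Hill coefficient (h > 0).
#' @param t_peak Time of peak response, days (> 0).
#' @param t_width Width of the time kernel in log-days (> 0).
#' @param baseline Response at dose 0 (> 0, default 1: fold scale).
#' @return An object of class `surface_params`.
#' @export
surface_params <- function(amplitude = 6, half_dose = 2, hill = 1.2,
                           t_peak = 14, t_width = 1.5, baseline = 1) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (half_dose <= 0) stop("half_dose must be positive")
  if (hill <= 0) stop("hill must be positive")
  if (t_peak <= 0) stop("t_peak must be positive")
  if (t_width <= 0) stop("t_width must be positive")
  if (baseline <= 0) stop("baseline must be positive")
  structure(list(amplitude = amplitude, half_dose = half_dose, hill = hill,
                 t_peak = t_peak, t_width = t_width, baseline = baseline),
            class = "surface_params")
}

#' Expected relative m6A level at a dose and time
#'
#' Evaluates the parametric dose--time response surface (see
#' [surface_params()]). Vectorized over `dose` and `tpi`.
#'
#' @param dose Absorbed dose in Gy (>= 0).
#' @param tpi Time post irradiation in days (> 0).
#' @param params A [surface_params()] object.
#' @return Expected m6A level as fold over sham (same scale as `baseline`).
#' @export
response_surface <- function(dose, tpi, params = surface_params()) {
  stopifnot(inherits(params, "surface_params"))
  if (any(dose < 0)) stop("dose must be non-negative")
  if (any(tpi <= 0)) stop("tpi must be positive")
  hill_term <- ifelse(dose == 0, 0,
                      dose^params$hill /
                        (dose^params$hill + params$half_dose^params$hill))
  time_term <- exp(-(log(tpi / params$t_peak))^2 / (2 * params$t_width^2))
  params$baseline + params$amplitude * hill_term * time_term
}

# ---- seed plumbing ----------------------------------------------------------

# Fixed child-seed scheme: one global seed expands to per-component seeds by
# adding a documented constant offset, so any simulation component can be
# re-run in isolation. Offsets are spaced so components never collide for
# global seeds below ~2.1e9 - 90000.
.seed_offsets <- c(dose_response = 10007L, epiarray = 20011L, ct = 30011L,
                   cv = 40009L, calibration = 50021L, pipeline = 60013L)

#' Derive a component child seed from a global seed
#'
#' @param seed Global integer seed.
#' @param component One of `"dose_response"`, `"epiarray"`, `"ct"`, `"cv"`,
#'   `"calibration"`, `"pipeline"`.
#' @return An integer seed for the component.
#' @export
child_seed <- function(seed, component) {
  component <- match.arg(component, names(.seed_offsets))
  as.integer((as.numeric(seed) + .seed_offsets[[component]]) %% .Machine$integer.max)
}

# Multiplicative log-normal noise factors with mean exactly 1 and coefficient
# of variation cv: sdlog^2 = log(1 + cv^2), meanlog = -sdlog^2 / 2.
.lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

# ---- dose-response simulation ----------------------------------------------

#' Simulate dose-response observations of a relative m6A marker
#'
#' One observation per (dose, timepoint, replicate) of the study design: the
#' response-surface mean times multiplicative log-normal measurement noise
#' with unit mean and coefficient of variation `noise_cv`. Relative m6A
#' fold values are strictly positive ratios, hence the multiplicative error
#' model.
#'
#' @param design A [study_design()].
#' @param params A [surface_params()].
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; default 0.1).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A data frame with columns `subject_id`, `m6a_value`, `m6a_scale`,
#'   `tpi_days`, `dose_gy`, `replicate` and `true_mean`.
#' @export
simulate_dose_response <- function(design, params = surface_params(),
                                   noise_cv = 0.1, seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (nrow(design$groups) == 0L) stop("empty design")
  g <- design$groups
  n <- design$replicates_per_group
  pts <- g[rep(seq_len(nrow(g)), each = n), , drop = FALSE]
  pts$replicate <- rep(seq_len(n), times = nrow(g))
  pts$true_mean <- response_surface(pts$dose_gy, pts$tpi_days, params)
  set.seed(seed)
  pts$m6a_value <- pts$true_mean * .lognormal_factor(nrow(pts), noise_cv)
  pts$m6a_scale <- "relative"
  pts$subject_id <- sprintf("d%g_t%g_r%d", pts$dose_gy, pts$tpi_days,
                            pts$replicate)
  rownames(pts) <- NULL
  pts[, c("subject_id", "m6a_value", "m6a_scale", "tpi_days", "dose_gy",
          "replicate", "true_mean")]
}

# ---- epiarray simulation ----------------------------------------------------

#' Default planted-signal table for the epiarray simulation
#'
#' @param n_consistent Genes elevated at every timepoint in exposed samples.
#' @param n_transient Genes elevated at `transient_tp` only.
#' @param n_hypo Genes symmetrically decreased at every timepoint.
#' @param effect Fold change on the m6A level for planted genes (> 0).
#' @param transient_tp Timepoint (days) at which transient genes respond.
#' @return Data frame with columns `gene_id`, `pattern`, `effect`,
#'   `timepoint` (NA except for transient genes); gene ids are the first
#'   ids of the simulated transcriptome.
#' @export
planted_signals <- function(n_consistent = 60, n_transient = 40, n_hypo = 30,
                            effect = 4, transient_tp = 3) {
  n <- n_consistent + n_transient + n_hypo
  data.frame(
    gene_id = sprintf("gene%05d", seq_len(n)),
    pattern = rep(c("consistent_hyper", "transient_hyper", "hypo"),
                  times = c(n_consistent, n_transient, n_hypo)),
    effect = rep(c(effect, effect, 1 / effect),
                 times = c(n_consistent, n_transient, n_hypo)),
    timepoint = c(rep(NA_real_, n_consistent),
                  rep(transient_tp, n_transient),
                  rep(NA_real_, n_hypo)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a two-channel m6A epitranscriptomic microarray study
#'
#' Generates per-probe linear IP (immunoprecipitated, Cy5 role) and Sup
#' (supernatant, Cy3 role) intensities for every sample of the design. Each
#' gene carries a baseline m6A fraction; planted genes multiply that fraction
#' by their effect size in exposed (dose > 0) samples at the timepoints their
#' pattern dictates. Spike-in probes share known base intensities in both
#' channels and are scaled, together with all other probes of a channel, by a
#' sample- and channel-specific factor, so spike-in normalization is
#' exercised. Gaussian noise of sd `noise_sd_log2` is added on the log2
#' intensity scale.
#'
#' @param design A [study_design()]; for screening studies a two-arm design
#'   (sham + one exposed dose) is typical.
#' @param n_genes Number of simulated transcripts.
#' @param n_spikeins Number of spike-in control probes (>= 3).
#' @param planted Data frame as from [planted_signals()]; gene ids must be a
#'   subset of the simulated ids. `NULL` plants nothing (pure null study).
#' @param noise_sd_log2 Gaussian noise sd on log2 intensities (>= 0).
#' @param seed Integer seed.
#' @return A list of class `epiarray_sim`: `ip` and `sup` probe-by-sample
#'   intensity matrices, `probes` (probe_id, gene_id, is_spikein), `samples`
#'   annotation data frame, and `truth` (per-gene pattern labels, `"null"`
#'   for unplanted genes).
#' @export
simulate_epiarray <- function(design, n_genes = 1000, n_spikeins = 10,
                              planted = NULL, noise_sd_log2 = 0.15,
                              seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  if (n_spikeins < 3) stop("n_spikeins must be >= 3")
  if (noise_sd_log2 < 0) stop("noise_sd_log2 must be non-negative")
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  if (!is.null(planted)) {
    if (!all(planted$gene_id %in% gene_ids)) {
      stop("planted gene ids must be a subset of simulated gene ids")
    }
    if (anyDuplicated(planted$gene_id)) stop("planted gene ids must be unique")
  }

  set.seed(seed)
  base_frac <- stats::runif(n_genes, 0.05, 0.15)  # baseline m6A fraction
  abundance <- 2^stats::runif(n_genes, 8, 12)     # per-gene total RNA signal

  effect <- rep(1, n_genes)
  pattern <- rep("null", n_genes)
  trans_tp <- rep(NA_real_, n_genes)
  if (!is.null(planted)) {
    idx <- match(planted$gene_id, gene_ids)
    effect[idx] <- planted$effect
    pattern[idx] <- planted$pattern
    trans_tp[idx] <- planted$timepoint
  }
  if (any(base_frac * pmax(effect, 1) >= 1) || any(base_frac * effect <= 0)) {
    stop("effect size drives an m6A fraction outside (0, 1)")
  }

  g <- design$groups
  nrep <- design$replicates_per_group
  samples <- g[rep(seq_len(nrow(g)), each = nrep), , drop = FALSE]
  samples$replicate <- rep(seq_len(nrep), times = nrow(g))
  samples$sample_id <- sprintf("s_d%g_t%g_r%d", samples$dose_gy,
                               samples$tpi_days, samples$replicate)
  rownames(samples) <- NULL
  ns <- nrow(samples)

  spike_base <- 2^seq(6, 10, length.out = n_spikeins)  # same in both channels
  probes <- data.frame(
    probe_id = c(sprintf("p_%s", gene_ids), sprintf("spike%03d", seq_len(n_spikeins))),
    gene_id = c(gene_ids, sprintf("SPIKE%03d", seq_len(n_spikeins))),
    is_spikein = rep(c(FALSE, TRUE), c(n_genes, n_spikeins)),
    stringsAsFactors = FALSE
  )

  ip <- matrix(NA_real_, n_genes + n_spikeins, ns,
               dimnames = list(probes$probe_id, samples$sample_id))
  sup <- ip
  scale_ip <- 2^stats::runif(ns, -1, 1)   # sample/channel scale factors
  scale_sup <- 2^stats::runif(ns, -1, 1)
  for (j in seq_len(ns)) {
    exposed <- samples$dose_gy[j] > 0
    f <- base_frac
    if (exposed) {
      on <- pattern == "consistent_hyper" | pattern == "hypo" |
        (pattern == "transient_hyper" &
           !is.na(trans_tp) & trans_tp == samples$tpi_days[j])
      f[on] <- base_frac[on] * effect[on]
    }
    ip0 <- c(abundance * f, spike_base) * scale_ip[j]
    sup0 <- c(abundance * (1 - f), spike_base) * scale_sup[j]
    npr <- n_genes + n_spikeins
    ip[, j] <- ip0 * 2^stats::rnorm(npr, 0, noise_sd_log2)
    sup[, j] <- sup0 * 2^stats::rnorm(npr, 0, noise_sd_log2)
  }

  structure(
    list(ip = ip, sup = sup, probes = probes, samples = samples,
         truth = data.frame(gene_id = gene_ids, pattern = pattern,
                            effect = effect, timepoint = trans_tp,
                            stringsAsFactors = FALSE),
         seed = as.integer(seed)),
    class = "epiarray_sim"
  )
}

#' Flatten an epiarray simulation to the long table schema
#'
#' @param sim An `epiarray_sim` object.
#' @return Data frame in the `array` table schema (one row per probe and
#'   sample), suitable for [write_table()].
#' @export
epiarray_long <- function(sim) {
  stopifnot(inherits(sim, "epiarray_sim"))
  npr <- nrow(sim$probes); ns <- nrow(sim$samples)
  data.frame(
    probe_id = rep(sim$probes$probe_id, times = ns),
    gene_id = rep(sim$probes$gene_id, times = ns),
    is_spikein = rep(sim$probes$is_spikein, times = ns),
    sample_id = rep(sim$samples$sample_id, each = npr),
    ip_intensity = as.vector(sim$ip),
    sup_intensity = as.vector(sim$sup),
    stringsAsFactors = FALSE
  )
}

# ---- qPCR Ct simulation -----------------------------------------------------

#' Simulate qPCR Ct records by inverting the quantification formulas
#'
#' Generates Ct tables whose noiseless round trip through the corresponding
#' quantification operation recovers the planted truth exactly: amounts obey
#' `amount = efficiency^(-ct)`, so planted ratios are encoded as Ct
#' differences and Gaussian noise of sd `ct_sd` is added per well.
#'
#' Three assay types are supported:
#' \describe{
#'   \item{`merip`}{`true_values` is a named vector of per-group IP/input
#'     enrichment ratios (at equal RNA mass); records carry the default
#'     masses (2000 ng IP, 500 ng input), so the mass-normalized
#'     [merip_enrichment()] recovers the planted enrichment.}
#'   \item{`select`}{`true_values` is a named vector of per-group true m6A
#'     fractions in `[0, 1]`; standard records at `standard_fractions` are
#'     emitted alongside (`group_id = "standard"`), generated from the line
#'     `r = intercept + slope * fraction` with `slope + intercept = 1` so the
#'     100 percent standard has relative product 1.}
#'   \item{`expression`}{`true_values` is a named vector of per-group fold
#'     changes vs the control group (named `"control"`, fold 1 implied if
#'     absent); target and reference records are emitted so
#'     [relative_expression_ddct()] recovers the fold.}
#' }
#'
#' @param true_values Named numeric vector, interpretation per `type`.
#' @param type One of `"merip"`, `"select"`, `"expression"`.
#' @param n_rep Replicate wells per group.
#' @param ct_baseline Baseline Ct of the reference condition (cycles).
#' @param ct_sd Gaussian Ct noise sd (>= 0).
#' @param efficiency Amplification efficiency (doubling = 2).
#' @param mass_ip_ng,mass_input_ng RNA masses for `merip` records.
#' @param select_slope Slope of the SELECT standard line (intercept is
#'   `1 - select_slope`).
#' @param standard_fractions m6A fractions of the SELECT standards.
#' @param seed Integer seed.
#' @return Data frame of Ct records in the `ct` table schema.
#' @export
simulate_ct_data <- function(true_values,
                             type = c("merip", "select", "expression"),
                             n_rep = 3, ct_baseline = 25, ct_sd = 0,
                             efficiency = 2, mass_ip_ng = 2000,
                             mass_input_ng = 500, select_slope = 0.9,
                             standard_fractions = c(0, 0.25, 0.5, 0.75, 1),
                             seed = 1L) {
  type <- match.arg(type)
  if (ct_sd < 0) stop("ct_sd must be non-negative")
  if (is.null(names(true_values)) || any(!nzchar(names(true_values)))) {
    stop("true_values must be a named vector (names are group ids)")
  }
  set.seed(seed)
  rec <- function(group, fraction, ct_true, mass = 500, target = "target1",
                  primer = "primer1") {
    data.frame(target_id = target, primer_id = primer, fraction = fraction,
               ct = ct_true + stats::rnorm(length(ct_true), 0, ct_sd),
               rna_mass_ng = mass, group_id = group, dose_gy = NA_real_,
               tpi = NA_real_, tpi_unit = "day", stringsAsFactors = FALSE)
  }
  out <- list()
  if (type == "merip") {
    if (any(true_values <= 0)) stop("enrichments must be positive")
    for (gname in names(true_values)) {
      enr <- true_values[[gname]]
      ct_input <- rep(ct_baseline, n_rep)
      # enrichment = eff^(ct_input - ct_ip) * (mass_input / mass_ip)
      ct_ip <- ct_input - log(enr * mass_ip_ng / mass_input_ng, base = efficiency)
      out[[length(out) + 1L]] <- rec(gname, "input", ct_input, mass_input_ng)
      out[[length(out) + 1L]] <- rec(gname, "IP", ct_ip, mass_ip_ng)
    }
  } else if (type == "select") {
    if (any(true_values < 0 | true_values > 1)) {
      stop("SELECT fractions must lie in [0, 1]")
    }
    intercept <- 1 - select_slope
    ct_ref_100 <- ct_baseline
    # relative product r = efficiency^(ct - ct_ref_100) => ct = ct_ref + log_e(r)
    ct_of <- function(fr) {
      r <- intercept + select_slope * fr
      if (any(r <= 0)) stop("standard line gives non-positive relative product")
      ct_ref_100 + log(r, base = efficiency)
    }
    for (i in seq_along(standard_fractions)) {
      fr <- standard_fractions[i]
      out[[length(out) + 1L]] <-
        rec("standard", "SELECT", rep(ct_of(fr), n_rep),
            target = sprintf("std_%g", fr), primer = "select1")
      out[[length(out)]]$std_fraction <- fr
    }
    for (gname in names(true_values)) {
      out[[length(out) + 1L]] <-
        rec(gname, "SELECT", rep(ct_of(true_values[[gname]]), n_rep),
            primer = "select1")
      out[[length(out)]]$std_fraction <- NA_real_
    }
  } else {
    if (any(true_values <= 0)) stop("fold changes must be positive")
    tv <- true_values
    if (!"control" %in% names(tv)) tv <- c(tv, control = 1)
    for (gname in names(tv)) {
      ct_ref <- rep(ct_baseline + 5, n_rep)   # reference gene, constant
      ct_tgt <- rep(ct_baseline, n_rep) - log(tv[[gname]], base = efficiency)
      out[[length(out) + 1L]] <- rec(gname, "reference", ct_ref,
                                     target = "ref_gene", primer = "ref1")
      out[[length(out) + 1L]] <- rec(gname, "expression", ct_tgt)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- calibration-surface simulation ----------------------------------------

#' Simulate dose observations from a known bivariate cubic calibration
#'
#' For parameter-recovery studies of the integrated dose model: observed
#' doses are generated as `cubic(m, t)` times multiplicative log-normal noise
#' with unit mean, over a fixed grid of marker values and times. Noise sits
#' on the response (dose), so ordinary least squares re-fitted to these data
#' is unbiased for the planted coefficients; perturbing the marker values
#' instead would be an errors-in-variables design with a different estimand.
#'
#' @param coefficients Numeric vector of 10 cubic coefficients in the order
#'   documented in [cubic_basis()].
#' @param m_values Marker grid (default: the Ncoa4-like surface evaluated on
#'   the standard 6 nonzero doses at each default timepoint).
#' @param t_values Timepoint grid in days.
#' @param n_per_cell Replicates per (m, t) cell.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return Data frame in the `dose_response` schema with `true_dose` added.
#' @export
simulate_calibration_data <- function(coefficients,
                                      m_values = NULL,
                                      t_values = c(1, 3, 7, 14, 28),
                                      n_per_cell = 5, noise_cv = 0.1,
                                      seed = 1L) {
  if (length(coefficients) != 10L) {
    stop("coefficients must have length 10 (total-degree-3 bivariate basis)")
  }
  if (is.null(m_values)) {
    pars <- surface_params()
    grid <- expand.grid(dose = c(0.2, 0.5, 1, 2, 4, 6.5), t = t_values,
                        KEEP.OUT.ATTRS = FALSE)
    grid$m <- response_surface(grid$dose, grid$t, pars)
  } else {
    grid <- expand.grid(m = m_values, t = t_values, KEEP.OUT.ATTRS = FALSE)
  }
  cells <- grid[rep(seq_len(nrow(grid)), each = n_per_cell), , drop = FALSE]
  X <- cubic_basis(cells$m, cells$t)
  mu <- as.vector(X %*% coefficients)
  if (any(mu <= 0)) stop("planted cubic is non-positive on the grid; choose coefficients with positive response")
  set.seed(seed)
  dose <- mu * .lognormal_factor(length(mu), noise_cv)
  data.frame(subject_id = sprintf("cal%04d", seq_along(mu)),
             m6a_value = cells$m, m6a_scale = "relative",
             tpi_days = cells$t, dose_gy = dose, true_dose = mu,
             stringsAsFactors = FALSE)
}
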