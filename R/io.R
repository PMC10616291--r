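# Table schemas, validated delimited IO, pipeline configuration and the
# end-to-end pipeline driver with its run manifest.

.schemas <- list(
  array = list(
    required = c(probe_id = "character", gene_id = "character",
                 is_spikein = "logical", sample_id = "character",
                 ip_intensity = "numeric", sup_intensity = "numeric")),
  samples = list(
    required = c(sample_id = "character", dose_gy = "numeric",
                 tpi_days = "numeric", replicate = "integer")),
  ct = list(
    required = c(target_id = "character", primer_id = "character",
                 fraction = "character", ct = "numeric",
                 rna_mass_ng = "numeric", group_id = "character",
                 dose_gy = "numeric", tpi = "numeric", tpi_unit = "character")),
  dose_response = list(
    required = c(subject_id = "character", m6a_value = "numeric",
                 m6a_scale = "character", tpi_days = "numeric",
                 dose_gy = "numeric")),
  truth = list(
    required = c(gene_id = "character", pattern = "character",
                 effect = "numeric", timepoint = "numeric")),
  diff_calls = list(
    required = c(gene_id = "character", log2_fc = "numeric",
                 p_value = "numeric", bh_fdr = "numeric",
                 status = "character"))
)

#' Table schemas understood by the pipeline
#'
#' @return Named list; each entry gives the required columns and their types
#'   for one schema id (`array`, `samples`, `ct`, `dose_response`, `truth`,
#'   `diff_calls`).
#' @export
table_schemas <- function() .schemas

.coerce_column <- function(x, type, col, path) {
  if (type == "numeric" || type == "integer") {
    suppressWarnings(v <- as.numeric(x))
    bad <- which(!is.na(x) & x != "NA" & is.na(v))
    if (length(bad)) {
      stop(sprintf("%s: column '%s' must be numeric; offending line(s): %s",
                   path, col,
                   paste(utils::head(bad + 1L, 5), collapse = ", ")))
    }
    if (type == "integer") as.integer(round(v)) else v
  } else if (type == "logical") {
    v <- as.logical(x)
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad)) {
      stop(sprintf("%s: column '%s' must be logical; offending line(s): %s",
                   path, col,
                   paste(utils::head(bad + 1L, 5), collapse = ", ")))
    }
    v
  } else {
    as.character(x)
  }
}

#' Read a validated pipeline table
#'
#' Reads a tab-delimited table and validates it against a named schema:
#' missing required columns are an error naming the column, unknown columns
#' a warning, and type violations an error reporting the offending file
#' line numbers (header = line 1).
#'
#' @param path File path.
#' @param schema_id One of `names(table_schemas())`.
#' @return Data frame with columns coerced to the schema types (extra
#'   columns kept as read).
#' @export
read_table <- function(path, schema_id) {
  if (!schema_id %in% names(.schemas)) stop("unknown schema: ", schema_id)
  if (!file.exists(path)) stop("file not found: ", path)
  schema <- .schemas[[schema_id]]$required
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(df), names(schema))
  if (length(extra)) {
    warning(sprintf("%s: unknown column(s) kept as-is: %s", path,
                    paste(extra, collapse = ", ")))
  }
  for (col in names(schema)) {
    df[[col]] <- .coerce_column(df[[col]], schema[[col]], col, path)
  }
  df
}

#' Write a pipeline table, validating it against its schema
#'
#' @param x Data frame.
#' @param path Output path (tab-delimited, no quoting, no row names).
#' @param schema_id One of `names(table_schemas())`; `NULL` skips
#'   validation.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, schema_id = NULL) {
  if (!is.null(schema_id)) {
    if (!schema_id %in% names(.schemas)) stop("unknown schema: ", schema_id)
    schema <- .schemas[[schema_id]]$required
    missing <- setdiff(names(schema), names(x))
    if (length(missing)) {
      stop("missing required column(s): ", paste(missing, collapse = ", "))
    }
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration with study defaults
#'
#' All thresholds default to the study's stated values: differential-call
#' fold-change bounds 2 and 0.5 at p < 0.01; two sub-clusters per category
#' with fuzzifier 2; qPCR efficiency 2 with 2000/500 ng IP/input masses;
#' bivariate cubic dose model evaluated by 100-times-repeated five-fold CV
#' at cutoffs 0.2--6.5 Gy. The configuration round-trips losslessly through
#' JSON ([write_config()]/[read_config()]).
#'
#' @param seed Global seed; component seeds derive from it via
#'   [child_seed()].
#' @param n_genes,n_spikeins,noise_sd_log2 Epiarray simulation size/noise.
#' @param screen_effect,screen_n_consistent,screen_n_transient,screen_n_hypo
#'   Planted-signal settings for the screening stage.
#' @param fc_hi,fc_lo,alpha Differential-call thresholds.
#' @param n_clusters,fuzzifier Clustering settings.
#' @param efficiency,mass_ip_ng,mass_input_ng,select_mode qPCR settings.
#' @param model_kind,cubic_basis_kind,cv_k,cv_reps,cutoffs,stratify_by,clamp
#'   Dosimetry settings.
#' @param noise_cv Dose-response measurement noise CV.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_genes = 2000, n_spikeins = 10,
                            noise_sd_log2 = 0.15,
                            screen_effect = 4, screen_n_consistent = 60,
                            screen_n_transient = 40, screen_n_hypo = 30,
                            fc_hi = 2, fc_lo = 0.5, alpha = 0.01,
                            n_clusters = 2, fuzzifier = 2,
                            efficiency = 2, mass_ip_ng = 2000,
                            mass_input_ng = 500, select_mode = "ct",
                            model_kind = "bivariate_cubic",
                            cubic_basis_kind = "total_degree",
                            cv_k = 5, cv_reps = 100,
                            cutoffs = c(0.2, 0.5, 1, 2, 4, 6.5),
                            stratify_by = "group", clamp = FALSE,
                            noise_cv = 0.1) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path File path for the JSON configuration.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- pipeline_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base$seed <- as.integer(base$seed)
  structure(base, class = "pipeline_config")
}

# Order-insensitive content hash of the configuration (djb2 over its
# canonical JSON), recorded in the manifest.
.config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config)[order(names(config))],
                         auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (b in utf8ToInt(as.character(js))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

.fmt_num <- function(x) formatC(x, digits = 12, format = "g")

#' Run the full pipeline: simulate, quantify, screen, fit, evaluate
#'
#' Executes the end-to-end workflow under one configuration: simulates the
#' epiarray screening study and the dose-response study, quantifies m6A
#' levels, runs the two-stage screen, runs the MeRIP and SELECT qPCR
#' round-trips, fits the per-TPI quadratic and integrated cubic dose models
#' and evaluates cross-validated cutoff AUCs. All outputs are written as
#' delimited text/JSON under `out_dir` together with a machine-readable run
#' manifest (package version, seed, configuration and its hash) and a
#' human-readable summary. Outputs are a pure function of the
#' configuration: re-running with the same manifest reproduces them
#' byte-identically.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return List of class `pipeline_result` with the in-memory stage results
#'   and `files`, the paths written.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  files <- character(0)
  keep <- function(p) { files <<- c(files, p); p }

  # -- simulate ---------------------------------------------------------------
  sim <- stage("simulate", {
    screen_design <- study_design(doses = 6.5)
    planted <- planted_signals(n_consistent = config$screen_n_consistent,
                               n_transient = config$screen_n_transient,
                               n_hypo = config$screen_n_hypo,
                               effect = config$screen_effect)
    arr <- simulate_epiarray(screen_design, n_genes = config$n_genes,
                             n_spikeins = config$n_spikeins,
                             planted = planted,
                             noise_sd_log2 = config$noise_sd_log2,
                             seed = child_seed(config$seed, "epiarray"))
    dr <- simulate_dose_response(study_design(), surface_params(),
                                 noise_cv = config$noise_cv,
                                 seed = child_seed(config$seed, "dose_response"))
    ct_merip <- simulate_ct_data(c(control = 1, irradiated = 3),
                                 type = "merip", n_rep = 5, ct_sd = 0.1,
                                 efficiency = config$efficiency,
                                 mass_ip_ng = config$mass_ip_ng,
                                 mass_input_ng = config$mass_input_ng,
                                 seed = child_seed(config$seed, "ct"))
    ct_select <- simulate_ct_data(c(sham = 0.1, day7 = 0.35, day14 = 0.55),
                                  type = "select", n_rep = 3, ct_sd = 0.1,
                                  seed = child_seed(config$seed, "ct") + 1L)
    list(array = arr, dose_response = dr, ct_merip = ct_merip,
         ct_select = ct_select, planted = planted)
  })
  write_table(sim$dose_response[, c("subject_id", "m6a_value", "m6a_scale",
                                    "tpi_days", "dose_gy")],
              keep(file.path(out_dir, "dose_response.tsv")), "dose_response")
  write_table(sim$array$truth, keep(file.path(out_dir, "truth.tsv")), "truth")
  write_table(sim$ct_merip, keep(file.path(out_dir, "ct_merip.tsv")), "ct")

  # -- quantify-array + screen ------------------------------------------------
  screen <- stage("screen", {
    mat <- m6a_level_matrix(sim$array)
    screen_two_stage(mat, fc_hi = config$fc_hi, fc_lo = config$fc_lo,
                     alpha = config$alpha, n_clusters = config$n_clusters,
                     fuzzifier = config$fuzzifier, seed = config$seed)
  })
  cat_df <- data.frame(gene_id = names(screen$categories),
                       category = unname(screen$categories))
  write_table(cat_df, keep(file.path(out_dir, "categories.tsv")))
  cand_df <- data.frame(gene_id = screen$candidates$genes,
                        provenance = paste(screen$candidates$provenance,
                                           collapse = "+"))
  write_table(cand_df, keep(file.path(out_dir, "candidates.tsv")))
  for (tp in names(screen$diff_calls)) {
    d <- screen$diff_calls[[tp]]
    d$log2_fc <- .fmt_num(d$log2_fc); d$p_value <- .fmt_num(d$p_value)
    d$bh_fdr <- .fmt_num(d$bh_fdr)
    write_table(d, keep(file.path(out_dir,
                                  sprintf("diff_calls_day%s.tsv", tp))))
  }

  # -- qPCR -------------------------------------------------------------------
  qpcr <- stage("merip", {
    enr <- merip_workflow(sim$ct_merip, efficiency = config$efficiency)
    rel <- relative_m6a_level(enr$enrichment[enr$group_id == "irradiated"],
                              enr$enrichment[enr$group_id == "control"])
    sel <- select_workflow(sim$ct_select, mode = config$select_mode)
    list(enrichments = enr, relative = rel, select = sel)
  })
  enr_out <- qpcr$enrichments
  enr_out$enrichment <- .fmt_num(enr_out$enrichment)
  write_table(enr_out, keep(file.path(out_dir, "merip_enrichment.tsv")))
  jsonlite::write_json(
    list(slope = qpcr$select$curve$slope,
         intercept = qpcr$select$curve$intercept,
         r2 = qpcr$select$curve$r2,
         ct_ref_100 = qpcr$select$curve$ct_ref_100,
         mode = qpcr$select$curve$mode,
         estimates = qpcr$select$estimates),
    keep(file.path(out_dir, "select_curve.json")),
    auto_unbox = TRUE, digits = NA)

  # -- fit-dose ---------------------------------------------------------------
  dose <- stage("fit_dose", {
    pts <- sim$dose_response
    cubic <- fit_bivariate_cubic(pts, basis = config$cubic_basis_kind)
    per_tpi <- lapply(split(pts, pts$tpi_days), fit_per_tpi_quadratic)
    list(cubic = cubic, per_tpi = per_tpi)
  })
  jsonlite::write_json(
    list(kind = dose$cubic$kind, basis = dose$cubic$basis,
         coefficient_order = names(dose$cubic$coefficients),
         coefficients = unname(dose$cubic$coefficients),
         r2 = dose$cubic$r2, n_train = dose$cubic$n_train,
         seed = config$seed),
    keep(file.path(out_dir, "dose_model.json")),
    auto_unbox = TRUE, digits = NA)
  per_tpi_df <- data.frame(
    tpi_days = as.numeric(names(dose$per_tpi)),
    b0 = .fmt_num(sapply(dose$per_tpi, function(m) m$coefficients[1])),
    b1 = .fmt_num(sapply(dose$per_tpi, function(m) m$coefficients[2])),
    b2 = .fmt_num(sapply(dose$per_tpi, function(m) m$coefficients[3])),
    r2 = .fmt_num(sapply(dose$per_tpi, function(m) m$r2)))
  write_table(per_tpi_df, keep(file.path(out_dir, "per_tpi_models.tsv")))
  pred <- predict_dose(dose$cubic, sim$dose_response$m6a_value,
                       sim$dose_response$tpi_days, clamp = config$clamp,
                       interval = TRUE)
  pred_fmt <- pred
  for (nm in c("dose", "lwr", "upr")) pred_fmt[[nm]] <- .fmt_num(pred_fmt[[nm]])
  pred_out <- cbind(sim$dose_response[, c("subject_id", "dose_gy")], pred_fmt)
  write_table(pred_out, keep(file.path(out_dir, "predictions.tsv")))

  # -- evaluate ---------------------------------------------------------------
  roc <- stage("evaluate", {
    lapply(config$cutoffs, function(cut) {
      evaluate_cutoff(sim$dose_response, cut,
                      model_spec = config$model_kind,
                      basis = config$cubic_basis_kind,
                      cv = list(k = config$cv_k, reps = config$cv_reps,
                                seed = child_seed(config$seed, "cv"),
                                stratify_by = config$stratify_by))
    })
  })
  roc_df <- data.frame(
    cutoff_gy = sapply(roc, `[[`, "cutoff_gy"),
    apparent_auc = .fmt_num(sapply(roc, `[[`, "auc")),
    cv_mean_auc = .fmt_num(sapply(roc, `[[`, "cv_mean_auc")),
    cv_sd = .fmt_num(sapply(roc, `[[`, "cv_sd")),
    k = config$cv_k, reps = config$cv_reps)
  write_table(roc_df, keep(file.path(out_dir, "roc_cutoffs.tsv")))

  # -- manifest + summary -----------------------------------------------------
  manifest <- list(package = "radm6a",
                   version = as.character(utils::packageVersion("radm6a")),
                   seed = config$seed, config = unclass(config),
                   config_hash = .config_hash(config),
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary_lines <- c(
    "m6A radiation biodosimetry pipeline run",
    sprintf("seed: %d  config hash: %s", config$seed, manifest$config_hash),
    sprintf("screen: %d genes, %d candidates (planted consistent-hyper: %d)",
            config$n_genes, length(screen$candidates$genes),
            config$screen_n_consistent),
    sprintf("thresholds: FC > %g or < %g, p < %g", config$fc_hi,
            config$fc_lo, config$alpha),
    sprintf("MeRIP relative m6A level (irradiated vs control): %.4f",
            qpcr$relative$fold),
    sprintf("SELECT curve slope %.4f intercept %.4f r2 %.4f",
            qpcr$select$curve$slope, qpcr$select$curve$intercept,
            qpcr$select$curve$r2),
    sprintf("integrated cubic model R2: %.4f (n = %d)", dose$cubic$r2,
            dose$cubic$n_train),
    sprintf("cutoff %g Gy: apparent AUC %.4f, CV mean AUC %.4f (sd %.4f)",
            sapply(roc, `[[`, "cutoff_gy"), sapply(roc, `[[`, "auc"),
            sapply(roc, `[[`, "cv_mean_auc"), sapply(roc, `[[`, "cv_sd")))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  structure(list(sim = sim, screen = screen, qpcr = qpcr, dose = dose,
                 roc = roc, manifest = manifest,
                 files = c(files, file.path(out_dir, c("manifest.json",
                                                       "summary.txt")))),
            class = "pipeline_result")
}

#' Re-run a pipeline from a written manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param out_dir Output directory for the re-run.
#' @return A `pipeline_result`.
#' @export
run_from_manifest <- function(manifest_path, out_dir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- pipeline_config()
  for (nm in names(man$config)) cfg[[nm]] <- man$config[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  run_pipeline(cfg, out_dir)
}
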