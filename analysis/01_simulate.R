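#!/usr/bin/env Rscript
# Stage 1 — generate the study inputs.
#
# Simulates (i) a two-arm (sham vs 6.5 Gy) epiarray screening study over the
# five-timepoint course with planted hyper/hypo transcripts, (ii) the full
# 7-dose x 5-timepoint Ncoa4-like dose-response study used for dose
# reconstruction, and (iii) MeRIP and SELECT qPCR Ct tables. Everything is
# written as delimited text under results/inputs/.

suppressPackageStartupMessages(library(radm6a))
seed <- 1L
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

planted <- planted_signals(n_consistent = 60, n_transient = 40, n_hypo = 30,
                           effect = 4)
arr <- simulate_epiarray(study_design(doses = 6.5), n_genes = 2000,
                         n_spikeins = 10, planted = planted,
                         noise_sd_log2 = 0.15,
                         seed = child_seed(seed, "epiarray"))
write_table(epiarray_long(arr), file.path(out, "array.tsv"), "array")
write_table(arr$samples[, c("sample_id", "dose_gy", "tpi_days", "replicate")],
            file.path(out, "samples.tsv"), "samples")
write_table(arr$truth, file.path(out, "truth.tsv"), "truth")

dr <- simulate_dose_response(study_design(), surface_params(), noise_cv = 0.1,
                             seed = child_seed(seed, "dose_response"))
write_table(dr[, c("subject_id", "m6a_value", "m6a_scale", "tpi_days",
                   "dose_gy")],
            file.path(out, "dose_response.tsv"), "dose_response")

ct_merip <- simulate_ct_data(c(control = 1, irradiated = 3), type = "merip",
                             n_rep = 5, ct_sd = 0.1,
                             seed = child_seed(seed, "ct"))
write_table(ct_merip, file.path(out, "ct_merip.tsv"), "ct")
ct_select <- simulate_ct_data(c(sham = 0.1, day7 = 0.35, day14 = 0.55),
                              type = "select", n_rep = 3, ct_sd = 0.1,
                              seed = child_seed(seed, "ct") + 1L)
write_table(ct_select, file.path(out, "ct_select.tsv"), "ct")

cat(sprintf("simulated: %d-gene array over %d samples; %d dose-response points; %d Ct records\n",
            nrow(arr$truth), nrow(arr$samples), nrow(dr),
            nrow(ct_merip) + nrow(ct_select)))
cat(sprintf("planted: %d consistent-hyper, %d transient-hyper, %d hypo (x%g)\n",
            60, 40, 30, 4))
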