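#!/usr/bin/env Rscript
# Pool the survey waves by denormalizing weights against the population
# totals, exclude internally inconsistent FGM reports, and redistribute
# approximate "during infancy" answers over the per-survey distribution of
# precise early-childhood ages (fractional mode). Writes the analysis-ready
# records and the exclusion/anchor audit tables.

suppressMessages(library(fgmq))
out_dir <- "results"

md <- read_microdata(file.path(out_dir, "microdata.csv"))
stopifnot(nrow(md$rejections) == 0)
totals <- read_population_totals(file.path(out_dir, "totals.csv"))

pooled <- denormalize(md$records, totals)
write_table(pooled$provenance, file.path(out_dir, "pooling_provenance.csv"))
message("per-survey denormalized weight sums (person units):")
for (i in seq_len(nrow(pooled$provenance))) {
  message(sprintf("  %s: %.0f", pooled$provenance$survey_id[i],
                  pooled$provenance$weight_denorm_sum[i]))
}

exc <- exclude_inconsistent(pooled$records)
message(sprintf("excluded %d of %d records with age at FGM above current age",
                exc$audit$n_excluded_inconsistent, exc$audit$n_input))
write_table(exc$audit$per_survey, file.path(out_dir, "exclusions.csv"))

plan <- build_anchor_distribution(exc$records)
anchors <- data.frame(survey_id = rownames(plan$weights),
                      plan$weights, check.names = FALSE)
write_table(anchors, file.path(out_dir, "anchor_distributions.csv"))

rec <- redistribute_infancy(exc$records, plan, mode = "fractional")
message(sprintf("redistributed %d infancy-coded answers over ages 0..%d",
                attr(rec, "n_redistributed"), plan$max_age))

# analysis-ready records, fractional rows included
write_microdata_cols <- c("survey_id", "module", "current_age",
                          "birth_cohort", "fgm_status", "age_at_fgm",
                          "age_fgm_infancy", "education", "dob_complete",
                          "stratum_id", "cluster_id", "weight_norm", "n_rep",
                          "weight_denorm")
write_table(rec[, write_microdata_cols],
            file.path(out_dir, "analysis_records.csv"))
message("wrote analysis_records.csv (", nrow(rec), " rows)")
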