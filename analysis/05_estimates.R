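#!/usr/bin/env Rscript
# Composition tables (sample by survey/module, education and DoB
# completeness, cohorts, age-at-FGM bands) and weighted median age at FGM
# by birth cohort and module, on the synthetic pooled records; then the
# same percentage arithmetic on the published Senegal DHS counts shipped
# with the package.

suppressMessages(library(fgmq))
out_dir <- "results"
rec <- utils::read.csv(file.path(out_dir, "analysis_records.csv"))

tabs <- composition_tables(rec)
write_table(tabs$by_survey, file.path(out_dir, "table1.csv"))
write_table(tabs$composition, file.path(out_dir, "table2.csv"))
write_table(tabs$by_cohort, file.path(out_dir, "table3.csv"))
write_table(tabs$age_at_fgm, file.path(out_dir, "table4.csv"))

t6 <- median_table(rec)
write_table(t6, file.path(out_dir, "table6.csv"))
message("median age at FGM by cohort (both / women / daughters):")
print(t6, row.names = FALSE)

t4 <- tabs$age_at_fgm
message("age-at-FGM bands, per cent of FGM-positive:")
print(t4[, c("module", "band", "pct")], row.names = FALSE)

# published-count arithmetic: printed percentages from printed counts
pub <- published_counts("by_survey")
stopifnot(all(percent_int(pub$n_fgm, pub$n_obs) == pub$printed_pct))
tot <- pub[pub$survey == "total", ]
message(sprintf(
  "published pooled prevalence: women %d%% (%d/%d), daughters %d%% (%d/%d)",
  percent_int(tot$n_fgm[tot$module == "women"],
              tot$n_obs[tot$module == "women"]),
  tot$n_fgm[tot$module == "women"], tot$n_obs[tot$module == "women"],
  percent_int(tot$n_fgm[tot$module == "daughters"],
              tot$n_obs[tot$module == "daughters"]),
  tot$n_fgm[tot$module == "daughters"], tot$n_obs[tot$module == "daughters"]))
message("wrote table1.csv ... table6.csv")
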