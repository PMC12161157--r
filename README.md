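# fgmq — data quality of self- vs proxy-reported FGM survey data

Household surveys measure female genital mutilation (FGM) through two
instruments: women aged 15–49 report on themselves (self-report, often
decades after the event), and mothers report on their living daughters
under 15 (proxy report of recent events). Trend estimates of the *age at
FGM* splice the two streams — older birth cohorts are seen only through
the women's module, recent cohorts only through the daughters' — so any
systematic quality difference between them distorts apparent trends.
`fgmq` is an R package plus analysis workflow for quantifying that
difference on pooled DHS-style microdata, for survey methodologists and
analysts of harmful-practice indicators.

## What it computes

* **Pooling**: multi-survey weight denormalization,
  `w_i^denorm = w_i · N_s / Σ_{j∈s} w_j`, so each wave's weights sum to
  its eligible population `N_s` (women 15–49 + girls 0–14 in the survey
  year).
* **Preprocessing**: exclusion of records with age at FGM above current
  age; redistribution of approximate "during infancy" answers over each
  survey's distribution of precise responses at ages 0–5 (deterministic
  fractional mode, or seeded stochastic mode).
* **Completeness**: weighted share of FGM-positive records with missing
  age at FGM, by age, module, and survey.
* **Age heaping**: the smooth-transition index at target age *a* ∈
  {5, 10, 15}, `ratio(a) = C(a) / [(C(a−1) + C(a+1)) / 2]` on weighted
  counts `C(·)` — exactly 1 under local linearity (Whipple/Myers indices
  do not apply below age 10).
* **Completeness regression**: design-based logistic regression
  (weighted IRLS; Taylor-linearized stratified-cluster sandwich
  variance; Wald-*t* CIs at df = #PSUs − #strata) of age-reported vs
  missing on survey, module, age, education and date-of-birth
  completeness.
* **Medians**: lower weighted median age at FGM by birth cohort ×
  module.
* **Synthetic data**: a two-stage cluster-sample generator with a known
  truth layer (heaping probability, infancy coding, missingness
  log-odds) so every stage has parameter-recovery tests; its
  `preset_paper_like()` configuration encodes the pooled Senegal DHS
  2005–2023 study conditions (prevalence 34%/20%, missing age 6%/1%,
  women-vs-daughters completeness OR 0.16, heaping ratio 2.5 at age 5).

See `vignettes/fgm-data-quality.Rmd` for the estimators and the
reasoning behind every default.

## Worked example

```r
library(fgmq)
cfg <- preset_paper_like()                       # 4 waves, ~7700 respondents
sim <- generate_microdata(cfg, seed = 1)
rec <- denormalize(sim$records, config_population_totals(cfg))$records
rec <- exclude_inconsistent(rec)$records
plan <- build_anchor_distribution(rec)
rec <- redistribute_infancy(rec, plan, mode = "fractional")

completeness_profile(rec, group_by = "module")
#>      module n_fgm_yes share_missing_age undefined
#> 1 daughters   2095999       0.009832584     FALSE
#> 2     women   4985977       0.057251652     FALSE

heaping_index(rec)[, c("module", "age", "ratio")]
#>      module age    ratio
#> 1 daughters   5 1.698585
#> 2 daughters  10 0.000000
#> 3     women   5 2.213392
#> 4     women  10 1.947564
#> 5     women  15 2.338600

completeness_model(rec, terms = c("module", "age"))$fit
#> Design-based logistic regression
#>   n = 4933 (dropped 0), PSUs = 192, strata = 48, df = 144
#>         term estimate    se      or  ci_low ci_high
#>  (Intercept)  4.66000 0.414 106.000 46.5000 240.000
#>  modulewomen -1.65000 0.470   0.193  0.0762   0.488
#>          age -0.00653 0.011   0.993  0.9720   1.020
```

Reading the output: women's self-reports are missing the age at FGM
about six times as often as daughters' proxy reports (5.7% vs 1.0%), and
heap at age 5 about twice the smooth-transition expectation — both
distortions injected by the generator (truth: missingness OR 0.16,
closed-form heaping ratio 2.5) and recovered here at a small sample. The
module odds ratio 0.193 (95% CI 0.076–0.488) covers the generated truth
and excludes 1.

`median_table(rec)` shows the consequence: cohort medians read off the
pooled data drop from 2–3 years (cohorts observed through women's
self-reports) to 0–1 years (cohorts observed through daughters' proxy
reports) even though each module's own median is flat — the splice, not
the practice, creates the apparent trend.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end on synthetic
data and write all tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # microdata + truth + totals
Rscript analysis/02_pool_preprocess.R   # pooling, exclusions, redistribution
Rscript analysis/03_quality_metrics.R   # completeness profile, heaping index
Rscript analysis/04_completeness_model.R# design-based regression (table5)
Rscript analysis/05_estimates.R         # composition tables, cohort medians
```

`run_pipeline()` performs the same sequence in one call and writes a
manifest with per-table MD5 digests; identical config and seed give
byte-identical outputs.

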