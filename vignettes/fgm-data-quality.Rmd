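---
title: "Assessing self- versus proxy-reported survey data on female genital mutilation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing self- versus proxy-reported survey data on female genital mutilation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgmq)
```

## The measurement problem

Household surveys in the DHS family collect female genital mutilation
(FGM) data through two instruments. Women aged 15–49 report on
themselves — FGM status and, if affected, the age at which it happened —
often decades after the event. Mothers additionally report on each of
their living daughters under 15. The two streams measure the same
practice with different error structures: self-reports rely on long
recall of early childhood, proxy reports describe recent events
witnessed by the respondent. Because trend estimates of the *age at FGM*
splice the two streams (older birth cohorts are observed only through
the women's module, recent cohorts only through the daughters'), any
systematic quality difference between them propagates into apparent
trends.

`fgmq` implements the full quality-assessment pipeline for such data:

1. **pooling** of several survey waves by weight denormalization;
2. **preprocessing** — exclusion of internally inconsistent reports and
   redistribution of approximate "during infancy" answers;
3. **completeness profiling** of age-at-FGM reporting;
4. a **smooth-transition age-heaping index** at ages 5, 10 and 15;
5. a **design-based logistic regression** for reporting completeness;
6. **weighted median** age at FGM by birth cohort and module;

together with a **synthetic microdata generator** whose truth layer
makes every stage testable without access to the restricted survey
micro-files.

## Pooling by weight denormalization

Each survey ships weights normalized to mean 1 within the wave, so
stacked waves would contribute in proportion to their *sample* sizes.
Pooling instead rescales each wave to person units: with normalized
weights $w_i$ in survey $s$ and eligible population $N_s$ (women 15–49
plus girls 0–14 in the survey year, a config input),

$$w_i^{\mathrm{denorm}} = w_i \cdot \frac{N_s}{\sum_{j \in s} w_j}.$$

Each wave's denormalized weights then sum exactly to $N_s$, so waves
influence pooled estimates in proportion to the populations they
represent. The rescaling preserves relative weights within a wave and is
invariant to any positive rescaling of a wave's weights. By default one
combined total per survey is used; where per-module eligible populations
are available, `denormalize(..., by_module = TRUE)` rescales the women's
and daughters' modules separately. The combined default reflects that
both modules sample from the same eligible population definition; the
choice matters only when the two modules' weight sums are far from
proportional to their population shares.

## Preprocessing

**Inconsistent reports.** Records whose age at FGM exceeds the
respondent's current age are contradictory and are excluded (equality is
allowed). The filter runs *before* redistribution so that impossible
numeric answers never contaminate the anchor distributions; approximate
and missing answers cannot be inconsistent and are always retained.

**Infancy redistribution.** Women may answer only that FGM happened
"during infancy". These answers are information, not noise: they bound
the age from above. Following the convention that infancy spans ages
0–5 completed years (`max_age` is configurable; the interpretation of
"infancy" is an assumption, not a measured fact), each survey's precise
women's-module responses at ages 0–5 define an *anchor distribution*,
and every infancy-coded record is redistributed over it. Two modes:

* `fractional` (default): the record becomes six fractional-weight
  copies at ages 0–5 with weights multiplied by the anchor weights.
  Deterministic; conserves weighted and unweighted mass exactly. The
  row-multiplicity column `n_rep` carries the fractions so that
  unweighted counts remain conserved too.
* `stochastic`: one age is drawn per record from the anchor. Keeps
  records atomic (useful when downstream code needs integer ages) at
  the cost of Monte-Carlo noise; seeded, hence reproducible.

A survey with no precise early-age responses falls back to the pooled
all-survey anchor with a warning. The anchor uses denormalized weights
when pooling has run, raw counts otherwise, keeping it consistent with
the pooled estimand.

## Completeness

Completeness is the weighted share of FGM-positive records whose age at
FGM is reported; an infancy code counts as reported, since it is
retained and redistributed rather than discarded. Profiles by age,
module, age-by-module and survey-by-module are available; the
age-by-module profile makes the discontinuity at the module boundary
(daughters aged 14 versus women aged 15) directly visible.

## The smooth-transition heaping index

Classic digit-preference indices (Whipple, Myers) need age ranges above
10 and cannot be used here, where most FGM occurs before age 5. The
package instead uses a local index: for target age $a \in \{5, 10, 15\}$
with weighted counts $C(\cdot)$,

$$\mathrm{ratio}(a) = \frac{C(a)}{\bigl(C(a-1) + C(a+1)\bigr)/2}.$$

Under any distribution locally linear across $\{a-1, a, a+1\}$ the ratio
is exactly 1; it is invariant to global weight rescaling. Values above 1
measure the pile-up at round ages relative to the smooth transition from
adjacent ages. The daughters' module never emits a row at age 15 (its
ages end at 14). Note that the index reflects genuine curvature as well
as heaping: a steeply falling true age distribution yields ratios above
1 at age 5 even without digit preference, which is why interpretation
rests on the women-versus-daughters *contrast* rather than the absolute
level.

The generator's heaping model gives the index a closed form: if mass at
ages within $\pm 2$ years of a multiple of 5 snaps to it with
probability $p_h$, the displaced distribution is computable analytically
(`heaped_pmf()`), and `heap_prob_for_ratio()` inverts the implied ratio
in $p_h$ by root finding. On a locally flat distribution the ratio at 5
is $(1 + 4p_h)/(1 - p_h)$.

## Design-based logistic regression

The completeness outcome (1 = age reported, 0 = missing, defined on
FGM-positive records) is regressed on survey wave, module, current age
(continuous), education (mother's education for daughters) and
date-of-birth completeness, with treatment coding and references
education = none, earliest survey, module = daughters, DoB = imputed.
Records missing a covariate are dropped listwise and counted; the rare
"other" education level is dropped with them, matching the published
table layout for this analysis and avoiding a degenerate cell.

Point estimates solve the weighted score equations
$\sum_i w_i (y_i - \mu_i)\, x_i = 0$ by IRLS (convergence when the
maximum absolute score falls below $10^{-8}$ or the relative deviance
change below $10^{-10}$; 50 iterations at most; an absolute-score
criterion alone would be meaningless under population-scale weights,
hence the deviance alternative). Variance is by Taylor linearization:
score residuals $u_i = w_i (y_i - \mu_i) x_i$ are summed to PSU totals
$u_{hj}$, centered within strata, and combined as

$$\widehat{V}_{\mathrm{score}} = \sum_h \frac{n_h}{n_h - 1}
  \sum_j (u_{hj} - \bar u_h)(u_{hj} - \bar u_h)^{\top}, \qquad
  \widehat{V}(\hat\beta) = A^{-1} \widehat{V}_{\mathrm{score}} A^{-1},$$

with $A = X^{\top} \mathrm{diag}\{w_i \mu_i (1-\mu_i)\} X$. Confidence
intervals are Wald on the log-odds scale with a $t$ quantile at the
design degrees of freedom (#PSUs − #strata), the standard convention of
complex-survey software. Strata containing a single PSU cannot
contribute a variance term and are skipped with a warning; no finite
population correction is applied (no sampling-fraction information is
assumed). The regression uses denormalized pooled weights by default —
the same estimand as every other pipeline stage — since point estimates
are invariant to per-survey weight scale only when the model is
saturated in survey, which this model (survey main effects) nearly is.

## Weighted medians

The median age at FGM per birth cohort uses the *lower weighted median*:
the smallest value whose cumulative weight reaches half the total. With
equal weights this is the conventional lower median; ties go to the
smaller value. Ages are completed years, so medians are integers, which
matches how such tables are printed. Cells with no FGM-positive mass are
`NA` — in particular cohorts observed only through one module.

## The synthetic generator

`generate_microdata()` emulates the structure the pipeline consumes:

* **Design**: per survey, $H$ strata × $m$ PSUs × $\bar n$ respondents.
  PSU frame sizes vary log-normally (σ = 0.35), so two-stage inclusion
  probabilities $\pi = (m/M)(\bar n/N_{hj})$ and hence weights vary
  across PSUs; weights are normalized to mean 1 per survey, exactly as
  the real files ship them.
* **Modules and demographics**: respondents are women (15–49, uniform)
  or daughters (0–14, uniform) with a configurable mix; birth cohorts
  derive from survey year minus age (pre-1970 births pool into the
  oldest decade bin); daughters copy the education of a randomly chosen
  woman in their cluster, standing in for their mother.
* **FGM truth**: per-module prevalence; true age at FGM drawn from a
  configurable distribution over ages 0–17, truncated at the
  respondent's current age.
* **Reporting layer**, applied in the order *heap → infancy-code →
  missingness*, by default to the women's module only (the self- versus
  proxy-report contrast being the object of study, not an assumption
  under test): ages within ±2 years of a multiple of 5 snap to it with
  probability $p_h$; reported ages ≤ 5 become the infancy code with
  probability $p_i$; the age is then missing with probability
  $1 - \mathrm{logit}^{-1}(\alpha + \beta_{\mathrm{women}} + \gamma\,
  \mathrm{age})$.

The truth table records every FGM-positive record's pre-distortion age,
enabling parameter-recovery tests for each stage.

### The paper-conditions preset

`preset_paper_like()` fixes the generator at the study conditions the
pooled Senegal DHS composition implies: prevalence 34% (women) and 20%
(daughters); daughters' completeness 99% with a women-versus-daughters
odds ratio of complete reporting of 0.16 (giving ≈ 6% missing among
women); 45% of FGM-positive women answering "during infancy" (published
analyses report 35–60% across waves); education 62% none / 20% primary /
16% secondary; 64% of dates of birth imputed; and a women's heap
probability solved by root finding so the displacement closed form gives
a smooth-transition ratio of 2.5 at age 5 — about $p_h = 0.208$ for the
default age distribution. The default true age-at-FGM distributions
place roughly a fifth (women) and half (daughters-as-observed) of cases
in the first year of life, falling steeply thereafter, consistent with a
setting where FGM happens mostly in early childhood. These defaults are
fixed study conditions, not tuning knobs.

Because infancy coding strikes ages 0–5 uniformly, the surviving precise
responses keep the true 0–5 shape in expectation, so redistribution is
consistent: the reconstructed early-age distribution converges to the
truth as samples grow, and the heaping ratio measured after
redistribution converges to the closed-form value implied by $p_h$.

### What the generator does not emulate

Households and fertility (daughters are linked to mothers only through
shared clusters and copied education); geographic prevalence gradients;
survey nonresponse and weight adjustments beyond inverse inclusion
probability; correlation of reporting errors within households; and any
dependence of heaping or missingness on unobserved traits. Passing tests
therefore demonstrate that the *estimators* recover known truth under a
faithful design, not that the substantive Senegal findings would
replicate on the restricted microdata.

## Numerical and testing choices

* Percent tables round halves away from zero, matching printed survey
  tables.
* The fractional redistribution keeps rows with zero fraction out of
  the output; conservation is exact to floating-point addition
  (tolerance $10^{-9}$ in tests).
* Degenerate heaping cells (expected = 0) report `Inf` with a flag
  rather than failing.
* Simulation sizes in the tests were chosen to make Monte-Carlo noise
  small against the tested margins: 50 000 FGM ages for heaping checks
  (3-standard-error bands), 100 000 draws for total-variation
  comparisons (< 0.02 margin), and 500 replicates of n = 20 000 for
  confidence-interval coverage (binomial 95% band 92–98%).
* The coverage study fixes the module odds ratio at 0.16 but uses a
  moderate completeness baseline (logit 2, ≈ 88% complete among
  daughters) rather than the preset's 99%: at 99% a 20 000-respondent
  replicate yields only tens of incomplete daughter records, a regime
  where Wald intervals are known to undercover regardless of the
  variance estimator. The baseline is a free intercept choice; the
  effect under test is unchanged.

## Limitations

The index at age 15 straddles the module boundary (counts at 14 come
mostly from proxy reports, at 16 only from women), so its level mixes
measurement regimes. The smooth-transition index cannot separate true
local curvature from digit preference at a single age; only the
module contrast is interpretable. Fractional redistribution produces
non-integer "counts" in unweighted tables (stochastic mode avoids this).
And the design-based variance assumes at least two PSUs per stratum;
lonely PSUs are skipped conservatively rather than recentered.
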