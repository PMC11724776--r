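---
title: "Methods: scoring, FFQ mapping, agreement statistics and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, FFQ mapping, agreement statistics and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(med4child)
```

## The scoring model

The MED4CHILD screener asks 18 questions about a child's habitual diet and
awards one point per satisfied criterion, for a total of 0–18. Unlike
purely qualitative indices, every quantitative item has an explicit serving
size (50–80 g of vegetables, 15–20 g of nuts, a 10 mL tablespoon of olive
oil, a 200 mL glass of a sugary drink), so the package stores answers as
*quantities* in the item's unit and applies the thresholds itself:

```{r}
reg <- med4child_registry()
reg[c("item_id", "unit", "direction", "threshold",
      "serving_g_low", "serving_g_high")]
```

Three comparison directions exist. Items 2–9 and 11 reward consumption
(`at_least`: point iff answer ≥ threshold), items 12–18 reward restraint
(`less_than`: point iff answer < threshold, so zero consumption always
scores), and items 1 and 10 are binary preferences (olive oil as the main
culinary fat; white meat preferred over red). Item 3 carries a
sub-condition — at least one raw/salad vegetable serving per week — which
is ANDed with the main threshold whenever a sub-answer (`q03_raw`) is
present.

Two registry entries are configurable because the instrument's printed
criteria leave latitude:

* **Item 7 (legumes)** is printed as "2–3 or more servings a week"; the
  registry uses the lower bound (≥ 2) by default, with
  `item7_threshold = 3` available for the stricter reading.
* **Item 11 (sofrito)** has no criterion in the published item table; the
  default (≥ 2 servings/week) is the analogue of the corresponding item in
  the adult 14-item screener, and the item can always be excluded via
  `items_used`.

The total is categorised into the study's quartile bands — Q1 0–8, Q2
9–11, Q3 12–13, Q4 14–18, i.e. `cutpoints = c(9, 12, 14)` — or into
empirical sample quartiles on request, and dichotomised at ≥ 10 points
into low/high adherence (the cutoff is a parameter).

**Missing answers are preserved as missing**, never scored 0. The default
`complete_case` policy flags any record missing a used item as excluded
(the analysis set's behaviour); `score_zero` is available for descriptive
work. Whether the ≥ 10 dichotomy of the *total* should be computed over 18
or 17 items when comparing against the FFQ is genuinely open; the
validation report defaults to `total_mode = "matched_items"` (both totals
over the same 17 items, the comparison that isolates instrument
disagreement from item coverage) and offers `"all_items"`.

## Deriving the reference score from an FFQ

The reference instrument is a semi-quantitative FFQ whose output is
grams/day per food group, optionally with eating occasions/week in
`freq_<group>` columns. The mapping (`ffq_mapping()`) converts intakes to
servings — `servings = g/day ÷ g/serving`, ×7 for weekly criteria — and
applies the *same* registry criteria. Choices made here, all editable in
the shipped YAML:

* Serving-size **ranges collapse to midpoints** (65 g vegetables, 55 g
  fish, 17.5 g nuts): without item-level FFQ data there is no basis for
  anything finer, and the midpoint is unbiased under a symmetric spread.
* **Olive oil**: 10 mL/tablespoon × 0.92 g/mL = 9.2 g, since FFQ intakes
  are in grams.
* **Frequency-style items** (5, 12, 15–18) use `freq_<group>` occasions
  per week when present and fall back to gram-based servings otherwise;
  the preference item 10 compares white-meat vs red-meat frequency
  (white > red ⇒ point).
* **Item 1** uses a binary `olive_oil_main_fat` column when the FFQ
  recorded which culinary fat is mainly used — the natural way such an
  instrument captures the question — falling back to comparing olive-oil
  and butter/cream grams.
* **Item 3's raw/salad sub-condition is not separable** in group-level FFQ
  data; the main threshold alone decides the FFQ-derived point. This is a
  documented mapping limitation, not a scoring rule.
* **Item 11 (sofrito) is not derivable**: a slow-cooked mix of small
  vegetable portions has no food-group counterpart. Validation therefore
  covers 17 of the 18 items.

A structural property worth stating: a questionnaire response and an FFQ
record expressing the same underlying servings yield identical item
vectors for all 17 derivable items (the round-trip tests exercise exactly
this), so any disagreement measured on real data is attributable to the
instruments, not the arithmetic.

## Agreement statistics

Each item is summarised by the 2×2 cross-classification of the
administered indicator against the FFQ-derived one.

* **Percent agreement** is (a + d)/n — the raw fraction of concordant
  children. (Published validation tables of this kind sometimes print an
  "agreement" column on another, unstated scale; this package reports the
  standard proportion and nothing else.)
* **Cohen's kappa** is (P₀ − Pₑ)/(1 − Pₑ) with Pₑ from the marginal
  products. The 95% CI uses the large-sample two-rater, two-category
  variance of Fleiss–Cohen–Everitt; the interpretation bands are ≤ 0.20
  weak, 0.21–0.40 fair, 0.41–0.60 moderate, 0.61–0.80 substantial,
  > 0.80 almost perfect.
* **Degenerate items** (a method constant in the sample) make Pₑ = 1 and
  kappa undefined; the row is retained with an `undefined` flag rather
  than coerced to 0, because "no information about chance-corrected
  agreement" and "chance-level agreement" are different findings.
* **Bland–Altman**: differences are fixed as *administered minus
  FFQ-derived*, so a positive mean difference reads "the screener scores
  higher than the reference". Limits of agreement are d̄ ± 1.96·SD of the
  differences; under Gaussian differences ≈ 95% of children fall inside.

```{r}
k <- cohen_kappa(list(a = 40, b = 10, c = 5, d = 45))
c(kappa = k$kappa, lo = k$ci_low, hi = k$ci_high)
as.character(kappa_band(k$kappa))
```

## Cohort analyses

* `quartile_summary()` reports per-quartile means with t-based 95% CIs,
  the one-way ANOVA p, and a **p-for-trend from OLS of the variable on the
  integer quartile rank (1–4)** — the simplest defensible trend test when
  no method is prescribed; a monotone dose–response across ordered
  categories is what it detects.
* `adjusted_association()` fits OLS of each outcome on the total score
  plus covariates (default age and sex, sex as a single indicator) and
  reports the **unstandardized** per-point coefficient with its own 95% CI
  and p-value, plus a separately labelled standardized coefficient
  (β·SD(score)/SD(outcome)). The two scales are never mixed within one
  column pair.
* `homa_ir()` is fasting insulin (µU/mL) × glucose (mg/dL) / 405.
* `describe_cohort()` routes variables to mean ± SD with a pooled-variance
  t-test, or — when *declared* skewed, as lipid panels typically are — to
  median (P25–P75) with a Wilcoxon rank-sum test. Routing is configured,
  not auto-detected, so repeated runs of the same configuration cannot
  silently change summaries.
* **No multiple-testing correction** is applied anywhere, matching the
  single-instrument validation setting; with 17 items and ~7 outcomes,
  readers should interpret isolated p-values near 0.05 accordingly.

## The synthetic cohort generator

Real validation cohorts of this kind are access-restricted, so the
generator reproduces the *statistical structure* the validation assumes:

1. A one-dimensional latent adherence trait `Z ~ Normal(0, trait_sd)` per
   child. One dimension is an idealisation — diet quality is treated as a
   single construct by the score itself.
2. True item states `Bernoulli(plogis(base_i + loading_i · Z))`. Base
   logits are calibrated by quadrature + root finding
   (`calibrate_to_marginals()`) so the marginal prevalences match targets;
   the defaults are the prevalences observed for the administered
   instrument in its validation cohort (e.g. 96.3% for olive oil as main
   fat). The sofrito item, for which no prevalence was published, defaults
   to 0.60 — a deliberate, plausible choice, not a published value.
3. **Misreporting** flips each instrument's observed state with per-item
   probabilities. Direction `"toward_point"` models social desirability:
   over-reporting healthy consumption and under-reporting unhealthy
   consumption both push the indicator toward 1. The `"biased"` preset
   puts strong toward-point flips (p = 0.30) on the restraint items 12–18
   of the questionnaire and mild symmetric noise (p = 0.05) elsewhere,
   which reproduces the qualitative pattern that unhealthy-item kappas sit
   below healthy-item kappas.
4. **Observed quantities** are drawn uniformly from the satisfying (or
   violating) region of the reported state within plausible physiological
   bounds — e.g. a compliant nut intake lands in [7.5, 30] g/day. Uniform
   draws are the least-assumption choice given that only the indicator,
   not the intake distribution, enters the score.
5. **Outcomes** are linear in the *true* score with Gaussian noise plus
   age and sex effects: signs follow the reported association pattern
   (negative for waist circumference, triglycerides, HOMA-IR and BMI;
   positive for HDL and LDL cholesterol), magnitudes are this package's
   own defaults and not published values. Glucose is drawn, HOMA-IR is
   generated from its own effect model, and insulin is back-derived so
   that HOMA = insulin × glucose / 405 holds exactly. Ages are uniform on
   3–6 years and 50.3% of children are girls.

What the generator does **not** emulate: within-child correlation across
food groups beyond the shared trait (independence given Z is assumed),
energy adjustment, seasonality, digit preference and rounding in reported
quantities, and any real cohort's joint outcome distribution. Passing
validation and recovery tests on these cohorts therefore demonstrates that
the *pipeline arithmetic* is correct and that parameters are recoverable
under the stated model — it does not certify the screener's validity on
real children, which only field data can.

```{r}
co <- generate_cohort(cohort_preset("calibrated", n = 500, seed = 1))
co
```

## Numerical choices and degenerate inputs

* Threshold comparisons are ≥ for `at_least` and strict < for
  `less_than`, exactly as the criteria are worded; scores at a quartile
  cut point belong to the upper band (`findInterval` semantics).
* Calibration solves each base logit to |Δp| < 1e-10 (quadrature
  tolerance 1e-10, root bracket ±30 logits).
* Kappa's variance term is floored at 0 before the square root; Pₑ = 1 is
  detected with a relative tolerance near machine epsilon.
* Empirical quartiles use `stats::quantile` defaults; with heavily tied
  integer scores some empirical bands can be empty, which is why the fixed
  study bands are the default.
* Regression refuses rank-deficient designs and fewer than
  `max(min_n, p + 3)` complete cases rather than returning fragile
  estimates.
* Reproducibility: a cohort is a pure function of (config, seed); the
  object carries a hash of its four tables, and the pipeline stamps every
  output with the package version and a hash of the analytic
  configuration.

Test problem sizes were chosen to make sampling error negligible relative
to the assertions: n = 5 000 across five seeds for parameter recovery
(coefficients checked within 3 Monte-Carlo SEs, prevalences within 3
binomial SEs), n = 10 000 for distribution-level checks (binomial score
variance, limits-of-agreement coverage), and 1 000 replicates for the
uniformity of the null p-for-trend.

## Known limitations

* The FFQ mapping is a reconstruction from the published serving-size
  criteria, not a verbatim item-level crosswalk (which is not public);
  users validating against a different FFQ should edit the mapping YAML.
* Item 3's sub-condition and item 11 are structurally unverifiable from
  group-level FFQ data, as discussed above.
* The dichotomised-total kappa inherits all the item-level caveats and is
  additionally sensitive to the cutoff sitting near the score
  distribution's mode.
* Uniform within-region quantity draws make simulated intakes less
  right-skewed than real dietary data; agreement statistics depend only on
  the indicators, but quartile summaries of simulated grams should not be
  read as realistic intake distributions.
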