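# med4child

Scoring and relative-validity analysis of the **MED4CHILD** screener — an
18-item questionnaire measuring adherence to the Mediterranean diet in
children aged 3–6 years. Each item awards one point when consumption meets
an explicit serving-size criterion (e.g. ≥ 3 tablespoons of olive oil per
day, ≥ 3 servings of 15–20 g of nuts per week, red/processed meat < 2 times
per week), giving a total of 0–18 that is categorised into quartiles
(0–8, 9–11, 12–13, 14–18) and dichotomised at ≥ 10 points into low/high
adherence.

The package is aimed at nutritional epidemiologists who need to

- **score** the screener from quantity-level answers (thresholds are applied
  by the engine, not by the field form),
- **derive the same item indicators from a reference FFQ** — gram/day
  food-group intakes are converted to servings through editable serving-size
  definitions, so relative validity can be assessed item by item,
- **quantify agreement** between the two instruments: percent agreement
  (a + d)/n, Cohen's kappa κ = (P₀ − Pₑ)/(1 − Pₑ) with a large-sample
  (Fleiss-type) 95% CI and the usual interpretation bands (≤ 0.20 weak …
  > 0.80 almost perfect), and Bland–Altman limits of agreement
  d̄ ± 1.96·SD for the total score,
- **run the cohort analyses**: food/nutrient means by score quartile with
  ANOVA and p-for-trend, age- and sex-adjusted linear associations with
  cardiometabolic outcomes (BMI, waist circumference, lipids, HOMA-IR), and
  a sensitivity analysis excluding the unhealthy restraint items,
- **simulate cohorts** with a latent adherence trait driving both
  instruments, item-specific social-desirability misreporting and
  configurable outcome effects, so the whole pipeline is testable without
  access-restricted cohort data.

## Worked example

Simulate a cohort with social-desirability misreporting on the restraint
items, then run the full relative-validity pipeline:

```r
library(med4child)

co  <- generate_cohort(cohort_preset("biased", n = 2000, seed = 20))
res <- run_pipeline(pipeline_config(co$questionnaire, co$ffq, co$outcomes))

tail(res$validation[c("item", "pct_method1", "pct_method2",
                      "kappa", "band")], 4)
#>   item  pct_method1 pct_method2 kappa band
#> 1 16          0.603       0.420 0.647 substantial
#> 2 17          0.622       0.454 0.672 substantial
#> 3 18          0.786       0.718 0.818 almost_perfect
#> 4 total       0.690       0.586 0.733 substantial

res$bland_altman
#> $mean_difference  0.732
#> $sd_difference    1.21
#> $loa_low         -1.64
#> $loa_high         3.10
```

Each validation row is one item: the fraction scoring the point on the
administered questionnaire (`pct_method1`) versus on the FFQ-derived
reference (`pct_method2`), and their chance-corrected agreement. Under the
biased preset the questionnaire over-reports compliance on items 12–18
(0.60 vs 0.42 on item 16), dragging their kappas below the healthy items' —
and the administered total sits on average 0.73 points above the
FFQ-derived total in the Bland–Altman comparison.

Age- and sex-adjusted associations with the cardiometabolic outcomes
recover the generator's effect signs:

```r
res$associations[c("outcome", "beta", "ci_low", "ci_high", "p_value")]
#>   outcome     beta   ci_low  ci_high  p_value
#> 1 bmi      -0.0448  -0.0713  -0.0182  9.6e-04
#> 2 wc       -0.175   -0.262   -0.0891  7.0e-05
#> 3 hdl       0.360    0.206    0.514   4.6e-06
#> ...
```

`beta` is the unstandardized change in the outcome per one score point.

A thin command-line wrapper with `simulate`, `score`, `derive-ffq`,
`validate` and `run` subcommands ships in `inst/cli/med4child.R`.

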