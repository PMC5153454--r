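---
title: "Methods: nutrient profiling and claim analysis in nutriclaim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nutrient profiling and claim analysis in nutriclaim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriclaim)
```

## The problem

Pre-packaged foods across Europe carry health-related claims — statements
that a food has beneficial nutritional properties (*nutrition claims*) or
that a relationship exists between the food and health (*health claims*,
in the sense of EU Regulation 1924/2006). Whether claim-bearing foods are
actually healthier than claim-free foods is an empirical question, and
one way to answer it is a cross-sectional survey of store shelves: sample
foods in several countries, record the per-100 g nutrient declarations
and the on-pack claims, and compare the two groups — nutrient by
nutrient, and overall through a nutrient profile model.

`nutriclaim` implements that analysis as a tested pipeline:

1. **Survey model** — records with provenance-tracked nutrient panels
   (`read_food_table()`, `missingness_summary()`).
2. **Claim taxonomy** — resolving structured claim annotations into
   health / nutrition / not-a-claim (`resolve_claims()`,
   `exclusion_screen()`), and claim prevalence with confidence intervals
   (`prevalence_by_group()`).
3. **FSANZ NPSC scoring** — the Food Standards Australia New Zealand
   Nutrient Profiling Scoring Criterion (`npsc_score()`,
   `score_survey()`, `pass_proportions()`).
4. **Databank supplementation** — filling missing declarations from a
   matched food-composition reference with correlation validation
   (`supplement()`, `validate_matches()`, `kappa_agreement()`).
5. **Statistics** — Mann–Whitney and Kruskal–Wallis rank tests,
   category-adjusted regression, Wald proportion intervals, the
   two-proportion test and the design-precision calculation.
6. **Synthetic survey generator** — `generate_survey()` draws five-country
   surveys with known ground truth, so every estimator above can be
   checked by parameter recovery.

## The FSANZ NPSC

The scoring criterion awards *baseline points* (A) for the per-100 g
levels of energy (kJ), saturated fat, total sugars and sodium, and
*modifying points* for fruit/vegetable/nut/legume content (V), protein
(P) and fibre (F). Points for a nutrient are the number of ascending band
thresholds strictly exceeded — a value exactly on a threshold scores the
lower band. The final score is

$$\mathrm{score} = A - (V + P + F),$$

with one wrinkle: when $A \ge 13$ and $V < 5$, protein points are
suppressed (the *protein cap*). A food passes if its score does not
exceed the threshold of its NPSC category (1 beverages, 2 general foods,
3 fats/oils/spreads/cheese).

The band tables ship as data (`inst/extdata/npsc_points.yaml`), not code,
using the FSA/Ofcom-derived schedule on which the FSANZ criterion is
based: energy bands at 335 kJ steps, saturated fat at 1 g, sugars at
4.5 g, sodium at 90 mg, protein at 1.6 g, fibre at roughly 0.9 g, and
V points jumping 1/2/5 at 40/60/80 % FVNL. Category 3 extends the
saturated-fat and sodium bands linearly to 30 points; these extensions
are deliberately config-overridable so users can verify them against the
current official schedule.

**Pass-threshold orientation.** Published descriptions of the criterion
differ in which category gets the strictest threshold. The package
default (`orientation = "standard"`) is the FSANZ schedule: beverages
fail above 0, general foods above 3, category 3 above 27. The alternative
reading — general foods fail above 0, *drinks* above 3 — is available as
`orientation = "literal"`. The choice is explicit, never silent; both
orientations share the same band tables.

Missing FVNL defaults to 0 % (no V points) and is flagged per record in
`npsc_fvnl_assumed`; that is conservative for foods whose fruit content
simply was not recorded.

## Claims: codes first, keywords second

Claim classification consumes surveyor-assigned taxonomy codes (the
INFORMAS-style code families: content, comparative, nutrient function,
other function, disease risk reduction, general health), not raw language
modelling — field coding of claims is manual work, and the package's job
is to make it reproducible. A keyword *exclusion screen* runs first as a
safety net: eight families of on-pack statements (natural/organic/Halal,
additive absence, allergy advice, diet statements such as "gluten free",
storage advice, mere food-presence statements, sport or cause
advertising, and nutrition-labelling schemes) are not health-related
claims no matter what code they carry. Rules are evaluated
case-insensitively on whitespace-normalised text, in their listed order,
first match wins; both the code map and the rules are editable YAML.

## Statistical choices

* **Per-100 g, declared panels only.** Nutrient comparisons are
  complete-case per nutrient on declared values; supplemented values feed
  *only* the NPSC (`scoring_panel()`), because databank values are
  generic and would dilute label-level contrasts.
* **Rank tests** for unadjusted contrasts, since per-100 g nutrient
  levels are strongly right-skewed. `mann_whitney()` computes U from
  midrank sums with a tie-corrected, continuity-corrected normal
  approximation, switching to exact enumeration of all
  $\binom{n_1+n_2}{n_1}$ assignments when $n_1+n_2 \le 12$ (ties
  permitted — this is why the enumeration is in-package rather than
  `wilcox.test()`, which refuses exact p-values under ties;
  `wilcox.test()` is the cross-check in the test suite).
  `kruskal_wallis()` delegates to `stats::kruskal.test()`.
* **Category-adjusted regression.** `adjusted_difference()` fits
  `outcome ~ claim` (model 1) or `outcome ~ claim + food_group` (model 2)
  by least squares, treatment coding with the largest food group as
  reference (the reference choice cannot affect the claim coefficient).
  Model 2 is the primary estimate: claims concentrate in some food
  groups, and food groups differ hugely in nutrient levels, so the
  unadjusted contrast is confounded. No robust or survey-weighted
  variants — plain OLS, as is standard for this design.
* **Wald intervals** for proportions
  ($\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/n}$, clipped to [0, 1]), with
  display percentages rounded half-up to integers; this arithmetic
  reproduces printed survey tables from their counts, which Wilson
  intervals do not. A pooled-variance z test compares two proportions.
* **No multiple-testing adjustment.** The analysis reports many
  uncorrected p-values; pipeline outputs carry the number of tests so a
  reader can apply their own discount.
* **Design precision.** `precision_half_width(n, p)` returns
  $100 \cdot 1.96\sqrt{p(1-p)/n}$ percentage points — with 400 foods per
  country the worst case (p = 0.5) is ±4.9, i.e. ±5 points, enough to
  detect a 10-point prevalence difference between countries.

## The synthetic survey generator

Real shelf surveys of this kind are rarely deposited, so the package
ships a generator whose defaults *are* the study conditions the analysis
assumes, with full ground-truth bookkeeping:

* **Design:** five countries (DE 399, NL 416, ES 405, SI 416, UK 398
  foods; 2034 in total), each with 75 foods from a discounter, 75 from a
  neighbourhood store and the remainder from a supermarket.
* **Food-group mix** (seven Eatwell-style groups, including the added
  composite and miscellaneous groups) and per-group health/nutrition
  claim prevalences follow the observed survey margins.
* **Nutrient levels** are log-normal with group-specific means (the
  observed per-group means) and a common coefficient of variation of 0.8
  — positive and right-skewed, which is what per-100 g data look like.
  Dispersions are assumptions, clearly surfaced in
  `survey_config()`, because surveys publish means, not spreads. Total
  sugars are drawn as a Beta fraction of carbohydrate and saturated fat
  as a Beta fraction of total fat, so panel invariants (sugars ≤
  carbohydrate, saturated ≤ total fat, everything ≥ 0) hold by
  construction.
* **Claim effects.** The generator injects the category-adjusted
  (model-2) effect for each claim type and nutrient, so that
  `adjusted_difference()` is a fair parameter-recovery test. Positive
  effects (fibre; carbohydrate under nutrition claims) are injected as
  uniform additive within-group shifts — the regression is then correctly
  specified. Negative effects cannot be uniform: a −842 mg/100 g sodium
  shift against group means of 200–260 mg would demand negative sodium.
  They are instead injected as one multiplicative factor per claim type,
  root-solved so that the claim-variance-weighted average of within-group
  mean contrasts equals the configured effect exactly (this weighted
  average is precisely the large-sample OLS estimand of model 2). Targets
  that would require a non-positive factor raise an infeasible-config
  error before any sampling.
* **Claim overlap.** Health and nutrition flags are drawn independently
  within food group. Real surveys show positive overlap between the two
  claim types, but dependent flags would make each single-flag model-2
  regression an omitted-variable estimate of something other than the
  injected effect; independence keeps the recovery test honest. The
  configured prevalences are per claim type; the "any claim" margin is
  the independence-implied one.
* **Missingness** is applied after the truth is captured: per country, a
  no-information share loses the entire panel, and the remaining foods
  lose each nutrient at the conditional rate implied by the configured
  per-nutrient counts. Missingness is independent of nutrient values and
  claims (missing completely at random) — real label missingness is
  plausibly *not* MCAR (smaller producers both omit declarations and
  make different foods), which is one reason passing recovery tests here
  does not certify the estimators against informative missingness.
* **Reference databank.** `generate_reference_databank()` produces one
  generic entry per food: the pre-missingness truth plus Gaussian noise
  scaled to a fraction *f* of the per-nutrient SD, floored at zero and
  capped to keep panels consistent. The closed-form attenuation
  $r = 1/\sqrt{1+f^2}$ describes the expected declared-vs-reference
  correlation; because flooring skewed nutrients at zero damps the noise,
  the generator can alternatively root-solve *f* so the *realised*
  correlation hits a requested `target_r` exactly.

What the generator does **not** emulate: real product names and brands,
country-specific nutrient composition differences (only missingness
differs by country), informative missingness, correlated claim types, or
label rounding of declared values. Passing tests on synthetic surveys
therefore demonstrates the estimators' correctness under the stated
sampling model, not robustness to every pathology of shelf data.

## Numerical conventions

* Energy is stored in kJ (the NPSC is kJ-denominated); kcal is derived at
  4.184 kJ/kcal, and a reader fills whichever unit is absent. Salt
  declarations convert as sodium = salt/2.5 × 1000 via the reader
  dialect.
* An empty cell is *missing*; an explicit 0 is a value.
* Panel invariants carry a 0.5 g tolerance on the sugars/carbohydrate and
  saturated/total-fat orderings and max(2 kJ, 2 %) on energy-unit
  agreement, absorbing on-pack rounding.
* Nutrient values go into band lookups as-is, with strict-inequality band
  edges; no pre-rounding.
* Display percentages round half *up* (`round_half_up()`), matching how
  survey tables are printed; base R's `round()` rounds halves to even and
  does not reproduce them.
* All simulation entry points take a single integer seed;
  `generate_survey()` is byte-reproducible given (config, seed).

## Problem sizes used in the test suite

The shipped tests run the full 2034-food design: 100 seeded replicates
for effect recovery, 1000 replicates for each type-I-error calibration,
1000 random panels for the NPSC oracle check, and single surveys
elsewhere. These sizes give binomial noise comfortably inside the
asserted bands while keeping the default `R CMD check` run in minutes.

## Known limitations

* Classical OLS confidence intervals undercover slightly (empirically
  ≈ 89–92 % rather than 95 %) for effects on strongly skewed,
  group-heteroskedastic nutrients such as fibre; the recovery tests
  assert ≥ 85 % coverage for exactly this reason. Robust standard errors
  would narrow the gap but are out of scope by design.
* The NPSC category-3 band extensions beyond the published 10-point
  tables are a linear continuation and should be verified against the
  official schedule before regulatory use.
* The shipped taxonomy map covers the code families named in the claim
  definitions; site-specific coding schemes should extend the YAML.
* Matching of survey foods to databank entries is expert input, not
  computed; the package validates matches (Pearson r, outlier flags) and
  never creates or amends them automatically.
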