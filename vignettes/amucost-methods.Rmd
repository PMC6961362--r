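---
title: "Methods: costing antimicrobial use in small-scale chicken flocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: costing antimicrobial use in small-scale chicken flocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amucost)
```

## The problem

Small-scale meat-chicken farms in settings such as the Mekong Delta buy
antimicrobial products over the counter and administer them through drinking
water or feed. Surveillance of this use needs three things that raw farm
diaries do not directly provide: a **price metric that is comparable across
products** (packages differ in size, concentration and dosing), a
**public-health-relevance classification** of each product (the WHO ranks
antimicrobial classes by their importance for human medicine), and
**longitudinal summaries** of how use, disease, mortality and expense evolve
over a production cycle. `amucost` implements that pipeline, plus the mixed
models used to ask what drives the prices farmers pay.

## Standardizing prices: the ADD~kg~

The unit of comparison is the *animal daily dose for a 1 kg bird*
(ADD~kg~): the amount of product needed to medicate 1 kg of live chicken
for one day, dosed according to the label. For a label prescribing an
amount $a$ of product per carrier quantity (litres of water or kg of feed),
the dilution factor is $DF = a / \text{carrier}$, and

$$\text{ADD}_{kg} \,[\mathrm{g}] = \begin{cases}
DF\,[\mathrm{g/L}] \times 0.225 & \text{water route} \\
DF\,[\mathrm{g/kg}] \times 0.063 & \text{feed route,}
\end{cases}$$

using the daily intake of a 1 kg bird: 225 ml of water or 63 g of feed
(configurable via `intake_constants()`). When a label offers both carriers
the water indication is followed. The price of one ADD~kg~ in cents of US$
(written ₵) is the package unit price times this amount, converting
Vietnamese dong at a fixed study-period rate of 23,319 VND/US$
(`default_fx_rate`; a configuration scalar, not a live feed). For
multi-ingredient products, the per-ingredient price attribution divides the
product ADD~kg~ price equally by the number of active ingredients (1, 2 or
4 in the observed catalogue), so shares always recompose the product price
exactly.

Numerical choices: millilitre-denominated liquid products are treated
identically with ml in place of g; a dose *range* on a label ("1–2 g/L")
resolves to its midpoint by default (`range_policy` can select either end)
— the least-assumption summary where the source is silent. Label strength
(mg of ingredient per g of product) is parsed and carried but deliberately
not used in pricing: the metric prices the *dose of product*, not the mass
of active ingredient.

## WHO-criticality classification

Classification is purely dictionary-driven. The packaged dictionary
(`inst/extdata/aai_dictionary.csv`) maps each canonical ingredient name to
one of four categories — highest priority critically important, high
priority critically important, highly important, other — and carries an
alias column for spelling variants (sulpha-/sulfa-, catalogue typos). A
product's *category combination* is a pure function of the set of distinct
categories among its ingredients, joined in the fixed order Highest →
High → Highly → Other, with an "only" suffix for single categories; this
makes labels canonical and order-invariant. The dictionary is a versioned
CSV input, so revisions of the WHO list are swappable without code changes.

Two curation notes, visible in the dictionary's `note` column: the
transcribed catalogue contains the spelling "neomycine" in combinations the
source groups as highest-priority, although neomycin proper is a
high-priority aminoglycoside; the dictionary keeps "neomycine" as a
distinct entry so the transcription reproduces its source row memberships,
at the cost of counting 38 rather than 37 distinct ingredients. Similarly,
sulfadimidine and sulfamethazine (chemically the same compound) are kept as
separate entries, following the source catalogue.

## Diary analytics

Diaries are long tables: one row per flock-week, or one row per
antimicrobial-use (AMU) event within a flock-week. Per week of age, the AMU
probability is the share of observed flocks with at least one event, with
binomial standard error. Expense metrics per flock-week are the summed
event expenses (₵), divided by birds at the start of the week (per bird)
and additionally by estimated bird weight (per kg). Weight by age is an
injectable growth curve; the default is Gompertz,
$w(t) = 1.8\,e^{-3.72 e^{-0.179 t}}$ kg, anchored at about 0.08 kg at week
1 and 1.55 kg at week 18 — typical of slow-growing native meat chickens.
Weekly mortality is 100 × deaths / birds at start, dichotomized at 2.8
deaths per 100 bird-weeks (the observed-mean cut-off in the source
setting); `cutoff = "auto"` recomputes the cut-off as the data's own mean.

Group comparisons (disease vs no-disease weeks; high vs low mortality among
disease weeks) use the tie-corrected Kruskal–Wallis statistic with average
ranks, implemented in-package and property-tested against a brute-force
rank oracle. The frequency–price association (weeks of use per product vs
its mean ADD~kg~ price) uses Spearman's rank correlation with the two-sided
t approximation; both statistics refuse degenerate inputs (single group,
constant vector) loudly.

## Price-determinant models

Both models are linear mixed models with a farm random intercept, fitted by
REML via `lme4`. The response is the **natural log** of the ADD~kg~ price
in ₵: the source analysis never states the transform, but its negative
intercepts (−1.221, −1.331) on a strictly positive price are only coherent
on a log scale; the transform is config-overridable to identity.

* **Product-level model** (one row per price record): number of
  ingredients (baseline 1), WHO type of the most critical ingredient
  (baseline highly-important), pure-vs-mixed formulation (baseline mixed),
  district (baseline Thap Muoi). In the multivariable stage the WHO factor
  is, by default, collapsed to the single contrast "high-priority vs all
  other types combined", mirroring the source's footnoted treatment.
* **Farm-week model** (one row per AMU week): owner age band, gender,
  experience band, education, log flock size, log week of age, disease,
  high mortality, district.

Selection is forward stepwise: candidates with a univariable p < 0.20
enter in ascending-p order (ties broken alphabetically, so the procedure is
invariant to input order); each addition is retained iff its multivariable
p ≤ 0.05; a deterministic backward sweep then removes terms whose drop-one
p has risen above 0.05, which resolves correlated candidates. Screening
and retention use maximum-likelihood likelihood-ratio tests so multi-level
factors enter or leave as one term.

Because `lmerTest` is not available in the target environment, coefficient
p-values are Wald t with residual degrees of freedom $n - p$ rather than
Satterthwaite. This matters mainly for between-farm covariates (e.g.
district), whose effective sample size is the number of farms: their Wald
standard errors are mildly anticonservative (about 8% small at ~100 farms
in our calibration runs). This is documented rather than patched, and is
the reason the strict 2-SE/95%-of-seeds calibration check in the acceptance
suite hovers at 93–95% observed coverage.

Residual handling: after the final fit, records with |standardized
residual| > 3 (an unstated threshold in the source; 3 is the conventional
default) are excluded and the model refit; both fits are reported, and the
refit fails loudly if exclusions empty a factor level.

The *farm-adjusted mean price* is operationalized as the back-transformed
intercept of an intercept-only farm-random-intercept model on log price
(delta-method SE); the source does not define the estimator, and for
balanced designs on the identity scale this reduces to the mean of farm
means. A single-farm input falls back to the crude mean with a warning.

## The synthetic world

The generator (`generator_config()`, `generate_catalog()`,
`generate_diaries()`) emulates the study's stated conditions so every
downstream stage is testable without field data:

* 102 farms, 203 flock cycles; lognormal flock sizes with median 300
  (IQR 200–495 ⇒ sdlog 0.672); cycle lengths from a rounded normal with
  median 18 and IQR 16–20, clamped to 10–28 weeks.
* Weekly AMU and disease indicators follow logistic-in-age decays anchored
  at the printed week-1 values (0.76 and 0.56). The decay rates are **not**
  printed; they are fixed from the printed overall means: 0.40/week makes
  the 18-week mean AMU probability 0.219 ≈ the printed 0.21, and 0.15/week
  makes the mean disease share 0.283 ≈ the printed 28.19%.
* Within a week, AMU is more likely under disease at a risk ratio of 1.5,
  with the disease/no-disease split constructed to preserve the marginal
  weekly AMU probability exactly.
* Deaths are binomial with a gamma-overdispersed weekly rate (shape 0.35)
  whose mean is 1.5/100 plus a Gaussian mid-cycle peak (4.67/100 at week
  7.5, SD 2 weeks); the 18-week mean rate is 2.8/100, the printed cut-off
  value, while overdispersion keeps the median cumulative mortality well
  below the mean-implied value, as in right-skewed field mortality.
* Prices are lognormal. Product-level records use the printed product-model
  coefficients (intercept −1.221; two-ingredient +0.102; high-priority
  +0.122; pure +0.152; Cao Lanh +0.468); AMU-week prices use the printed
  farm-week coefficients (intercept −1.331; log-age +0.153; Cao Lanh
  +0.514). Farm random SD 0.35 and residual SD 0.55 are unprinted
  realism choices fixed once. Product choice targets the week's expected
  log price so older flocks receive more expensive products; a `uniform`
  choice model is available for independence tests.
* The expense of an AMU week is ADD~kg~ price × birds × weight × treatment
  days. Treatment days is the single free scalar of the expense process;
  the mean course implied by the printed cumulative per-bird expense of
  ₵3.91 under all other anchors is 5.13 days (`expected_cumulative_per_bird()`
  reproduces the closed form), rounded to a whole-day course of 4–6 days
  (mean 5), which puts the generator's expectation at ₵3.81. The 2.5%
  discretization gap is documented rather than tuned away.

What the generator does **not** emulate: transcription errors and missing
diary weeks, within-week event timing, multiple products per week,
non-antimicrobial health products, seasonal effects, and any dependence of
product choice on disease severity beyond the declared price-targeting
rule. A green test on synthetic data therefore establishes that the
*pipeline computes its statistics correctly under the stated world*, not
that the field numbers themselves are recovered; printed field statistics
that depend on the unpublished raw diaries (e.g. the Kruskal–Wallis χ² of
367.3) are covered by oracle-agreement and parameter-recovery properties
instead.

## Reproducibility and seeds

One integer seed drives ordered sub-streams (catalogue; farms; diaries), so
each artefact regenerates independently and byte-identically. Deterministic
stages never consume randomness; the VND→₵ conversion happens exactly once,
at pricing.

## Known limitations

* Wald-t p-values (see above); between-farm effects would benefit from
  Satterthwaite or Kenward–Roger df if those packages are available.
* The dictionary ships with the 38 ingredients of the transcribed
  catalogue only; applying the classifier to a new catalogue requires
  extending the CSV.
* The four-ingredient case is handled generically (any composition length
  ≥ 1 classifies), but the price-attribution warning outside {1, 2, 4}
  reflects the source's rule rather than a chemical principle.
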