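---
title: "Methods: predicting added and free sugars and scoring carbohydrate quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting added and free sugars and scoring carbohydrate quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`carbquality`, the assumptions behind them, the parameters that matter, and
the places where the design was genuinely open and a choice had to be made.

## The estimation problem

Total sugars are declared on essentially all packaged-food labels; *added*
sugars (caloric sweeteners introduced during processing) and *free* sugars
(added sugars plus sugars in honey, syrups, fruit juices and concentrates)
mostly are not, outside a few jurisdictions. The package estimates them from
the two things every label carries:

- the **ingredient list**, ordered by descending quantity, so the position of
  a sugar-bearing ingredient bounds how much of the product it can be; and
- the **nutrition facts panel**, normalized to per 100 g: energy (kcal),
  total fat, saturated fat, carbohydrate, fiber, total sugars, protein (g),
  sodium (mg).

The downstream use is a thresholded criterion, the 10:1|1:2 carbohydrate
ratio, so moderate errors in predicted grams often do not flip the verdict;
what matters most is classifying *whether* added sugars are present and
getting the amount roughly right relative to fiber.

## Cleaning rules

Real label data are noisy; records must be internally consistent before any
modelling. `clean_products()` enforces, with named and counted rejection
reasons: a complete, finite, non-negative panel; `saturated_fat ≤ total_fat
+ 0.5 g`; `total_sugars ≤ carbohydrate + 0.5 g`; `fiber ≤ carbohydrate +
0.5 g`; `fat + carbohydrate + protein ≤ 105 g/100 g`; an Atwater
energy-consistency check `|E − (4C + 9F + 4P)| ≤ 0.25·E`; a positive serving
size; at least one parseable ingredient; a launch year inside the configured
window (2014–2024 by default); and, when declared, added sugars at most
total sugars + 0.5 g. All slacks are arguments of `cleaning_rules()`.

Two deliberate simplifications: the Atwater check ignores fiber's ~2 kcal/g
(the 25 % relative tolerance absorbs it together with label rounding, which
is country-specific and not modelled), and sodium stays in mg/100 g rather
than salt equivalent, matching panel convention. Cleaning is a partition —
kept plus rejected always equals the input — and is idempotent.

## Ingredient tagging

`parse_ingredient_list()` splits on top-level commas/semicolons only
(separators inside balanced parentheses or brackets are ignored), drops
parenthetical annotations and percentage marks, and strips leading
qualifiers ("organic", "enriched"). Compound ingredients are *not* expanded
into sub-ingredients by default: the position semantics of the label refer
to the top-level list. An `expand_compound` option appends sub-ingredients
after their parent for users who want the other reading.

`tag_ingredients()` flags each of the first six names as added sugar, dairy
sugar source, and/or fruit–vegetable sugar source by matching a curated
regex lexicon, case-insensitively. Design choices:

- **Exclusions veto everything.** Non-caloric sweeteners (sucralose,
  aspartame, stevia, …), sugar alcohols, and plant-based "milks" match no
  category regardless of other patterns: they carry no free sugars (or, for
  plant drinks, no lactose).
- **Ambiguous ingredients keep both flags, added wins downstream.** "Fruit
  juice concentrate" is both a fruit term and, under the WHO free-sugar
  definition, an added sugar; both flags are set and the added flag governs
  the free-sugar classification. The flags are features, not mutually
  exclusive classes.
- **Fixed width.** Products with fewer than six ingredients are padded with
  all-false flags; positions beyond six are provably ignored (property- and
  fixture-tested). Six positions cover the bulk of product mass under the
  descending-quantity convention.

The shipped lexicon (YAML under `inst/extdata/`) has ~60 added-sugar, ~15
dairy and ~40 fruit/vegetable patterns plus exclusions. It is data, not
code: users can enrich it or supply another language entirely, and
monotonicity is guaranteed — adding patterns to a category can only add that
category's flags, never remove them.

## The gated two-stage model

`sugar_model()` fits, on products that declare added sugars:

1. **Presence stage.** Three binary tree-based classifiers — a random
   forest, bagged trees (a forest with `mtry = p`, i.e. no feature
   subsampling), and gradient-boosted trees — each output a probability that
   the product contains added sugars. The decision is a **majority vote of
   thresholded probabilities**; the common threshold is tuned on the
   validation set to maximize balanced accuracy over a 0.10–0.90 grid
   (step 0.05, first maximum wins as the tie-break). The number three and
   the vote are a design choice: with three families the vote is never tied,
   and each family errs differently. A `mean_prob` combination rule is
   available in `sugar_model_control()`.
2. **Quantity stage.** On added-sugar-positive training records only, two
   base tree-ensemble regressors (random forest, gradient boosting) are fit;
   their predictions on the *held-out validation positives* — data neither
   base model saw — fit a linear meta-regressor (classic stacking). At
   predict time the meta-regressor combines the two base predictions.

Predictions are **gated** — a presence-negative product gets exactly
0 g/100 g, never a small regression residue — and **clipped** to
`[0, total_sugars]`, the physical range, with a flag recording when clipping
occurred. The presence label is `declared_added_sugars > 0` (threshold
configurable via `presence_cut`).

Defaults, chosen once as conventional mid-range settings for tabular data of
this width (26 features): 300 trees per classifier forest, 500 for the
regression forest, 150/300 boosting rounds at learning rate 0.1 and depth 6.
At least 200 positive training records are required (`min_positive`);
stacking falls back to an equal-weight average if the validation set has
fewer than three positives. Every stochastic step is seeded from the single
`seed` argument, the fit records its metadata, and identical inputs give
bit-identical predictions, including across serialization
(`write_sugar_model()` / `read_sugar_model()`, which refuses bundles from a
different feature-contract version).

Features never include the declared label (no target leakage; tested by
shuffling labels at predict time), and the **kNN baseline**
(`knn_baseline()`) deliberately uses only the eight standardized panel
nutrients — the performance gap between it and the full model measures what
the ingredient tags contribute.

## Free sugars and the 10:1|1:2 verdict

`assign_free_sugars()` resolves one free-sugar value per product with
precedence **override > declared > predicted**: products in an override
category ("Juice Drinks", "Carbonated Soft Drinks", "Sweeteners & Sugar",
"Sugar & Gum Confectionery") or sub-category ("Flavoured Water", "Honey",
"Syrups", "Ready To Drink (Iced) Tea", "Water Based Ice Lollies, Pops &
Sorbets") take their total sugars — their sugars are free sugars by
composition — regardless of model availability; otherwise the declared
value when present (and `prefer_declared` is set), else the prediction.
Category matching is exact after whitespace normalization,
case-insensitive, since the names come from a controlled vocabulary.

`meets_carb_ratio()` takes the two inequalities literally:

- 10:1 is **inclusive** ("at least 1 g of fiber per 10 g of carbohydrate"):
  `fiber ≥ carbohydrate/10`. A zero-carbohydrate product meets it
  vacuously.
- 1:2 is **strict** ("less than 2 g of free sugars per 1 g of fiber"):
  `free_sugars < 2·fiber`. Exactly 2:1 fails.

Two degenerate cases are genuinely underdetermined and are explicit,
configurable choices: `fiber = 0 ∧ free_sugars = 0` **meets** 1:2 by default
(zero free sugars cannot violate a free-sugar limit;
`zero_fs_meets_1_2 = FALSE` flips it), and zero-carbohydrate products are
**scored, not excluded** by default (beverage categories live near zero
carbohydrate; `exclude_zero_carb = TRUE` drops them). The test is
scale-invariant, so any common mass basis works.

## Surveillance statistics

`summarize_groups()` reports per group: n, mean ± sample SD (n−1
denominator, SD missing for single-product groups) of carbohydrate, fiber
and free sugars, and the three meeting-percentages. The combined percentage
can never exceed either component (conjunction).

`proportion_ztest()` is the **pooled, two-sided two-proportion z-test
without continuity correction**:
p̂ = (xₐ+x_b)/(nₐ+n_b), z = (pₐ−p_b)/√(p̂(1−p̂)(1/nₐ+1/n_b)). The variant was
chosen because it exactly reproduces published surveillance-table p-values
after integer counts are recovered from printed rounded percentages
(`recover_count_from_percent()`, which errors on ambiguous or impossible
printed values rather than guessing); a Yates correction sits behind
`correct = TRUE`. Equal proportions return p = 1 by definition, which also
covers the zero-standard-error case. No multiple-testing adjustment is
applied across category rows, mirroring per-row table reporting; callers
can `p.adjust()` downstream. When both proportions are zero a table
reporter may prefer "NA" over p = 1; the test function stays pure and the
presentation choice is left to the caller. Report percentages round half
away from zero to 1 decimal, matching table style.

`trend_by_year()` computes the *incremental* (cumulative) series: at year Y,
the proportion among all products launched up to and including Y. By
construction the final-year value equals the whole-window proportion —
asserted in tests. February-partial final years are retained; dates are
reduced to calendar years.

## What the synthetic generator emulates — and what it does not

`generate_products()` exists because the product databases this methodology
targets are proprietary. Per product it draws a category (the default mix
covers every override category/sub-category plus staples: breads, cereals,
biscuits, bars, soups, dairy, juices, confectionery), a market and launch
year; builds an ingredient list of 4–9 terms whose quantity shares decay
geometrically with label position (`position_decay = 0.55`, i.e. each
position carries roughly half the previous one — steep enough that the
first six positions dominate, as on real labels); places added-sugar
ingredients within a category-specific position range (position 1 for table
sugar and confectionery, positions 4–6 for bread — this is what makes
category sugar levels realistic, since position determines mass); credits
sugar mass per ingredient via per-term sugar fractions (1.0 for sugars and
syrups, 0.5 for milk powder, 0.05 for fresh fruit, …); and assembles the
panel bottom-up: total sugars = added + natural, carbohydrate = sugars +
fiber + starch, Atwater-exact energy. Declared values are truth plus
truncated-normal noise (`noise_sd = 0.5 g` by default, emulating label
rounding/tolerance), present only in markets configured as declaring; the
noise applies to zero-truth products too, so roughly half of them declare a
small positive value — realistic label noise the presence stage must absorb,
and the reason validation "presence accuracy" (against noisy labels) is
lower than test accuracy against the noiseless hidden truth. Ground truth
(true added and free sugars, corruption flags) lives in a sidecar table
keyed by product id and never in the visible record.

`make_benchmark()` fixes the evaluation recipe: 5,000 train / 1,000
validation products from one declared "US-like" market, 1,000 test products
from three non-declaring markets, evaluated against sidecar truth — the
train-in-one-country, predict-globally protocol. These sizes were chosen as
the smallest at which ensemble training is stable and prevalence estimates
are tight; all tests and the acceptance script use them.

What passing on synthetic data does **not** show: the generator's
ingredient vocabulary is small and English-only; its sugar content is an
exact deterministic function of ingredient positions, which real recipes
are not; its category nutrient profiles are stylized rather than fit to any
real distribution; and there are no mislabeled or adversarial products
(e.g. declared sugars with no sugar ingredients). Real-data error will be
higher, and the lexicon will need enrichment per market. The synthetic
results validate the *machinery* — gating, stacking, clipping, scoring,
aggregation — not real-world error rates.

Corruption (`corruption_rate`, default 0) injects one named invariant
violation per affected record, flagged in the sidecar, so cleaning tests
can verify that kept counts equal the generator's clean counts exactly.

## Numerical and implementation notes

- Splits are stratified by presence with largest-remainder rounding, so the
  100-record, (0.8, 0.1, 0.1) case gives exactly 80/10/10 and per-split
  prevalence stays within a fraction of a point of the global value.
- All RNG use saves and restores the caller's RNG state; `seed` arguments
  are the only entry point for randomness. Tree learners run single-threaded
  with fixed seeds for bit-reproducibility.
- MAPE is computed only over positive truths (undefined otherwise); R² is
  reported missing when all truths are equal rather than dividing by zero.
- `knn_baseline()` standardizes nutrients by training mean/SD; zero-variance
  columns get unit scale (contributing nothing when train and query agree).

## Known limitations

English-only default lexicon; no OCR or unit parsing beyond g/ml/mg and
kcal; country-specific label rounding rules are absorbed by tolerances, not
modelled; claim counting is exact-string based; no causal interpretation of
trend series. The CLI is a thin wrapper — all behaviour lives in the
documented functions.
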