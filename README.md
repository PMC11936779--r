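# carbquality

Added- and free-sugar prediction and carbohydrate-quality scoring for
packaged foods and beverages, from on-pack information only.

## The problem

Carbohydrate quality — not just quantity — is linked to human health, and a
practical product-level criterion is the **10:1|1:2 ratio**: a product meets
it when

- **10:1** — it has at least 1 g of dietary fiber per 10 g of total
  carbohydrate (`fiber ≥ carbohydrate / 10`), and
- **1:2** — it has less than 2 g of *free sugars* per 1 g of fiber
  (`free_sugars < 2 · fiber`, with zero free sugars meeting the limit).

The blocker for applying this at food-supply scale is free sugars: total
sugars are declared on virtually every label, but added/free sugars are
mandatory only in a few countries (the US among them). Everywhere else they
must be inferred from what *is* on the pack — the ingredient list and the
nutrition facts panel.

`carbquality` implements an automated pipeline for exactly that, aimed at
nutrition researchers and food-supply surveillance analysts:

1. **Clean** product records to internally consistent per-100 g panels
   (non-negativity, sugars/fiber ≤ carbohydrate, SFA ≤ fat, Atwater 4/9/4
   energy consistency).
2. **Tag** each of the first six label ingredients — ingredient lists are
   ordered by descending quantity, so position carries signal — as *added
   sugar*, *dairy sugar source*, or *fruit/vegetable sugar source*, using a
   curated, extensible regular-expression lexicon (fruit juice concentrates
   count as added, per the WHO free-sugar definition; non-caloric sweeteners
   are vetoed by exclusion patterns).
3. **Predict** added sugars with a gated two-stage model: three tree-based
   binary classifiers (random forest, bagged trees, gradient boosting)
   vote on *presence* of added sugars; if present, two stacked tree-ensemble
   regressors combined by a linear meta-regressor predict the *amount*,
   clipped to `[0, total_sugars]`. Features are the 18 position×category tag
   flags plus the eight panel nutrients. A nutrient-only kNN baseline is
   included for comparison.
4. **Score** free sugars (declared value, model prediction, or — for
   intrinsically sugary categories such as juices, soft drinks, honey and
   confectionery — total sugars) against the 10:1|1:2 criterion.
5. **Aggregate** by category, country, and launch year: group summaries,
   cumulative yearly trend series, claim counts, and pooled two-proportion
   z-tests comparing adherence computed from declared vs predicted values.

Because the product databases this is designed for are proprietary, the
package ships a **synthetic label generator** with known ground truth
(ingredient lists with position-decaying quantity shares, Atwater-consistent
panels, category-dependent added-sugar prevalence, market/year strata), so
the entire pipeline is testable end to end.

## Worked example

```r
library(carbquality)

sim   <- generate_products(gen_config(3000, seed = 42))
parts <- split_dataset(sim$products, c(0.7, 0.15, 0.15), seed = 42)
fit   <- sugar_model(parts$train, parts$validation, seed = 42)
fit
#> Gated two-stage added-sugar model
#>   presence: 3 tree-based classifiers (rf, bagged, gbt), majority @ threshold 0.9
#>   quantity: stacked rf + gbt -> linear meta-regressor
#>   trained on 2100 products (1679 with added sugars), seed 42
#>   validation: MAE 0.769 g/100 g, R2 0.989, presence accuracy 0.904

pred  <- predict(fit, parts$test)
truth <- sim$truth[match(parts$test$product_id, sim$truth$product_id), ]
evaluate(truth$true_added_sugars, pred$added_sugars_pred)
#> n = 450  MAE = 0.719 g/100 g  MAPE = 10.0%  R2 = 0.989

scored <- score_dataset(assign_free_sugars(parts$test, pred))$scored
head(summarize_groups(scored, by = "category")[
  , c("category", "n", "pct_meeting_combined")])
#>                 category  n pct_meeting_combined
#> 1 Bread & Bread Products 56            26.785714
#> 2 Carbonated Soft Drinks 32             0.000000
#> 3           Cold Cereals 48            39.583333
#> ...
```

The fit's validation MAE of 0.77 g/100 g is the mean absolute gap between
predicted and declared added sugars; presence accuracy is against the noisy
declared labels, while the test evaluation above is against the generator's
noiseless hidden truth. The per-category table is the surveillance shape:
cereals and breads meet the ratio far more often than beverages, which lack
fiber.

Surveillance p-values can be recomputed directly from a published-style
table row (group size plus rounded percentages):

```r
proportion_ztest(recover_count_from_percent(32.0, 485), 485,
                 recover_count_from_percent(33.4, 485), 485)
#> two-proportion z-test: 155/485 vs 162/485  z = -0.4792  p = 0.6318
```

A command-line front end wrapping the same functions is installed at
`exec/carbquality` (subcommands `simulate`, `clean`, `tag`, `train`,
`predict`, `score`, `aggregate`, `ztest`, `trend`).

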