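# plantserve

Quantifying the plant and animal content of everything people actually eat —
not just whole foods, but multi-ingredient products and mixed dishes — is a
prerequisite for assessing plant-based diets from 24-hour recalls, food
records and diet histories. Food-composition databases in the AUSNUT
2011–2013 / Australian Dietary Guidelines (ADG) tradition express foods as
*food-group servings per 100 g*, but leave many commercial products and
composite dishes unclassified, and overlook ingredients buried inside
recipes (the egg in home-made pasta, the butter in a pastry).

`plantserve` implements a systematic expansion of such a database so that
**every** food, beverage and dish carries servings per 100 g across 23
plant/animal food groups, plus water and alcohol side channels. It is
written for nutrition epidemiologists and dietitians building or applying
food-group databases to dietary survey data.

## The model

Every food group converts content into servings by one of four linear bases:

- **mass** — `servings = amount_g / serving_size_g` for core groups
  (e.g. 75 g cooked vegetables, 150 g fruit, 250 g milk per serving);
- **energy** — `servings = energy_kJ / 600` for energy-dense fat groups
  (animal fats, saturated plant fats, miscellaneous groups), following the
  600 kJ discretionary-food serving convention;
- **sodium** — `servings = sodium_mg / 120` for salty-but-lean products
  (stocks, sauces, gravies), anchored to the 120 mg Na/100 g low-salt
  threshold;
- **nutrient-direct** — added sugars (g/100 g) pass through unchanged.

Multi-ingredient products are resolved by recipe disaggregation. For a
recipe with ingoing ingredient weights `w_i` and weight-change (yield)
factors `f_i` (raw → cooked-equivalent; `f < 1` is moisture loss):

```
p_i        = w_i f_i / Σ_j w_j f_j          (ingredient proportions, Σ p_i = 1)
S_g(prod)  = Σ_i p_i · S_g(ingredient_i)     (servings per 100 g, per group g)
```

applied recursively (with memoisation and cycle detection) down to base
foods. Products without recipes fall back to **label-based** estimation
(`declared_percent / 100 ×` the ingredient's vector) and then to a
**proxy** product whose vector is copied. Curated exclusion categories
(non-nutritive sweeteners, infant formula, supplements, yeast, cooking
additives, plain water/alcohol) stay unclassified with a zero vector —
their water and alcohol are still recorded. Intake records convert as
`servings = amount_g × servings_per_100g / 100`.

A seeded synthetic-data generator (`generate_fixture()`) emulates all four
source files with analytically known ground truth, so the whole pipeline is
verifiable without any external data.

## Worked example

A three-food miniature database anchors the serving bases:

```r
library(plantserve)
ex  <- make_worked_example()
cls <- classify_all(ex$db, assignments = ex$assignments, tags = ex$tags)

resolve_food("27000001", ex$db, assignments = ex$assignments, tags = ex$tags)
#> <resolved_product 27000001 method=direct depth=0>
#> <servings_vector method=direct> water=85 alcohol=0 g/100g
#>   miscellaneous_animal   2.45833 servings/100g

person_totals(ex$intakes, cls)[, c("person_id", "miscellaneous_animal", "water_g")]
#> # A tibble: 1 × 3
#>   person_id miscellaneous_animal water_g
#>   <chr>                    <dbl>   <dbl>
#> 1 p1                         0.3       8
```

The gravy carries 295 mg Na/100 g, so the sodium basis yields
295/120 = 2.45833 servings per 100 g; the butter-like fat at 600 kJ/100 g
yields exactly 1 serving; and eating 20 g of a sauce holding 1.5
servings/100 g contributes 1.5/100 × 20 = 0.3 servings.

Summaries over a classified database mirror the standard reporting shapes:
`summarize_by_major_group()` (containment counts per two-digit major food
group), `summarize_core_discretionary()` (core vs discretionary strata,
unflagged foods kept out of both denominators) and `compare_databases()`
(per-person serving distributions under two database versions, ready for
plotting with `plot_database_comparison()`).

A thin CLI mirroring the main operations ships in
`inst/cli/plantserve.R` (subcommands `simulate`, `classify`, `intake`,
`summarize`).

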