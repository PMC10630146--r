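---
title: "Methods: building plant/animal food-group servings databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building plant/animal food-group servings databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantserve)
```

## The problem

Dietary-guideline databases express foods as food-group servings per 100 g,
which makes intake quantification a multiplication: servings consumed =
grams eaten × servings per 100 g / 100. But such databases typically leave
commercial products and mixed dishes partly or wholly unclassified, and
ignore plant or animal ingredients hidden inside recipes. `plantserve`
expands a database of this kind so every item carries a complete servings
vector across 23 plant/animal food groups, with water and alcohol carried
alongside as side channels that never enter plant/animal membership.

## The classification schema

The default schema (`food_group_schema()`) has 13 plant groups, 9 animal
groups and `added_sugars`. Added sugars are tagged `neither` by default:
treating them as plant would conflate plant- and animal-derived sugars
(honey) and double-count sugar already captured by other groups. A schema
switch (`added_sugars_kingdom = "plant"`) re-tags them for sensitivity
analyses. The group list itself and all serving sizes are configuration,
not constants: surveys and guideline revisions differ, so
`food_group_schema()` and `read_serving_rules()` accept replacements, with
validation (exactly 23 unique keys, one kingdom tag each, one default rule
per group).

## Serving rules

Four linear bases convert content into servings per 100 g:

| basis | formula | default denominator | used for |
|---|---|---|---|
| mass | amount / serving size | group-specific (5–250 g) | core groups |
| energy | kJ / 600 | 600 kJ | fats, energy-dense miscellaneous items |
| sodium | mg Na / 120 | 120 mg | stocks, sauces, gravies |
| nutrient-direct | identity | — | added sugars |

The energy basis follows the discretionary-food convention that one serving
equals 600 kJ; the sodium basis anchors salty-but-lean products to the
120 mg Na/100 g low-salt threshold, which characterises them better than
energy does. Which rule applies is decided by `select_rule()`: an explicit
food-id tag, then a case-insensitive name pattern (e.g.
`"stock|sauce|gravy"`), then the group default. Exactly one rule resolves
for every (food, group) pair, or a configuration error names both.

Default mass serving sizes follow dietary-guideline conventions (75 g
cooked vegetables/grains/legumes, 150 g fruit, 125 g juice, 30 g nuts, 65 g
red meat, 80 g poultry, 100 g fish, 60 g egg, 250 g milk, 40 g cheese, 10 g
oil, 5 g herbs/spices, 250 g for a tea/coffee beverage). Published
guideline sub-group tables refine these within groups; ship your own rule
file to reproduce a specific release. Tea and coffee deserve a note: the
convention for them is not standardised, so the package defaults to a mass
basis with a 250 g beverage serving applied to the non-milk fraction that
the recipe engine isolates (milk inside a latte propagates to the dairy
group via the recipe path); a count-of-cups convention can be emulated by
editing the denominator.

## Recipe disaggregation

For a product with ingoing ingredient weights $w_i$ and weight-change
factors $f_i$, the engine computes adjusted weights $w_i f_i$, proportions
$p_i = w_i f_i / \sum_j w_j f_j$, and the product's vector
$S(\text{prod}) = \sum_i p_i\, S(\text{ingredient}_i)$, recursing into
composite ingredients first. The weight-change factor converts the
raw/ingoing weight into the cooked-equivalent state in which serving sizes
are defined — a boiled grain takes up water ($f > 1$), a roasted meat loses
it ($f < 1$).

Two factor roles exist in principle: per-ingredient conversion and a
product-level yield factor (`final_weight()` = sum of ingredients × product
factor). Source files in this tradition supply one factor column; the
package applies it consistently in both roles, so the final weight equals
the sum of adjusted weights. Factors may be encoded as multipliers (0.8) or
signed percentages (−20); `read_recipe_file(factor_encoding=)` normalises
both to multipliers — the identity factor (1.0) is the only safe default
when the column is absent, and its use is warned about.

Implementation details that matter:

- **Determinism.** Ingredients are visited in sorted food-id order and
  resolution is memoised per food, so provenance and logs are reproducible
  and shared sub-recipes are computed once.
- **Cycles.** A self- or mutually-referential recipe raises a cycle error
  listing the loop; in whole-database runs the offending food becomes
  `unclassified` with the reason recorded.
- **Excluded ingredients.** Water, salt, yeast and other exclusion-listed
  items resolve to a zero-group vector carrying only their water/alcohol
  content. Without this, any dish listing water as an ingredient — most
  dishes — would fail to resolve; with it, water correctly dilutes
  per-100 g servings.
- **Linearity.** All steps are linear, so doubling every ingredient weight
  changes nothing per 100 g, and increasing one ingredient raises its
  groups while renormalising every other ingredient's contribution down.
  Both properties are tested.

## Label and proxy fallbacks

Products without recipes use their packaging: each declared ingredient
contributes `declared_percent / 100` × its own vector. Percentages are per
100 g of final product, exactly as printed, so no weight factor applies on
this path. Under-declared labels (sums below 100 %) leave the remainder at
zero servings and are reported, never renormalised — scaling up would
fabricate content the label does not claim; sums above 100 % are rejected.
Because labels do not declare water, the product's own nutrient record
supplies the water/alcohol channels on this path (and on the direct and
unclassified paths); the recipe path uses propagated values instead, which
coincide whenever nutrients are coherent with the recipe.

When label data are unusable, a comparable classified product (or a
standard published recipe entered as one) acts as a proxy: its vector is
copied verbatim and the provenance records the proxy id. A proxy must be
classified by a non-proxy route — chains of proxies are rejected — and a
zero-content proxy propagates with a warning rather than silently.

## The whole-database workflow

`classify_all()` routes every food through exclusion check → direct
(existing servings, then single-group rule assignment) → recipe → label →
proxy; the first success wins, so each food receives exactly one method and
method counts partition the database. Failures are per-food, never fatal.
`derive_flags()` turns vectors into membership flags using a containment
tolerance of 1e-9 servings/100 g (floating-point dust from long recipe
chains must not count as "contains"). Because the "entirely plant"
percentage admits two denominators, `database_headline_summary()` reports
it against both the plant-containing subset and all classified foods,
explicitly labelled; likewise for animal. A 20 % audit sample for
independent cross-checking is drawn reproducibly by `audit_sample()`
(deterministic given the seed, sampling without replacement, size =
round(fraction × n)); the draw saves and restores the global RNG state.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` produces the four source files plus label, proxy and
exclusion side inputs, with a ground-truth vector per food computed at
construction time by the flattened analytic formula — a code path
deliberately separate from the engine, so agreement between the two is a
real check. Defaults: 2 base foods per group (46 base foods), 40
composites of 2–4 ingredients nested to depth 2 (3 where nesting is the
point of the test), weight factors uniform on [0.5, 1.3], 15 % of
composites label-routed with percentages equal to their recipe proportions,
10 % proxy-routed, 5 % exclusion-listed items, intended servings uniform on
[0.3, 3]. Nutrients are made coherent: an energy-basis food carries
600 × S kJ so the rule recovers S; sauce foods carry 120 × S mg Na;
composite nutrients are proportion-weighted ingredient nutrients, which
keeps nutrient-derived values stable under nesting and makes
classification idempotent.

The generator aims at structural realism only: every method route, serving
basis and nesting depth is exercised. It does not emulate the marginal
distributions of a real food supply, correlated nutrient profiles, brand
variability in labels, or the manual curation behind real proxy choices.
Passing tests therefore demonstrate that the arithmetic and routing are
correct, not that any particular real database is reproduced.

## Numerical choices

- Proportions are exact ratios of doubles; conservation is asserted to
  1e-9 in tests and typically holds to 1e-15.
- Engine-vs-oracle and label-vs-recipe agreement are asserted at 1e-9.
- Round-tripping an expanded database through CSV is lossless to at least
  1e-6 (values written at full precision).
- Decimal parsing accepts both `.` and the middle dot `·` found in printed
  source tables.
- Degenerate inputs are typed errors, not NAs: non-positive weights or
  factors, negative nutrients, water + alcohol above 100 g/100 g,
  percentages outside (0, 100], empty recipes, unknown group keys.

## Problem sizes

The shipped test suite and acceptance script verify the engine against the
independent flattening oracle on 210 seeded composites (three fixtures of
70, depth up to 3) plus the hand-built nested examples, and run the
whole-pipeline checks on databases of roughly 90 foods — sizes chosen so a
full verification pass completes in well under a minute while covering
every route and basis.

## Known limitations

- Sub-group serving sizes within a group are modelled by subgroup tags with
  one denominator each; a guideline release with many sub-group sizes needs
  a correspondingly detailed rule file.
- The label path trusts declared percentages; batch and brand variation is
  out of scope.
- No nutrient recalculation for recipes is attempted — only food-group
  servings, water and alcohol propagate.
- Survey weighting, plant-based diet index scoring and epidemiological
  inference sit above this package's remit: it produces the servings
  database and per-person totals those analyses consume.
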