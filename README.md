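# fopcap

Tools for food-supply surveillance at the intersection of two Canadian
nutrition policies: the mandatory front-of-package (FOP) **'high in'**
labelling regulations and the proposed restrictions on marketing to
children (M2K). The package answers, for a table of packaged foods, the
questions a policy evaluation asks:

* Which products would have to display a 'high in' nutrition symbol for
  saturated fat, total sugars and/or sodium?
* Which products carry child-appealing packaging (CAP) — characters, games,
  playful designs — and how does symbol prevalence compare between CAP and
  non-CAP products?

## The model

A product is exempt (health / technical / practical exemptions) or else
assessed per nutrient at a percent-daily-value threshold

```
%DV = 100 * amount_at_basis / daily_value,   basis = max(serving size, reference amount)
```

against a tier threshold: **10 %DV** for small-format products (reference
amount or serving size ≤ 30 g), **15 %DV** for most foods, **30 %DV** for
main dishes with reference amount ≥ 200 g (≥ 170 g for toddler foods). A
product meeting or exceeding any threshold displays the symbol, listing
however many nutrients it is 'high in' (0–3). Default daily values
(standard age group): 20 g saturated fat, 100 g total sugars, 2300 mg
sodium. A package displaying ≥ 1 coded child-appealing marketing technique
is CAP, with a marketing power score equal to the number of distinct
techniques. CAP vs non-CAP symbol prevalence is compared with a two-sided
Fisher exact test (probability-mass rule), overall and per TRA
subcategory, because category strata often have low expected counts.

## Worked example

```r
library(fopcap)

cfg    <- preset_flip_like(seed = 1)       # 20-category synthetic supply, n = 5850
run    <- run_pipeline(config = cfg, m2k = m2k_policy(), out_dir = "reports")
glance(run$summary)
#> # A tibble: 1 × 7
#>       n n_cap cap_prevalence_pct cap_displays_pct noncap_displays_pct overall_displays_pct  p_value
#>   <int> <int>              <dbl>            <dbl>               <dbl>                <dbl>    <dbl>
#> 1  5850   730               12.5             78.1                63.7                 67.6 3.54e-11
```

Read: of 5850 synthetic products, 730 (12.5 %) carry child-appealing
packaging; 78.1 % of those would display a 'high in' symbol versus 63.7 %
of non-CAP products (Fisher p ≈ 4e-11), because the generator's CAP arms
are sugar-enriched. `run_pipeline()` also writes `table3.tsv` (symbol
prevalence by category), `table4.tsv` (exempt/0/1/2/3 threshold counts),
`table5.tsv` (per-nutrient tallies), `summary.json` and `manifest.json`.

Individual stages compose with the pipe:

```r
supply <- read_products("products.csv")          # schema: product_columns()
fop    <- evaluate_products(supply, fop_policy())
cap    <- classify_cap(supply)
summarize_supply(supply, fop, cap) |> table_symbol()
```

`autoplot()`, `plot_threshold_counts()` and `plot_nutrient_prevalence()`
give ggplot views of a summary; `evaluate_m2k()` screens the same products
against the stricter proposed M2K criteria (6/5/10 %DV for
sodium/sugars/saturated fat).

Published surveillance tallies can be cross-checked without any data file:
`verify_reference_tallies()` recomputes every headline percentage and the
overall Fisher test from the published integer count tables and compares
them to the printed values.

See the methods vignette (`vignettes/fop-cap-methods.Rmd`) for the decision
model, the tie-break and rounding conventions, and what the synthetic
generator does and does not emulate.

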