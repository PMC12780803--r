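---
title: "Methods: the 'high in' decision engine and the CAP comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the 'high in' decision engine and the CAP comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fopcap)
```

## The problem

Canada's front-of-package (FOP) labelling regulations require pre-packaged
foods that meet or exceed percent-daily-value (%DV) thresholds for the three
nutrients-of-concern — saturated fat, total sugars and sodium — to display a
'high in' nutrition symbol. A separate proposed policy would restrict
marketing to children (M2K) at stricter nutrient criteria, but neither policy
currently covers child-appealing packaging (CAP): characters, games and
playful graphic design printed on the package itself. fopcap implements the
full analytic chain used to quantify that policy gap in food-supply
surveillance data: evaluate every product against the FOP regulation,
classify CAP from coded marketing techniques, and compare symbol prevalence
between the CAP and non-CAP arms with exact contingency-table statistics.

## The decision model

For each product the engine applies, in order:

1. **Exemption screening.** Health, technical and practical exemptions each
   remove a product from the assessment entirely; an exempt product never
   displays a symbol regardless of its nutrient levels. When several flags
   are present the *reported reason* follows the fixed precedence
   health > technical > practical; the precedence can never change the
   exempt/non-exempt outcome, only the label attached to it. Exemption
   status is an input flag coded with the data (the calcium-content test
   behind the expanded dairy exemption would require calcium data the
   schema does not carry).

2. **Scaling basis.** Amounts in a Nutrition Facts table are per stated
   serving. The regulation assesses the *greater* of the stated serving size
   and the regulated reference amount (RA), so per-serving amounts are
   scaled linearly by `basis / serving_size`. Linear scaling assumes
   nutrient homogeneity, the only assumption available when per-serving
   declarations are the sole data. When no serving size is stated the RA is
   the only basis and amounts are used unscaled.

3. **Tier selection.** Main dishes with RA ≥ 200 g (170 g for foods intended
   for children one to under four years) are screened at 30 %DV; products
   whose RA (or serving size when no RA exists) is ≤ 30 g at 10 %DV; all
   other products at 15 %DV. All boundaries are inclusive. Where the
   small-format wording "reference amount or serving size" could conflict,
   the engine gives the RA primacy, matching the regulation's framing of
   small-format products by reference amount; this is a deliberate
   resolution of an ambiguity, exposed through `select_tier()` so users can
   audit it.

4. **Threshold test.** A nutrient is 'high in' when its unrounded %DV is
   **greater than or equal to** the tier threshold ("meeting and/or
   exceeding"). Whether regulators round the %DV before comparing is not
   publicly specified; comparison of unrounded values is the default, with
   an opt-in pre-rounding hook (`fop_policy(round_pct_dv = )`) for
   sensitivity analyses. A missing nutrient amount yields a *missing* flag:
   it is never imputed to zero (which would silently suppress symbols) and
   never counts toward `n_high`.

Daily values are configuration, not code. The shipped defaults are the
Canadian DVs for standard products — 20 g saturated fat, 100 g total sugars,
2300 mg sodium — and no default is provided for the toddler age group: a
supply containing `young_child` products fails loudly until the user supplies
those DVs, because silently reusing adult DVs would misclassify toddler
foods.

The M2K screen (`evaluate_m2k()`) applies fixed thresholds of 6 %DV sodium,
5 %DV sugars and 10 %DV saturated fat with no tiers and no exemptions, on
the same greater-of-the-two basis. Basis reuse is a package choice — the
M2K proposal does not spell out its scaling basis — and since every M2K
threshold is at most every FOP tier threshold, a product clean under M2K can
never display a FOP symbol; this dominance is enforced by a property test.

## CAP classification

The validated package-coding instruments for child-appealing marketing are
represented by their decision rule: a package displaying **one or more**
recognized techniques is CAP, and the marketing power score is the count of
distinct techniques. `classify_cap()` intersects each product's coded
techniques with a user-extensible inventory; unknown codes are ignored and
logged rather than failing, because coded datasets routinely carry codes
from newer instrument revisions. No image analysis is attempted — technique
presence is pre-coded input, as in the manual-coding workflow the package
supports.

## Comparative statistics

Per TRA subcategory and overall, `summarize_supply()` tallies each arm's
exempt / 0 / 1 / 2 / 3 threshold counts, symbol counts and per-nutrient
'high in' counts, and compares symbol prevalence between arms with a
two-sided Fisher exact test — chosen over asymptotic tests because many
category strata have low expected counts. The p-value uses the
probability-mass rule (sum of the probabilities of all margin-fixed tables
no more probable than the observed one), with a relative tolerance of 1e-7
for floating-point ties — the dominant convention, and the one
`stats::fisher.test` follows, which serves as an independent cross-check in
the test suite while the package computes its own enumeration. Degenerate
margins return p = 1 by convention. The sample odds ratio `(ad)/(bc)` is
reported descriptively only (`Inf` with a zero denominator cell, `NA` when
both diagonals vanish); no conditional-MLE estimate, mid-p variant or r×c
generalization is attempted.

Reporting conventions: percentages are rounded half-up (not banker's) to one
decimal, the convention that reproduces every published surveillance
percentage; exempt products sit in the "no symbol" column of the Fisher
table but are also tallied separately, and an exempt-excluded p-value is
emitted alongside since published reports leave that choice implicit. No
multiple-testing adjustment is applied across category strata by default
(matching surveillance practice); `p_adjust = "holm"` adds one.

## The synthetic supply generator

Real branded-food databases (such as the University of Toronto FLIP
database this package's schema mirrors) are proprietary, so every pipeline
stage is exercised against `generate_supply()`. Each category draws:

* a truncated-normal stated serving size (positive, rounded to 0.1 g);
* per-serving lognormal nutrient amounts — strictly positive and
  right-skewed, the characteristic shape of food-composition data;
* a Bernoulli CAP indicator at the category's prevalence; CAP products
  receive at least one technique from the inventory and a multiplicative
  shift (`cap_sugar_effect`) on their sugars median, emulating the
  well-replicated sugars enrichment of child-marketed foods. Enrichment is
  applied to sugars only by default; analogous multipliers exist for the
  other nutrients;
* independent Bernoulli exemption flags per class.

Categories are generated on isolated RNG substreams keyed by (seed,
category index), so a fixed seed reproduces the supply exactly and editing
one category's spec never perturbs another's draws. Substreams are
per-category rather than per-field: that is the granularity the
reproducibility property actually requires, and it keeps the generator a
straightforward vectorized draw.

`preset_flip_like()` is a 20-subcategory preset at the scale of a national
surveillance sample (5850 products, overall CAP prevalence ≈ 12.8 %), with
high health-exemption rates in the calcium-source dairy categories,
practical exemptions concentrated in syrups/spreads, and a main-dish
category screened at 30 %DV. Its nutrient parameters are *illustrative*:
the true distributions of proprietary databases are unpublished, so the
preset is tuned only so the marginal exempt/0/1/2/3 mix is broadly
realistic (within ten percentage points of published surveillance
marginals), not to reproduce any category-level published number. Passing
tests on this preset therefore demonstrate correctness of the *decision
logic and statistics*, not recovery of any real database's results; the
published headline percentages are instead recomputed exactly from their
printed integer count tables by `verify_reference_tallies()`, which is
possible because each published percentage is a deterministic function of
published integers.

## Numerical and degenerate-input choices

* Percent DV comparisons use unrounded doubles with `>=`; the half-up
  report rounding uses an epsilon of 1e-9 to guard against binary
  representation of exact halves.
* Liquids are assumed pre-converted to grams at density 1 g/mL by the data
  producer; the model stores grams only.
* A product must carry at least one of serving size / reference amount;
  validation rejects records with neither basis rather than guessing.
* Empty technique sets serialize as empty CSV cells; technique and
  exemption cells are order-insensitive sets on disk (semicolon-delimited,
  written sorted for byte-stable output).
* The published benchmark tallies contain a one-product discrepancy between
  the prevalence numerator (747) and the CAP arm total (746); both are kept
  as printed, and the pipeline always surfaces its own computed counts.

## Problem sizes used in the test suite

The suite checks engine-oracle equivalence on 1000 preset-drawn products,
Fisher exactness by full enumeration of all 2×2 tables with total ≤ 40
(with spot checks against the reference implementation up to total 200),
type-I calibration of the null CAP-symbol comparison over 2000 replicate
supplies of 2000 products each (attained size within three Monte-Carlo
standard errors of 5 %), and generator parameter recovery at n = 10 000.
These sizes give stable Monte-Carlo behaviour while keeping a full test run
in a few minutes on one CPU.

## Known limitations

* Exemption status is an input; the package does not compute eligibility
  (e.g. the calcium criterion for dairy).
* The generator emulates marginal structure, not the covariance of real
  food supplies (e.g. brand-level clustering, category-correlated serving
  sizes); calibration results on synthetic data do not certify behaviour on
  any particular real database.
* Only the three regulated nutrients-of-concern are modelled; no
  ingredient-list parsing, price data or package imagery.
* Regulatory %DV rounding rules, if any apply before comparison, are not
  implemented beyond the optional rounding hook.
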