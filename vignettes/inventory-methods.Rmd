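---
title: "Methods: an emission-factor inventory for synthetic N fertilizer GHG emissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an emission-factor inventory for synthetic N fertilizer GHG emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfertghg)
```

## The accounting model

`nfertghg` implements a tier-1, emission-factor greenhouse-gas inventory
for synthetic nitrogen fertilizer use on upland wheat and maize. Two
emission pathways are accounted per (province, crop, year) record:

**Manufacture emissions.** Each of the four fertilizer products —
urea, compound fertilizer (CF), diammonium phosphate (DAP) and ammonium
bicarbonate (ABC) — carries a cradle-to-product life-cycle emission
factor $EF_M$ (kg CO~2~-eq per kg fertilizer-N) covering fossil-fuel
mining and transport, ammonia synthesis and product conversion. For a
record with per-product N application rate $NR_p$ (kg N ha^-1^) and
sown area $A$ (ha),

$$E_{M,p} = NR_p \cdot A \cdot EF_{M,p}.$$

The default factors are Chinese industry values: urea 8.1, CF 7.4,
DAP 10.3, ABC 7.2 kg CO~2~-eq kg N^-1^.

**Direct soil N~2~O.** Applied synthetic N stimulates nitrous oxide
emission from the fertilized soil. Following the IPCC inventory method
with region- and crop-specific factors, the summed N rate across all
four products is charged with a single direct emission factor $EF_D$
(kg N~2~O-N per kg N) indexed by (agricultural region, crop), and
44/28 converts N~2~O-N mass to N~2~O mass:

$$E_D = \Big(\sum_p NR_p\Big) \cdot A \cdot EF_D \cdot \tfrac{44}{28}.$$

Synthetic N acts as a class here — the pathway does not distinguish
products — which is why $EF_D$ is applied to the summed rate. The
44/28 ratio is stored as the exact rational evaluated in floating
point, not a rounded 1.571, to avoid avoidable drift.

**CO~2~-equivalence and intensities.** N~2~O is expressed in CO~2~-eq
through its 100-year global warming potential (default 298). The
total, area-scaled and yield-scaled emissions of a record are

$$E = E_M + 298\,E_D, \qquad E/A \;(\text{kg CO}_2\text{-eq ha}^{-1}),
\qquad E/Y \;(\text{kg CO}_2\text{-eq kg grain}^{-1}).$$

A design note: the published formulation of the intensity equations
multiplies the *sum* $(E_M + E_D)$ by 298, which is dimensionally
inconsistent — $E_M$ is already in CO~2~-eq. The package applies the
GWP to the N~2~O term only; this form reproduces every published
national identity exactly (e.g. $52.11 = 41.44 + 35.82 \times 0.298$
Mt CO~2~-eq for wheat), so it is unambiguous that it is what the
published numbers used.

All internal arithmetic is in kg and ha; Mt, Gg and t appear only at
reporting.

## Spatial model

Nineteen provinces partition into five agricultural regions — NEC
(Northeast China), NC (North China), MLYR (middle and lower Yangtze
reaches), NWC (Northwest), SSWC (South and Southwest). Thirteen
provinces grow wheat in the benchmark dataset; all nineteen grow
maize. $EF_D$ exists for every (region, crop) pair except NEC wheat:
that lookup raises a defined "no-factor" error rather than returning
zero, so an NEC wheat activity row parses cleanly but fails loudly at
computation time. Province names are canonicalised ("Shannxi" and
"Shaanxi" are both seen in official statistics and map to the same
province).

Compound fertilizer statistics are reported as total nutrient mass;
with the common N:P~2~O~5~:K~2~O = 1:1:1 formulation, N is one third
of nutrient mass (`cf_n_from_nutrient()`). Activity CSVs carry N
directly, in the units of the manufacture equation.

## Aggregation

Rollups stratify province → region → national. Extensive metrics
(emissions, area, yield) are summed within each year and the yearly
totals averaged over years; the standard deviation is the *sample*
(n−1) SD of the yearly totals, since interannual variation is the
error source the published tables report. With three years, the n−1
versus n choice is material; the sample convention was chosen and the
SD is recomputed at every scope from that scope's yearly totals, not
by summing lower-level SDs. Intensities are never averaged across
provinces: a regional or national intensity is recomputed from the
pooled totals, $\sum E / \sum A$, within each year. This guarantees
the aggregate intensity lies between the provincial extremes, which
the test suite checks.

Rounding to the two decimals of the published tables happens strictly
at render time (`build_report()`); all reconciliation tests run on
unrounded values. Published regional sums occasionally differ from
their column sums by 0.01–0.02 of the last printed digit because the
source rounded before summing; the package sums unrounded values.

Rate-class area fractions (`rate_class_area_fractions()`) bin records
by total N rate into left-closed, right-open intervals, weighted by
sown area, with 50 kg ha^-1^ classes from 0 to 300 plus an open top
class as the default.

## The synthetic-data generator

No machine-readable provincial activity data are deposited with the
benchmark values, so `generate_activity()` emulates their structure:
one record per (province, crop, year), 13 wheat / 19 maize provinces,
three years. Defaults are the published national means — per-product
rates wheat 124/72/17/9 and maize 111/62/15/8 kg N ha^-1^ (the maize
products sum to 196 against a published 197 mean; the per-product
means are used as printed).

Distributional choices, where only means are published, are documented
conventions, not published values:

* per-province rates are normal, truncated at zero, with relative SD
  `rate_cv = 0.25` across provinces — a guess sized to typical
  cross-province dispersion of fertilization intensity;
* year effects are multiplicative, shared within a province across
  crops and products, with relative SD `interannual_cv = 0.05`,
  mirroring the small interannual SDs of the published tables;
* provincial sown areas are log-normal (means sized so national totals
  land near the published 2.33×10^7^ ha wheat and 3.78×10^7^ ha
  maize); per-hectare yields are uniform on 4,000–7,500 kg ha^-1^.

A "figure-1 mode" rescales the areas of records whose total rate falls
in the published anchor class (wheat 200–250 kg ha^-1^, maize
150–200) so those classes hold exactly 42.5% and 64.0% of crop area,
enabling a recovery test of the binning operation.

What passing tests on synthetic data do show: the engine's exact
linearity (EF recovery to <1% by regression), conservation under
aggregation, determinism under a fixed seed. What they do not show:
anything about real provincial heterogeneity, spatial correlation of
rates with area, or reporting errors in the underlying statistics —
the generator draws provinces independently.

## The embedded benchmark fixture

`china_uplands_fixture()` embeds the published national and provincial
benchmark values (2015–2017 averages for Chinese upland wheat and
maize): the default emission factors, national per-product rates and N
consumption (5.18 and 7.45 Mt N), the national-average pseudo-records
whose areas are implied by consumption ÷ mean rate (wheat
5.18×10^9^ ÷ 222 ≈ 2.33×10^7^ ha), and the provincial manufacture and
N~2~O tables. Pseudo-record yields are back-derived from the published
yield-scaled intensities and are marked as implied, not published.
`reconcile_fixture()` recomputes fourteen headline checks — arithmetic
identities, the manufacture recomputation (wheat within 0.5%; maize
within 1%, its printed per-product rates being more coarsely rounded
relative to their sum), intensity recomputations within ±0.01 t
CO~2~-eq ha^-1^, regional sums, and percentage shares to one decimal:

```{r}
rec <- reconcile_fixture()
rec[, c("check", "computed", "expected", "pass")]
```

## Numerical and degenerate-input choices

* Zero yield with nonzero emissions yields a defined `NA` intensity,
  never an infinity; zero emissions at zero yield is 0.
* Validation errors name the offending row and field; unknown
  provinces and missing EFs name the offender.
* The generator restores the caller's RNG state; identical
  seed + config gives a byte-identical CSV.
* Problem sizes in the test suite (1,000-record oracle comparisons,
  ~260 seeded replicates for the rate-convergence check) were chosen
  as the smallest sizes at which the Monte-Carlo checks are stable.

## Limitations

Indirect N~2~O pathways (volatilisation, leaching), background soil
emissions and manure N are out of scope — the inventory covers direct
synthetic-N emissions only. Emission factors are fixed inputs, not
re-estimated; alternative GWP horizons are available only as a
configurable constant. The NEC wheat gap is inherited from the factor
registry: the benchmark dataset simply has no NEC wheat records, and
the package makes that state explicit rather than imputing a factor.
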