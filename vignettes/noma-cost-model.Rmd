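---
title: "The noma cost model: methods, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The noma cost model: methods, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nomacost)
```

## The model

Noma is an acute gangrenous disease of the face that strikes malnourished
children, kills roughly 90% of untreated cases, and leaves survivors
disfigured and socially excluded. Because surveillance is essentially
absent in the affected countries, burden estimation works from a small set
of published indicators rather than case registries. `nomacost`
operationalises a cost-of-illness model for this setting as three layers.

**Prevalence cascade.** From a country's population at risk $P$ (persons
aged 0–29, supplied directly or derived from an age pyramid), an annual
incidence $r$ gives potential cases $\lfloor P r \rfloor$; a care-seeking
fraction $c$ gives cases receiving treatment
$\lfloor \lfloor P r \rfloor c \rfloor$; an untreated-mortality proportion
$m$ gives deaths $\lfloor \lfloor P r \rfloor m \rfloor$. The same
incidence applied to the working-age (15–29) and marriageable-age female
sub-populations yields the cohorts behind the two morbidity-related
indirect costs. Each country-year is an annual snapshot: no cohort ageing,
stage progression or epidemic dynamics are modelled.

**Direct-cost ledger.** Each component of a configurable unit-cost
schedule declares the cohort it applies to (all treated cases, a fraction
of them, or a fixed head count, e.g. the number of patients transferred
abroad) and a unit cost in whole US dollars; its line is the exact product
and the direct total the exact sum. A component may instead carry a
published *override* total; the computed value is retained alongside so
that validation reports the difference rather than silently choosing one.

**Indirect costs (human capital approach).** Lost production values each
working-age potential case at one year of mean income. Premature death
values each untreated death at the mean annual income over the years of
life lost, $\mathrm{YLL} = e_0 - \bar a_d$ (life expectancy at birth minus
mean age at death). Inability to marry values each marriageable-age female
case at the mean dowry and related marriage expenses — in these settings
the forgone dowry is a real economic transfer lost to the family, and
survivors' impaired marriage prospects are one of the best-documented
social consequences of the disease. Intangible costs (pain, stigma,
discrimination) are carried as an explicit `"not computed"` sentinel so no
report can ever print a silent zero for them.

## Parameters and defaults

| Parameter | Units | Bundled value | Rationale |
|---|---|---|---|
| incidence_rate | cases/person-year | 0.0064 | consensus estimate for the noma belt |
| care_fraction | proportion | 0.10 | lower bound of the reported 10–15% of survivors who seek care |
| untreated_mortality | proportion | 0.90 | reported case fatality without treatment |
| mean_age_at_death | years | 6 | centre of the reported 4–7.6-year range |
| at-risk ages | years | 0–29 inclusive | reported age range of occurrence |
| working / marriageable ages | years | 15–29 inclusive | legal working age within the at-risk range |
| discount_rate | per year | 0 | undiscounted human capital is the baseline; discounting is opt-in |

Unit costs are whole dollars per person and live entirely in the
configuration files, with the original Swiss-franc or CFA amounts kept as
provenance notes. One physiotherapy row's native amount implies a
currency-conversion factor inconsistent with every other row; the dollar
figure is treated as canonical and the native amount stored as provenance
only.

## Exact arithmetic and the floor convention

The acceptance surface of this model is a set of printed integers (head
counts and whole-dollar totals), so the package never lets binary floating
point decide a unit. Every rate is rewritten as an exact integer ratio
$\mathrm{num}/10^k$ (`decimal_to_ratio()`), products are kept below
$2^{53}$ where doubles are exact integers, and `floor_count()` repairs the
machine quotient against the exact products. This matters in practice:
products such as $2{,}315{,}625 \times 0.0064 = 14{,}820$ land exactly on
an integer, where a naive `floor()` of the floating product can lose a
unit. The decimal YLL enters dollar totals as
$(\text{deaths} \times \text{income} \times 10\,\mathrm{YLL})/10$, again
exactly. The rounding convention at every cascade stage is *floor*,
pinned by the bundled Niger configuration where $105{,}858.89$ and
$10{,}585.8$ truncate rather than round.

Consequences the user should know: rates must be short decimals (at most
9 fractional digits) and Monte-Carlo draws are rounded to 7 decimals
before entering the model, so the exact floor applies inside every
replicate rather than being approximated around it.

## Design choices

* **Aggregates over pyramids.** The bundled configurations store the
  published at-risk aggregates directly; a full age pyramid is accepted
  but a direct aggregate takes precedence, so no age structure has to be
  invented to reproduce published counts. `derive_population_at_risk()`
  refuses an age range that cuts through a band — no interpolation.
* **Back-computed sub-populations.** The working-age populations (and the
  Niger female marriageable population) are not printed in the source
  tables; the bundled values are back-computed so the floor rule
  reproduces the printed cohort counts, and are labelled as such in the
  YAML provenance notes.
* **Absolute care sub-cohorts.** The published per-component head counts
  (surgery, accommodation, schooling, care abroad) follow no stated
  generating rule, so the configurations pin them as absolute counts; a
  fractional rule exists for synthetic scenarios. A strict invariant
  rejects an absolute count exceeding its base cohort.
* **Overrides are explicit.** One published line total (income-generating
  assistance, Burkina Faso) contradicts its own count × unit cost by 833
  dollars; it ships as a `printed_override` so the direct total matches
  the published sum while `validate_report()` reports the delta.
* **Validation, not reproduction, of source errors.** The published
  tables contain a transposed marriage total (13,365,000 vs the computed
  13,356,000), a direct total 27,000 dollars below the sum of its own
  printed lines (Niger), and a summary table repeating cells across
  countries. Computed values are canonical; every printed cell is stored
  in `inst/extdata/printed_values.csv` and compared cell by cell, with
  non-zero deltas classified `printed_override_used` or `discrepancy`.

## Sensitivity analysis

`one_way()` recomputes a chosen output at each parameter's bounds, holding
the rest at baseline, and ranks swings for a tornado plot. `monte_carlo()`
samples all declared distributions independently per replicate (uniform,
triangular via inverse CDF, or point), reruns the full deterministic model
each time, and summarises the 2.5/50/97.5 percentiles; it is bit-identical
under a fixed seed, which is recorded in the result. The shipped default
distributions are a triangular incidence over the span reported across
field studies (8.3 per 100,000 to 7 per 1000, mode 6.4 per 1000) and a
uniform care fraction on 10–15%; unit costs have no published ranges and
default to point masses. Because fixed absolute sub-cohort counts cannot
follow a perturbed cascade (under a lower incidence they would exceed
their base and trip the strict invariant), sensitivity runs convert them
to equivalent fractions of their baseline base cohort, ceiled at $10^{-7}$
so the baseline is reproduced exactly; set `rescale_counts = FALSE` to
keep them fixed.

## The synthetic-data generator

`generate_profile()` draws a complete country configuration — age
structure as shares of the total (which is all the model consumes),
integer income and unit costs, short-decimal rates — deterministically
from a seed, and records the ground truth. `recovery_check()` then reruns
the full model and verifies every output against closed-form expectations
computed through an independent modular-arithmetic floor; agreement is
exact, with no tolerance. The generator emulates the *statistical shape*
of real inputs, not their dependence structure: incomes, rates and costs
are drawn independently, there is no realistic demographic projection, and
unit costs are independent of incidence. Passing recovery checks therefore
demonstrates that the pipeline computes its defined model exactly — not
that the model's parameter values are right for any real country.

## Problem sizes and test design

All computations are desk scale: a full country report is a few thousand
arithmetic operations and runs in milliseconds. The test suite exercises
the floor oracle on 1000 random cascade inputs, zero-discount equivalence
on 500 random draws, ground-truth recovery on 100 generated profiles, and
Monte-Carlo determinism at 25–30 replicates; the default Monte-Carlo run
uses 1000 replicates (a few tens of seconds) and scales linearly.

## Limitations

The model inherits the limitations of its inputs: incidence estimates for
noma span two orders of magnitude across studies, most derive from
hospital data, and survivors remain hidden, so absolute burden figures are
indicative and likely underestimates. Pre-hospital and traditional-care
costs, prevention programmes, funeral costs, and intangible costs are out
of scope by design. Mean annual income hides the extreme-poverty tail of
the affected households, and the human capital approach values life years
by market income only. The single-year snapshot ignores multi-year
treatment pathways and the lifetime persistence of disability.
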