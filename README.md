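# nomacost

Cost-of-illness modelling for noma (cancrum oris), the gangrenous orofacial
disease of malnourished children in the "noma belt" south of the Sahara.
`nomacost` is aimed at health economists and NTD researchers who need
country-level estimates of the disease's economic and social burden: it
implements a prevalence cascade, a direct-cost ledger, and human-capital
indirect costs, and ships fully specified 2018 configurations for Burkina
Faso and Niger that reproduce the published table values to the unit.

## The model

For a country-year with population at risk $P$ (ages 0–29), the cascade is

$$
C_{\text{pot}} = \lfloor P \cdot r \rfloor,\qquad
C_{\text{tx}} = \lfloor C_{\text{pot}} \cdot c \rfloor,\qquad
D = \lfloor C_{\text{pot}} \cdot m \rfloor
$$

with annual incidence $r$ (6.4 per 1000), care-seeking fraction $c$ (10%)
and untreated mortality $m$ (90%). Every stage floors to whole persons, and
the floor is taken in exact integer arithmetic (rates are rewritten as
integer ratios $\mathrm{num}/10^k$), never in binary floating point.

Costs are split the standard way:

* **Direct costs** — one ledger line per component (treatment, surgery,
  accommodation, psychological care, physiotherapy, income-generating
  assistance, schooling, care abroad): $\text{count} \times \text{unit
  cost}$, summed exactly.
* **Indirect costs** (human capital approach) — lost production
  $C_{15\text{–}29} \cdot \bar{y}$; premature death
  $D \cdot \bar{y} \cdot \mathrm{YLL}$ with
  $\mathrm{YLL} = e_0 - \bar{a}_d$ (life expectancy at birth minus mean age
  at death, e.g. $61.2 - 6 = 55.2$ years); inability to marry
  $C^{F}_{15\text{–}29} \cdot \text{dowry}$ over marriageable-age women.
  An opt-in discounted
  variant is available; the default rate is 0.
* **Intangible costs** — represented by an explicit *not computed* marker,
  never a number.

On top of the deterministic model sit one-way (tornado) and Monte-Carlo
sensitivity analyses, a synthetic country-profile generator with known
ground truth, and cell-by-cell validation against the published tables
(which deliberately surfaces the publication's own internal
inconsistencies as exact deltas instead of reproducing them).

## Worked example

```r
library(nomacost)

report <- build_report(noma_example_config("burkina_faso_2018"))
report
#> <noma_report> Burkina Faso (2018)
#>   potential cases                95,610
#>   receiving treatment             9,561
#>   untreated deaths               86,049
#>   direct costs (USD)         28,179,901
#>   lost_production            19,402,500
#>   premature_death         3,562,428,600
#>   inability_to_marry         13,356,000
#>   intangible costs         not computed
```

Of the 14.9 million Burkinabè aged 0–29, an incidence of 6.4/1000 implies
95,610 potential cases a year, of whom 9561 (10%) receive care; direct care
and social costs total USD 28.2 million, while the 86,049 untreated deaths,
each valued at 55.2 years of lost income at USD 750/year, dominate the
burden at USD 3.56 billion. `tidy(report)` returns the full cost ledger as
a tibble, `glance(report)` a one-row summary, `autoplot(report)` a bar
chart of the lines, and `write_report(report, dir)` the CSV/JSON table
analogues.

Validation against the published tables:

```r
subset(validate_report(report), classification != "match")
# flags the income-assistance line (printed override, delta 833) and the
# published marriage total (delta 9,000), with every other cell matching.
```

Sensitivity:

```r
one_way(noma_example_config("niger_2018"), target = "grand_total")
mc <- monte_carlo(noma_example_config("niger_2018"), replicates = 500, seed = 1)
glance(mc)   # 2.5/50/97.5 percentiles of the total burden
```

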