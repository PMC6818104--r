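---
title: "Interpreting verbal autopsies: the Bayesian engine and the COMCAT sub-model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting verbal autopsies: the Bayesian engine and the COMCAT sub-model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vacomcat)
library(dplyr)
```

## The problem

Where deaths are not medically certified, verbal autopsy (VA) interviews
with final caregivers are interpreted into likely causes of death.
Automated interpreters of the InterVA family treat this as naive-Bayes
classification against an expert knowledge base. Medical cause, however, is
only half of what a health planner needs: a death from obstetric
haemorrhage at home because no transport could be mobilised calls for a
different intervention than the same cause after an unsuccessful facility
admission. The Circumstances Of Mortality CATegories (COMCATs) summarise
that circumstantial dimension in six assignable categories — *traditions*,
*emergencies*, *recognition*, *resources*, *health systems*,
*inevitability* — plus a derived *multiple* category when no single factor
predominates. `vacomcat` implements the per-death engine for both category
sets and the population summaries built on top.

## The model and its assumptions

For a death with substantive responses $r_1,\dots,r_m$ and category set
$C$ with prior $\pi$, the posterior likelihood of category $c$ is

$$
P(c \mid r_1,\dots,r_m) \;=\;
\frac{\pi(c)\prod_{j=1}^{m} P(r_j \mid c)}
     {\sum_{c' \in C} \pi(c')\prod_{j=1}^{m} P(r_j \mid c')} .
$$

The conditional probabilities come from the probbase. The assumptions are
those of any naive-Bayes model: responses conditionally independent given
the category, and a single generating category per death. Three contracts
matter in practice:

* **Missing never updates.** Only substantive yes/no responses contribute
  factors. The WHO instrument's "don't know"/"refused" collapse to missing
  on ingest: the engine consumes substantive responses only. This is a
  documented interpretation — how the original software treats "don't know"
  in its circumstantial sub-model is not stated in public descriptions.
* **`no` is informative only when the probbase says so.** A probbase may
  supply only a `yes` row for an indicator, making negative responses
  non-informative for it; supplying both rows makes `no` a factor of
  $1-P(\text{yes}\mid c)$ or whatever the author encodes. Whether negative
  responses should update is therefore data-driven, not hard-coded.
* **Parallel independence.** The cause model and the COMCAT sub-model run
  on the same record without sharing any state; adding or removing one
  cannot change the other's output. Neither takes year of death as input,
  so any temporal variation in outputs is data-driven.

### The dominance rule

A COMCAT is assigned iff its likelihood **strictly exceeds** the threshold
(default 0.5); exact ties at the threshold, flat distributions and
degenerate (all-zero-mass) records yield *multiple*. Two categories cannot
both exceed 0.5, so the assignment is unambiguous. For causes the engine
reports up to `max_causes` (default 3) causes in descending likelihood
while they stay at or above `report_threshold` (default 0.1); the rest of
the mass is the *indeterminate* residual. The cause-reporting truncation is
a configurable convention, not something the COMCAT design fixes.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.5 | dominance threshold for COMCAT assignment (strict) |
| `max_causes` | 3 | maximum reported causes per death |
| `report_threshold` | 0.1 | minimum likelihood for a cause to be reported |
| `token_map` | see `default_token_map()` | CSV tokens mapping to yes/no/missing |
| age bands | `<5, 5-19, 20-49, 50-69, 70+` | strata for standardisation |
| `per` | 1000 | person-year scale of rates |

## The probbase

A probbase is priors plus a rectangular table of
$P(\text{response} \mid \text{category})$ values in $[0,1]$, authored as
numerals or as grade symbols resolved through a **user-supplied** symbol
table. No default symbol mapping is shipped: the expert consensus matrix
behind the released software is unpublished, and inventing numbers for it
would misrepresent them as consensus values. The packaged
`synthetic_comcat_probbase.csv` is an illustrative, clearly synthetic
matrix over the ten WHO-2016 circumstantial items, good for demonstrations
and tests. Its prior is uniform across the six COMCATs — whether the real
sub-model uses distinct priors is unstated, so uniformity is the neutral
default. Derived categories (*multiple*, *indeterminate*) are never
probbase columns: they are decision-rule outcomes. Whether the
circumstantial sub-model should read only the ten circumstantial items or
all interview indicators is likewise left to the probbase: the engine uses
exactly the rows the probbase supplies.

## Numerical choices

* Products are accumulated in log space throughout, so interviews with
  hundreds of indicators cannot underflow; zero conditionals become
  $-\infty$ and annihilate a category exactly. Normalisation happens once
  at the end, which makes the posterior exactly invariant to rescaling all
  of a row's conditionals by a constant.
* A record whose total unnormalised mass is zero is flagged *degenerate*
  and mapped to *multiple* (fully indeterminate for causes) rather than
  erroring, so field datasets process end to end.
* Priors are normalised once on load (idempotently), with the
  pre-normalisation sum retained for audit.
* Count ties in rankings break by the canonical COMCAT order; argmax ties
  only arise below the dominance threshold, where they are irrelevant.
* Ingest is total: every CSV cell maps to exactly one of yes/no/missing,
  with unrecognised tokens coerced to missing and counted, unknown columns
  ignored with a warning, and duplicate record ids rejected — so record
  counts always reconcile.

## Standardisation

"Internally standardised" rates are computed by direct standardisation,
$\sum_s w_s r_s$ over age × sex strata, with the weights taken from the
whole dataset's own person-year distribution (the named procedure is not
defined in public descriptions; this is the package's interpretation, with
death-count weights available as an alternative via
`internal = "deaths"`). Standardised rates are convex combinations, hence
always within the range of the stratum rates. Person-year denominators are
user-supplied, HDSS-style; without them the package reports fractions only
and never fabricates rates.

## The synthetic-data generator

`scenario_spec()` + `generate_probbase()` + `generate_records()` emulate
exactly the statistical structure the engine assumes: a true category per
death drawn from a mixture, responses conditionally independent given that
category, independent missingness, demographics from a configurable
mixture. Each category owns a round-robin *signature* subset of
indicators; a signature indicator's yes-odds under its own category are
`sharpness` times the baseline odds (baseline yes-probability 0.2, so each
signature response shifts the log-odds by about $\log(\text{sharpness})$).
`sharpness = 1` reproduces the degenerate case of identical probbase
columns. Defaults — 500 records, sharpness 20, missingness 0.1, uniform
mixtures over the six COMCATs and over 5 age bands × 2 sexes × years
2012–2016 — were fixed once as a realistic desk-scale scenario: 0.1 is a
typical item-nonresponse level for VA interviews, and 30 indicators at
sharpness 20 give each category a five-indicator signature whose expected
log-likelihood-ratio margin over any competitor is large compared to its
standard deviation, so recovery should approach 1 while the
non-discriminative probbase collapses assignment to *multiple*.

Because the generator satisfies the engine's assumptions by construction,
recovery experiments measure the *engine*, not robustness to model
misspecification; real VA data have correlated indicators, cause-specific
missingness and informative "don't know" patterns that these tests do not
exercise. Passing them shows the inference machinery is correct, not that
any particular probbase is valid in the field.

## Problem sizes

The shipped tests run the engine against an independent brute-force oracle
on 1,000 random small instances (≤5 categories, ≤8 indicators), invariance
sweeps over ~100 random probbases, the 500-death recovery scenario at
sharpness 20 and 1, spreadsheet-checked aggregation on a printed 10-row
fixture, and a byte-identity rerun of the simulate → process → summarize
pipeline. These sizes keep the whole suite under a minute while leaving
the statistical conclusions comfortably clear of their thresholds.

## Known limitations

* The engine does not attempt to bit-match the legacy executable, and no
  attempt is made to reconstruct its expert probability matrix.
* No uncertainty intervals on fractions or rates; no physician-review or
  hierarchical (InSilicoVA-style) estimation.
* The wide-CSV reader expects WHO-2016-shaped exports (one column per
  indicator); long formats and ODK/XML instruments are out of scope.
* Cause labels map to broad groups through a user-editable table; the
  packaged table is illustrative, not an official mapping.
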