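# vacomcat

Bayesian interpretation of verbal autopsies with Circumstances Of Mortality
CATegories (COMCATs).

In settings without routine medical certification of deaths, **verbal
autopsy (VA)** — a structured interview with witnesses of a death — is the
pragmatic route to cause-of-death statistics. Automated interpreters of the
InterVA family process each interview with a naive-Bayes model driven by a
**probbase**: a matrix of expert-derived conditional probabilities linking
each indicator response to each cause. Beyond the medical cause, the
*circumstances* of a death (could care be reached? was the danger
recognised? was anything avertable at all?) matter directly to health
planners. `vacomcat` implements the full pipeline: the per-death Bayesian
engine over any category set, the parallel **COMCAT sub-model** over six
circumstantial categories with its dominance rule, and the population-level
summaries (CSMFs, COMCAT fractions, sex splits, person-year rates,
internally age/sex standardised rates) used to report such analyses. It is
aimed at researchers working with HDSS or CRVS mortality data and at anyone
studying InterVA-style inference itself.

## The model

For death *i* with substantive responses \(r_1, \dots, r_m\) (yes/no;
missing responses contribute nothing) and a category set \(C\) with prior
\(\pi\), the engine computes

```
P(c | r_1..r_m)  ∝  π(c) · Π_j P(r_j | c)
```

with the conditional probabilities \(P(r_j \mid c)\) taken from the
probbase. Likelihoods are normalised per death; products are accumulated in
log space so long interviews cannot underflow.

Two category sets are processed independently per death:

* **Causes**: ranked causes are reported while their likelihood stays above
  a reporting threshold (default 0.1, at most 3 causes); the remaining mass
  is the **indeterminate** residual.
* **COMCATs**: traditions, emergencies, recognition, resources, health
  systems, inevitability. The **dominance rule** assigns a single COMCAT
  only when its likelihood strictly exceeds 50%; otherwise the derived
  seventh category **multiple** applies.

Population summaries follow standard demographic practice: category
fractions over complete partitions, stratum rates per 1,000 person-years,
and direct standardisation with internal weights (the dataset's own
age × sex person-year distribution).

The expert consensus probability matrix of the original software is not
published; the package ships a clearly labelled *synthetic* COMCAT probbase
for the ten WHO-2016 circumstantial items (`Id10450`–`Id10459`) and accepts
any user-supplied probbase, including symbol-graded ones with a
user-supplied symbol table.

## Worked example

```r
library(vacomcat)

pb <- read_probbase(system.file("extdata", "synthetic_comcat_probbase.csv",
                                package = "vacomcat"), set_name = "comcats")
rec <- tibble::tibble(
  record_id = c("D001", "D002", "D003"),
  age_group = c("20-49", "70+", "<5"), sex = c("male", "female", "female"),
  year = 2014L,
  Id10450 = c("no", "yes", "yes"),      Id10451 = c("no", "yes", "yes"),
  Id10452 = c("missing", "yes", "no"),  Id10453 = c("missing", "yes", "no"),
  Id10454 = c("missing", "yes", "no"),  Id10455 = c("yes", "no", "no"),
  Id10456 = c("no", "no", "yes"),       Id10457 = c("yes", "no", "no"),
  Id10458 = c("no", "yes", "yes"),      Id10459 = c("yes", "no", "no"))

res <- va_process(rec, pb)
dplyr::select(res, record_id, comcat, comcat_lik_resources,
              comcat_lik_health_systems, comcat_lik_recognition)
#>   record_id comcat         comcat_lik_resources comcat_lik_health_systems comcat_lik_recognition
#> 1 D001      resources                0.766                      0.000639               0.0117
#> 2 D002      health_systems           0.00000257                 0.999                  0.0000315
#> 3 D003      multiple                 0.00166                    0.0309                 0.460
```

D001 never reached a facility, lived over two hours away, used traditional
medicine and faced prohibitive costs: the *resources* likelihood (0.77)
exceeds 50%, so that COMCAT is assigned. D002 reached a facility but
reported problems with admission, treatment and medications: *health
systems* at 0.999. D003's likelihoods split between *recognition* (0.46)
and *inevitability* (0.43) — nothing dominates, so the derived *multiple*
category applies.

```r
glance(res)
#>   n_deaths n_multiple multiple_rate n_degenerate mean_updates max_likelihood_mean
#> 1        3          1         0.333            0            9               0.742
```

`tidy(res)` returns the full long posterior; `autoplot(res)` draws the
COMCAT distribution; `category_fractions()`, `stratum_rates()`,
`standardize_rates()` and `comcat_by_cause_ranking()` build the population
tables.

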