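---
title: "Model structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petcea)
```

## The decision problem

Patients with biochemically recurrent (BCR) prostate cancer — a rising PSA
after prostatectomy (≥ 0.20 ng/mL) or radiation (≥ 2.0 ng/mL) without
radiographic disease — face a choice of restaging imaging. PSMA-PET detects
metastatic disease that conventional CT plus bone scintigraphy (CTBS)
misses, but triggers earlier use of expensive systemic therapy. `petcea`
implements a decision-analytic model that quantifies this trade-off for
three strategies: up-front PSMA-PET, PSMA-PET as a reflex test after
negative CTBS, and CTBS alone. Outcomes are discounted lifetime
quality-adjusted life-years (QALYs) and costs (2023 USD) from a payer
perspective, compared on the incremental cost-effectiveness frontier at a
willingness-to-pay threshold of $150,000/QALY with 3% annual discounting.

## Decision tree

PSMA-PET is treated as the criterion standard: true disease prevalence
*equals* its detection probability, and the PSMA-PET arm has no false
classifications. For CTBS, sensitivity and specificity split the cohort
into true/false positives/negatives; the localized share among
CTBS-detected disease uses the CTBS-conditional proportion (3.42%), while
undetected (false-negative) disease keeps the criterion-standard
localized/metastatic composition, obtained by subtraction. Three
assumptions the model inherits from its source and keeps:

* false positives receive the same treatment or monitoring as true
  positives (they enter the same treated states);
* false negatives are managed like true negatives (they enter the
  "no radiographic disease" state);
* a single imaging event — imaging costs are charged once at cycle 0, and
  in the reflex strategy PSMA-PET is charged only for the CTBS-negative
  fraction.

Two splits are not published and are package decisions: the
localized/metastatic composition of CTBS false *positives* reuses the
criterion-standard split, and the localized and metastatic treated masses
are distributed over treatment states with placeholder proportions (below).

## Markov model

Ten mutually exclusive health states: (1) no radiographic disease, (2–4)
localized disease under no/local/systemic treatment, (5) no radiographic
disease after local treatment, (6–7) metastatic disease under ADT+ARSI or
metastasis-directed therapy, (8) metastatic castration-resistant disease
(mCRPC), (9) prostate-cancer death, (10) death from other causes. The
permitted transitions (see `transition_adjacency()`): state 1 may develop
localized or metastatic disease; localized states may progress to
metastatic; only state 3 may clear to state 5; state 5 is at risk of
metastasis (annual probability 2.27%); only state 8 reaches state 9;
metastatic states never revert. Background mortality applies to every
living state.

**Cycle length and horizon.** Monthly cycles (the source does not state a
cycle length; a month resolves early progression dynamics), lifetime
horizon capped at age 100, cohort entering at the median age of 66. Annual
probabilities convert by `1 − (1 − p)^(1/12)`.

**Competing risks.** Background mortality is applied first each cycle;
disease transitions act on the survivors
(`M(t) = q(t)·[→10] + (1 − q(t))·P_disease`). The disease matrix is
age-independent, so it is built once per pathway — this is also what makes
10,000-draw probabilistic analysis affordable in pure R.

**Background mortality.** No specific life table is cited by the source;
the package ships a synthetic Gompertz approximation of recent US male
mortality (`make_life_table()`, hazard `3.4e-5·exp(0.092·age)`), swappable
through `cea_settings()`.

**Hazard-ratio modifiers.** Hazard ratios are applied on the log-survival
scale, `p' = 1 − (1 − p)^hr`. Disease detected by PSMA-PET carries the
early- vs delayed-treatment hazard ratio (0.56) on the progression
transitions (localized→metastatic and metastatic→mCRPC); CTBS-detected
disease is the delayed reference (hazard 1). CTBS false negatives carry the
increased-progression hazard ratio (1.79).

A structural decision deserves emphasis: the false-negative hazard ratio
**persists on all progression transitions of that pathway** (exit from
state 1 and the downstream progression steps). Under the narrower reading —
the penalty applying only until the disease becomes radiographically
evident — the false-negative pathway would accrue *more* QALYs than early
PSMA detection, because it combines an untreated sojourn at utility 0.90
and zero cost with an identical downstream course; earlier detection could
then never dominate, contradicting both the source's directional findings
and clinical expectation. The persistent reading encodes lastingly worse
prognosis from delayed treatment; under the reflex strategy the
false-negative hazard is replaced by the early-detection hazard at cycle 0,
when reflex PSMA-PET reclassifies those patients. In the reflex strategy
the early-detection benefit applies only to the reflex-detected (former
false-negative) patients, not to CTBS-positives — which is why that
strategy combines the highest imaging cost with intermediate health
outcomes. The metastasis-directed-therapy hazard ratio multiplies the
progression hazard of state 7.

The state-5 metastasis probability keeps its baseline hazard in every
pathway: the early/delayed contrast concerns detection of the *presenting*
disease, not recurrence after successful local salvage.

## Economic accumulation

Utilities are state weights per year; QALYs and recurring costs integrate
over the trace with trapezoidal (half-cycle) weighting and
`(1.03)^(−t)` discounting. One-off costs — imaging at cycle 0, the local
salvage procedure on entry to state 3 (mean of prostatectomy, radiation
and cryotherapy), the metastasis-directed procedure on entry to state 7 —
are discounted at the entry time but not half-cycle corrected (standard
practice; the source is silent). Recurring costs: state 4 ADT; state 6
ADT + ARSI; state 7 ADT; state 8 ADT plus a 50/50 ARSI/docetaxel mix (the
mCRPC cost recipe is not published; the share is the `share_mcrpc_arsi`
parameter). ADT and ARSI costs are treated as annual, matching their
source's framing.

## Input distributions

Probabilities and utilities get beta distributions, costs gamma, hazard
ratios lognormal, all by moment matching with
`sd = (UI_high − UI_low)/(2·1.96)`; costs without a published interval use
a 20% coefficient of variation. Exact quantile matching was rejected —
printed intervals carry rounding error that moment matching tolerates
better. Lognormal fits anchor the *median* at the printed hazard ratio;
the 0.56 (0.49–0.92) interval is strongly asymmetric on the log scale, the
source does not say how it was parameterised, and we take the log-width
rather than guess. Draws are independent across parameters (no correlation
structure is published); categorical blocks (the localized/metastatic
split, which prints as 100.03% from rounding, and the treatment
proportions) are renormalized at the point of use, which is equivalent to
renormalizing after sampling.

## Placeholder inputs

Baseline progression probabilities between Markov states, mCRPC mortality,
the treatment-distribution proportions, the metastasis-directed-therapy
hazard ratio and the mCRPC cost recipe appear only in the source's
supplementary material or cited literature. They ship as `"placeholder"`
rows in `reference_parameters()`, chosen once on clinical grounds and not
revisited:

* metastatic→mCRPC 0.20/year (median ≈ 3 years to castration resistance
  under intensified androgen-axis therapy);
* mCRPC death 0.30/year (median overall survival ≈ 2.5 years);
* developing radiographic disease from state 1, 0.15/year (BCR cohorts
  with negative imaging progress to radiographic disease over ≈ 3–5
  years);
* localized progression 0.15/0.08/0.10 per year for no/local/systemic
  treatment; salvage success (state 3→5) 0.25/year;
* treatment distributions 20/60/20% (localized) and 80/20% (metastatic);
* metastasis-directed-therapy hazard ratio 0.60 (0.40–0.90), consistent
  with randomized ADT-free-survival effects of metastasis-directed
  therapy.

Every probabilistic or deterministic result computed from the reference
set is conditional on these values; they are flagged in the parameter
table's provenance column, and utilities/QALYs remain clinically ordered
(disease-free > localized > metastatic > mCRPC) under them.

## Probabilistic and value-of-information analysis

One parameter draw drives all three strategies per iteration (common
random numbers), 10,000 iterations by default. The acceptability curve is
the fraction of draws in which each strategy maximises net monetary
benefit. EVPI is `E[max NMB] − max E[NMB]`; QALY-denominated values divide
by the threshold. Grouped EVPPI uses the four published groups
(1 diagnostics, 2 disease characteristics, 3 imaging and treatment costs,
4 utility values), taken verbatim from the source table — including its
arguably surprising placement of the progression hazard ratios in the
diagnostics group; group labels for placeholder rows are package
assignments by kind. The default estimator regresses per-strategy NMB on
the group's parameters with additive `mgcv::gam` smooths over the existing
draws; nested two-level Monte Carlo is retained as the validation oracle
and agrees with the regression estimator on analytic toys (both are
checked against the closed form `E[max(0, S)] = μΦ(μ/σ) + σφ(μ/σ)`).

Value-of-information summaries default to the PSA < 2 ng/mL stratum: the
published decision-uncertainty peak ($115,000/QALY), the 52.6% acceptability
at that threshold and the group labels on the low-PSA rows all tie the VOI
analysis to that population. Population scaling counts the prevalent
cohort (50,000) undiscounted at time zero and discounts ten yearly
incident cohorts (40,000/year) from year 1:
`per-person × (50,000 + 40,000·Σ_{t=1..10} 1.03^{−t})`. The source does
not print its accrual convention, so population VOI is reproducible only
in order of magnitude; the convention is configurable.

## What the synthetic data do and do not establish

The test-suite's generators — the reference transcription, degenerate
scenarios (`no_uncertainty`, `perfect_ctbs`, `hr_neutral`, `immortal`) and
the multinomial micro-simulator that revalidates the cohort engine against
the same transition matrices — exercise internal consistency: mass
conservation, structural adjacency, hazard-ratio algebra, dominance logic,
information inequalities, seed determinism. A green suite establishes that
the machinery computes what the model definition says, *not* that the
placeholder inputs equal the source's supplementary values; the published
probabilistic results are therefore tracked with deliberately wide,
pre-registered bands and flagged as conditional.

## Numerical choices and edge cases

* Beta fits reject intervals too wide for the stated mean (implied
  concentration ≤ 0); zero-width intervals collapse to fixed specs.
* `adjust_probability(1, hr)` is rejected: a certain event has no finite
  rate.
* Transition rows whose forced probabilities exceed 1 raise an error
  rather than being silently renormalized.
* Frontier ties break by lower cost, then higher QALYs, then label, so
  output is deterministic and order-invariant.
* The per-draw pipeline aborts with the draw index if any draw produces an
  invalid matrix.
* Seeds: every stochastic entry point takes an explicit integer seed and
  restores the caller's RNG state.

## Known limitations

Single imaging event (no re-imaging of false negatives); no equivocal
reads; no individual-level heterogeneity beyond the classification
pathways; no adverse-event disutilities or societal costs; no correlated
sampling or Bayesian calibration; radioligand-therapy pathways are out of
scope. The placeholder inputs are the dominant caveat: stratified and
probabilistic conclusions transfer to the published setting only insofar
as those inputs approximate the supplementary values.
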