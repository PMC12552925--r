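# petcea

Cost-effectiveness and value-of-information analysis of PSMA-PET imaging
strategies for biochemically recurrent (BCR) prostate cancer.

## What this package is for

Patients whose PSA rises after definitive prostate-cancer treatment face a
restaging choice: PSMA-PET detects metastatic disease that conventional CT
plus bone scintigraphy (CTBS) misses, but earlier detection triggers earlier
— and costly — systemic therapy. `petcea` implements a decision-analytic
model for health-economics researchers who want to reproduce, stress-test or
extend this evaluation: a diagnostic-accuracy decision tree feeding a
ten-state Markov cohort model, compared across three strategies (up-front
PSMA-PET, PSMA-PET as a reflex test after negative CTBS, CTBS alone), with
PSA-level-stratified analyses, probabilistic uncertainty analysis and
expected value of (partial) perfect information.

## The model in brief

The decision tree distributes a cohort over true disease status × test
classification. PSMA-PET is the criterion standard, so prevalence equals its
detection probability; CTBS cells follow
`TP = π·se`, `FN = π·(1−se)`, `FP = (1−π)·(1−sp)`, `TN = (1−π)·sp`.
Classified patients enter a Markov model (monthly cycles, lifetime horizon)
over states: no radiographic disease; localized disease (no/local/systemic
treatment); disease-free after local treatment; metastatic disease
(ADT+ARSI or metastasis-directed therapy); mCRPC; cancer death; other-cause
death. Hazard ratios act on the log-survival scale,
`p' = 1 − (1 − p)^HR`: 0.56 for PSMA-detected (early-treated) progression,
1.79 for CTBS false negatives, and a metastasis-directed-therapy effect on
the state-7 progression hazard. Discounted lifetime QALYs and costs
accumulate with half-cycle correction,

```
QALY = Σ_t w_t (1.03)^(−t) Σ_s occ(t,s) u(s) Δt ,
```

strategies are ranked on the ICER frontier with strong and extended
dominance, and decision uncertainty is summarised by acceptability curves,
`EVPI = E[max_s NMB_s] − max_s E[NMB_s]` and regression-based grouped EVPPI
(net monetary benefit `NMB = λ·QALY − cost`).

Inputs ship as a transcribed parameter table (beta for probabilities and
utilities, gamma for costs, lognormal for hazard ratios, fitted from point
estimate + 95% interval by moment matching; 20% CV for costs without an
interval). Inputs only available in the source's supplementary material are
clearly marked `placeholder` — see the methods vignette
(`vignettes/methods.Rmd`) for what is published, what is assumed, and why.

## Worked example

```r
library(petcea)
res <- run_deterministic(reference_parameters(), strata = c("base", "lt2"))
res[, c("strategy", "cost", "qaly", "icer", "status", "cost_effective", "stratum")]
```

```
        strategy   cost  qaly   icer           status cost_effective stratum
            CTBS 288411 5.952     NA      on_frontier           TRUE    base
  CTBS_PLUS_PSMA 378270 6.318     NA weakly_dominated          FALSE    base
        PSMA_PET 408296 6.743 151469      on_frontier          FALSE    base
            CTBS 277037 6.431     NA      on_frontier          FALSE     lt2
  CTBS_PLUS_PSMA 338805 6.821     NA weakly_dominated          FALSE     lt2
        PSMA_PET 360900 7.204 108552      on_frontier           TRUE     lt2
```

Read: at the point estimates, up-front PSMA-PET buys ~0.8 additional
discounted QALYs over CTBS at ~$120k extra cost. Pooled over all PSA levels
its ICER (~$151k/QALY here) sits at the $150,000/QALY threshold, so CTBS is
(marginally) the cost-effective choice; in the PSA < 2 ng/mL stratum the
ICER falls to ~$109k/QALY and PSMA-PET becomes cost-effective — the same
qualitative conclusion as the published analysis. The reflex strategy is
never on the frontier. Probabilistic analogues:

```r
psa <- run_psa(reference_parameters(), n_draws = 10000, seed = 1, stratum = "lt2")
psa_summary(psa)           # means + 95% uncertainty intervals
ceac(psa, 150000)          # probability each strategy is cost-effective
population_voi(evpi(psa, 115000)$evpi_qaly)  # population EVPI in QALYs
```

A command-line front end lives at `inst/cli/petcea`
(`deterministic | psa | voi | fixtures` subcommands).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the installed package: the worked-example ICERs from the
shipped published summary estimates (low-PSA ICER after $1,000 rounding;
the minimum ICER of the two higher-PSA strata), and — from two fresh
10,000-draw probabilistic runs — the pooled-population ICER and PSMA-PET
mean QALYs, the probability PSMA-PET is cost-effective at $150,000/QALY
(pooled and PSA < 2), and the population EVPI in QALYs at $115,000/QALY.
Results are written as JSON keyed `t1`–`t7`; all randomness derives from
`--seed`. Takes roughly 10 minutes on one CPU.
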