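#' Degenerate test scenarios
#'
#' Named analytic limits used throughout the test-suite:
#' \describe{
#'   \item{`no_uncertainty`}{every distribution collapsed to its point
#'     estimate; downstream EVPI must be exactly zero.}
#'   \item{`perfect_ctbs`}{CTBS sensitivity and specificity fixed at 1; all
#'     three strategies then produce identical initial state vectors (only
#'     imaging costs differ).}
#'   \item{`hr_neutral`}{all three progression hazard ratios fixed at 1;
#'     detected-cohort traces coincide across strategies.}
#'   \item{`immortal`}{disease mortality switched off (mCRPC death
#'     probability 0); combined with a zero life table this gives closed-form
#'     annuity checks.}
#' }
#'
#' @param kind One of the four labels above.
#' @param seed Optional seed stored with the scenario.
#' @return A `scenario_spec`: list with `kind`, `overrides` (parameter name
#'   to fixed value) and `seed`.
#' @export
degenerate_scenario <- function(kind, seed = 1L) {
  kind <- match.arg(kind,
                    c("no_uncertainty", "perfect_ctbs", "hr_neutral",
                      "immortal"))
  overrides <- switch(kind,
    no_uncertainty = list(),
    perfect_ctbs = list(sens_ctbs = 1, spec_ctbs = 1),
    hr_neutral = list(hr_early = 1, hr_false_negative = 1, hr_mdt = 1),
    immortal = list(p_mcrpc_death = 0)
  )
  structure(list(kind = kind, overrides = overrides, seed = seed),
            class = "scenario_spec")
}

#' Apply a scenario to a parameter set
#'
#' Overridden parameters become `fixed` at the override value (in every
#' stratum where they appear); under `no_uncertainty` every parameter is
#' fixed at its point estimate.
#'
#' @param set A `parameter_set`.
#' @param scenario A [degenerate_scenario()] or a plain named list of
#'   overrides.
#' @return A modified `parameter_set`.
#' @export
apply_scenario <- function(set, scenario) {
  overrides <- if (inherits(scenario, "scenario_spec")) scenario$overrides
               else scenario
  fix_all <- inherits(scenario, "scenario_spec") &&
    scenario$kind == "no_uncertainty"
  unknown <- setdiff(names(overrides),
                     vapply(set$parameters, `[[`, "", "name"))
  if (length(unknown)) {
    stop("override(s) reference unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  }
  for (key in names(set$parameters)) {
    p <- set$parameters[[key]]
    if (p$name %in% names(overrides)) {
      v <- overrides[[p$name]]
      p$spec <- dist_spec("fixed", v, v, v)
    } else if (fix_all) {
      pe <- p$spec$point_estimate
      p$spec <- dist_spec("fixed", pe, pe, pe)
    }
    set$parameters[[key]] <- p
  }
  set
}
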