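#' Imaging strategies under comparison
#'
#' Three diagnostic strategies for biochemically recurrent prostate cancer:
#' `"PSMA_PET"` (up-front PSMA-PET without conventional imaging),
#' `"CTBS_PLUS_PSMA"` (PSMA-PET as a reflex test when conventional CT + bone
#' scintigraphy is negative or equivocal), and `"CTBS"` (conventional imaging
#' alone). PSMA-PET is treated as the criterion-standard modality: true
#' disease status is defined by its result, so the PSMA-PET arm has no false
#' classifications.
#'
#' @return Character vector of the three strategy labels.
#' @export
strategies <- function() c("PSMA_PET", "CTBS_PLUS_PSMA", "CTBS")

.true_states <- c("no_disease", "localized", "metastatic")
.classes <- c("true_pos", "true_neg", "false_pos", "false_neg")

# normalize a probability block that should sum to one (published splits sum
# to 100.03% through rounding; sampled draws are renormalized the same way)
.norm_block <- function(x) {
  s <- sum(x)
  if (s <= 0) stop("degenerate probability block (sum <= 0)")
  x / s
}

.get <- function(values, name) {
  i <- match(name, names(values))
  if (is.na(i)) stop("missing parameter value: ", name)
  v <- values[[i]]
  if (is.na(v)) stop("missing parameter value: ", name)
  v
}

#' Distribute the cohort over disease status and test classification
#'
#' Applies the diagnostic decision tree of one imaging strategy. True-disease
#' prevalence equals the PSMA-PET detection probability (criterion-standard
#' assumption). For `"CTBS"`, sensitivity and specificity split the cohort
#' into the four classification cells; the localized share among
#' CTBS-detected disease uses the CTBS-conditional proportion, while the
#' residual false-negative disease keeps the criterion-standard
#' localized/metastatic composition. For `"CTBS_PLUS_PSMA"`, PSMA-PET
#' reclassifies every CTBS-negative patient: false negatives become
#' (early-detected) true positives; CTBS false positives keep the
#' treated-as-positive pathway. Imaging cost is charged once, at cycle 0; the
#' reflex strategy charges PSMA-PET only for the CTBS-negative fraction.
#'
#' @param strategy One of [strategies()].
#' @param values Named numeric vector of parameter values (see
#'   [point_estimates()]), already resolved for a stratum.
#' @param stratum Stratum label carried through to the output.
#' @return An `initial_distribution`: list with `masses` (3 x 4 matrix of
#'   true state x classification), `imaging_cost` (per-patient USD at cycle
#'   0), `strategy`, `stratum`. Masses are non-negative and sum to 1.
#' @export
classify_cohort <- function(strategy, values, stratum = "base") {
  strategy <- match.arg(strategy, strategies())
  prev <- .get(values, "p_detect_psma")
  split <- .norm_block(c(.get(values, "p_loc_given_detect"),
                         .get(values, "p_met_given_detect")))
  p_loc <- split[[1]]
  if (prev < 0 || prev > 1) stop("detection probability outside [0,1]")

  m <- matrix(0, 3, 4, dimnames = list(.true_states, .classes))
  cost <- 0
  if (strategy == "PSMA_PET") {
    m["localized", "true_pos"] <- prev * p_loc
    m["metastatic", "true_pos"] <- prev * (1 - p_loc)
    m["no_disease", "true_neg"] <- 1 - prev
    cost <- .get(values, "cost_psma_pet")
  } else {
    sens <- .get(values, "sens_ctbs")
    spec <- .get(values, "spec_ctbs")
    if (any(c(sens, spec) < 0) || any(c(sens, spec) > 1)) {
      stop("CTBS sensitivity/specificity outside [0,1]")
    }
    p_loc_ctbs <- .get(values, "p_loc_given_ctbs_detect")
    tp <- prev * sens
    m["localized", "true_pos"] <- tp * p_loc_ctbs
    m["metastatic", "true_pos"] <- tp * (1 - p_loc_ctbs)
    # composition of the undetected disease: criterion-standard split minus
    # what CTBS found (clipped at zero if the CTBS localized share exceeds it)
    fn_loc <- max(0, prev * p_loc - tp * p_loc_ctbs)
    fn_met <- max(0, prev * (1 - p_loc) - tp * (1 - p_loc_ctbs))
    fn_tot <- prev * (1 - sens)
    fn <- if (fn_loc + fn_met > 0) .norm_block(c(fn_loc, fn_met)) * fn_tot
          else c(0, 0)
    m["localized", "false_neg"] <- fn[[1]]
    m["metastatic", "false_neg"] <- fn[[2]]
    # false positives keep the criterion-standard localized/metastatic split
    # (unspecified in the source; configurable assumption)
    fp <- (1 - prev) * (1 - spec)
    m["no_disease", "false_pos"] <- fp
    m["no_disease", "true_neg"] <- (1 - prev) * spec
    cost <- .get(values, "cost_ctbs")
    reflex_tp <- c(localized = 0, metastatic = 0)
    if (strategy == "CTBS_PLUS_PSMA") {
      # reflex PSMA-PET for all CTBS-negatives; false negatives become
      # early-detected true positives, staged with the criterion-standard
      # split. Their mass is tracked separately because the early-detection
      # hazard ratio applies to them but not to the CTBS-detected patients.
      reflex_fraction <- fn_tot + (1 - prev) * spec
      cost <- cost + .get(values, "cost_psma_pet") * reflex_fraction
      reflex_tp <- c(localized = fn[[1]], metastatic = fn[[2]])
      m["localized", "true_pos"] <- m["localized", "true_pos"] + fn[[1]]
      m["metastatic", "true_pos"] <- m["metastatic", "true_pos"] + fn[[2]]
      m["localized", "false_neg"] <- 0
      m["metastatic", "false_neg"] <- 0
    }
  }
  stopifnot(abs(sum(m) - 1) < 1e-12, all(m >= 0))
  structure(
    list(masses = m, imaging_cost = cost, strategy = strategy,
         stratum = stratum,
         reflex_tp = if (strategy == "CTBS_PLUS_PSMA") reflex_tp else NULL),
    class = "initial_distribution"
  )
}

#' Serialize an initial distribution to JSON
#'
#' @param dist An `initial_distribution`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
initial_distribution_json <- function(dist, path = NULL) {
  stopifnot(inherits(dist, "initial_distribution"))
  obj <- list(strategy = dist$strategy, stratum = dist$stratum,
              imaging_cost = dist$imaging_cost,
              masses = as.data.frame.table(dist$masses,
                                           responseName = "mass"))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.initial_distribution <- function(x, ...) {
  cat(sprintf("<initial_distribution> %s (stratum %s), imaging cost $%.0f\n",
              x$strategy, x$stratum, x$imaging_cost))
  print(round(x$masses, 5))
  invisible(x)
}

# split a diseased mass over the entry states given treatment distributions
.treated_entry <- function(values, loc_mass, met_mass) {
  v <- numeric(10)
  tx_loc <- .norm_block(c(.get(values, "tx_loc_no_treatment"),
                          .get(values, "tx_loc_local"),
                          .get(values, "tx_loc_systemic")))
  tx_met <- .norm_block(c(.get(values, "tx_met_adt_arsi"),
                          .get(values, "tx_met_mdt")))
  v[2:4] <- loc_mass * tx_loc
  v[6:7] <- met_mass * tx_met
  v
}

#' Map a classified cohort to initial Markov state occupancies
#'
#' Patients whose disease was detected (true positives) — and false positives,
#' who receive the same treatment or monitoring as true positives — enter the
#' treated states: localized disease splits over no treatment / local
#' treatment / systemic treatment, metastatic disease over ADT + ARSI /
#' metastasis-directed therapy. True negatives and (undetected) false
#' negatives enter state 1, "no radiographic disease"; the false negatives
#' carry the increased-progression modifier downstream.
#'
#' @param dist An `initial_distribution` from [classify_cohort()].
#' @param values Named numeric parameter values.
#' @return Named list of pathway components, each with `weight` (cohort
#'   fraction), `init` (length-10 state vector summing to 1) and `modifier`
#'   (`"early"`, `"delayed"` or `"false_negative"` — which progression hazard
#'   ratio applies). Pathways with zero weight are dropped. Component inits
#'   weighted by their weights sum to a probability vector over the 10 states.
#' @export
assign_initial_states <- function(dist, values) {
  stopifnot(inherits(dist, "initial_distribution"))
  m <- dist$masses

  pathways <- list()
  add <- function(label, weight, init, modifier) {
    if (weight <= 0) return()
    stopifnot(all(init >= 0), abs(sum(init) - weight) < 1e-9)
    pathways[[label]] <<- list(weight = weight, init = init / weight,
                               modifier = modifier)
  }

  # Disease detected by PSMA-PET carries the early-detection hazard ratio;
  # disease detected by CTBS is the "delayed" reference pathway. In the
  # reflex strategy only the PSMA-reclassified (former false-negative)
  # patients are PSMA-detected; CTBS-positives stay on the delayed pathway.
  tp_loc <- m["localized", "true_pos"]
  tp_met <- m["metastatic", "true_pos"]
  early_loc <- early_met <- 0
  if (dist$strategy == "PSMA_PET") {
    early_loc <- tp_loc; early_met <- tp_met
    tp_loc <- tp_met <- 0
  } else if (dist$strategy == "CTBS_PLUS_PSMA") {
    early_loc <- dist$reflex_tp[["localized"]]
    early_met <- dist$reflex_tp[["metastatic"]]
    tp_loc <- tp_loc - early_loc
    tp_met <- tp_met - early_met
  }
  early_init <- .treated_entry(values, early_loc, early_met)
  add("detected_early", sum(early_init), early_init, "early")

  delayed_init <- .treated_entry(values, tp_loc, tp_met)
  fp_mass <- m["no_disease", "false_pos"]
  if (fp_mass > 0) {
    split <- .norm_block(c(.get(values, "p_loc_given_detect"),
                           .get(values, "p_met_given_detect")))
    delayed_init <- delayed_init +
      .treated_entry(values, fp_mass * split[[1]], fp_mass * split[[2]])
  }
  add("detected_delayed", sum(delayed_init), delayed_init, "delayed")

  # true negatives: disease-free, baseline progression
  tn_mass <- m["no_disease", "true_neg"]
  add("true_negative", tn_mass,
      c(tn_mass, numeric(9)), "delayed")

  # false negatives (CTBS only): enter "no radiographic disease" but carry
  # the increased-progression hazard ratio for the whole pathway
  fn_mass <- sum(m[, "false_neg"])
  add("false_negative", fn_mass,
      c(fn_mass, numeric(9)), "false_negative")

  total <- sum(vapply(pathways, `[[`, numeric(1), "weight"))
  stopifnot(abs(total - 1) < 1e-9)
  pathways
}
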