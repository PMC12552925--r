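#' @title Parameter sets
#' @description A `parameter_set` holds every model input as a named
#'   parameter with a fitted [dist_spec()], an optional value-of-information
#'   group (1 diagnostics, 2 disease characteristics, 3 imaging and treatment
#'   costs, 4 utility values), a PSA stratum, units and a provenance note.
#'   Stratum-specific variants exist only for the inputs the source stratifies
#'   (disease detection and the localized/metastatic split); resolving any
#'   other parameter for a stratum falls back to the base-case value.
#' @name parameter_set
NULL

.strata <- c("base", "lt2", "2to5", "ge5")

#' PSA strata recognised by the model
#'
#' `"base"` (all patients), `"lt2"` (PSA < 2.00 ng/mL), `"2to5"`
#' (2.00-4.99 ng/mL), `"ge5"` (>= 5.00 ng/mL).
#' @return Character vector of stratum labels.
#' @export
psa_strata <- function() .strata

.parameter <- function(name, stratum, spec, voi_group = NA_integer_,
                       units = "", provenance = "") {
  stopifnot(stratum %in% .strata)
  structure(
    list(name = name, stratum = stratum, spec = spec,
         voi_group = voi_group, units = units, provenance = provenance),
    class = "cea_parameter"
  )
}

.param_key <- function(name, stratum) paste(name, stratum, sep = "@")

#' Construct a parameter set from a parameter table
#'
#' @param table A data.frame with columns `name`, `stratum`, `family`, `mean`,
#'   `ui_low`, `ui_high`, `voi_group`, `units`, `source_note`.
#' @param discount_rate Annual discount rate (fraction).
#' @param median_age Cohort starting age in years.
#' @return A `parameter_set`.
#' @export
parameter_set <- function(table, discount_rate = 0.03, median_age = 66) {
  required <- c("name", "stratum", "family", "mean", "ui_low", "ui_high",
                "voi_group", "units", "source_note")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop("parameter table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(table) == 0L) stop("parameter table is empty")
  bad <- !table$stratum %in% .strata
  if (any(bad)) {
    stop("malformed stratum label(s): ",
         paste(unique(table$stratum[bad]), collapse = ", "))
  }
  keys <- .param_key(table$name, table$stratum)
  if (anyDuplicated(keys)) {
    stop("duplicate parameter row(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  params <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    spec <- .fit_from_row(row$family, row$mean, row$ui_low, row$ui_high)
    params[[i]] <- .parameter(row$name, row$stratum, spec,
                              voi_group = row$voi_group, units = row$units,
                              provenance = row$source_note)
  }
  names(params) <- keys
  structure(
    list(parameters = params, discount_rate = discount_rate,
         median_age = median_age),
    class = "parameter_set"
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  tb <- as.data.frame(x)
  cat(sprintf("<parameter_set> %d parameters (%d placeholder), strata: %s\n",
              nrow(tb), sum(tb$source_note == "placeholder"),
              paste(unique(tb$stratum), collapse = ", ")))
  cat(sprintf("  discount_rate = %g, median_age = %g\n",
              x$discount_rate, x$median_age))
  invisible(x)
}

#' @export
as.data.frame.parameter_set <- function(x, ...) {
  rows <- lapply(x$parameters, function(p) {
    data.frame(name = p$name, stratum = p$stratum, family = p$spec$family,
               mean = p$spec$point_estimate, ui_low = p$spec$ui_low,
               ui_high = p$spec$ui_high, voi_group = p$voi_group,
               units = p$units, source_note = p$provenance,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load a parameter table from CSV
#'
#' The CSV must have columns `name, stratum, family, mean, ui_low, ui_high,
#' voi_group, units, source_note`. A reference transcription of the published
#' inputs ships with the package (see [reference_parameters()] and
#' `system.file("extdata", "parameters.csv", package = "petcea")`).
#'
#' @param path Path to the CSV file.
#' @inheritParams parameter_set
#' @return A `parameter_set`.
#' @export
load_parameter_table <- function(path, discount_rate = 0.03, median_age = 66) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  parameter_set(tb, discount_rate = discount_rate, median_age = median_age)
}

#' Write a parameter set back to CSV
#' @param set A `parameter_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(set, path) {
  utils::write.csv(as.data.frame(set), path, row.names = FALSE)
  invisible(path)
}

#' Resolve parameters for a PSA stratum
#'
#' Returns one parameter object per name: the stratum-specific variant where
#' one exists, the base-case parameter otherwise.
#'
#' @param set A `parameter_set`.
#' @param stratum One of [psa_strata()].
#' @return Named list of parameter objects (names without stratum suffix).
#' @export
resolve_parameters <- function(set, stratum = "base") {
  stopifnot(inherits(set, "parameter_set"), stratum %in% .strata)
  all_names <- unique(vapply(set$parameters, `[[`, "", "name"))
  out <- lapply(all_names, function(nm) {
    key <- .param_key(nm, stratum)
    if (!is.null(set$parameters[[key]])) return(set$parameters[[key]])
    base_key <- .param_key(nm, "base")
    if (is.null(set$parameters[[base_key]])) {
      stop("parameter '", nm, "' has neither a '", stratum,
           "' nor a base-case entry")
    }
    set$parameters[[base_key]]
  })
  names(out) <- all_names
  out
}

#' Point estimates for a stratum
#'
#' @inheritParams resolve_parameters
#' @return Named numeric vector of point estimates.
#' @export
point_estimates <- function(set, stratum = "base") {
  resolved <- resolve_parameters(set, stratum)
  vapply(resolved, function(p) p$spec$point_estimate, numeric(1))
}

#' Seeded Monte Carlo draws from a parameter set
#'
#' Draws are independent across parameters (no correlation structure is
#' published). The same `(seed, n_draws, set, stratum)` always reproduces the
#' identical matrix; `fixed` parameters repeat their point estimate.
#'
#' @inheritParams resolve_parameters
#' @param n_draws Number of Monte Carlo iterations (the published analysis
#'   uses 10,000).
#' @param seed Integer RNG seed.
#' @return A `parameter_draws` object: list with `draws` (an
#'   `n_draws x n_parameters` matrix), `n_draws`, `seed`, `stratum`.
#' @export
sample_parameters <- function(set, n_draws, seed, stratum = "base") {
  stopifnot(n_draws >= 1)
  resolved <- resolve_parameters(set, stratum)
  nm <- sort(names(resolved)) # fixed column order => determinism
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  draws <- vapply(nm, function(n) draw_dist(resolved[[n]]$spec, n_draws),
                  numeric(n_draws))
  draws <- matrix(draws, nrow = n_draws, dimnames = list(NULL, nm))
  structure(
    list(draws = draws, n_draws = n_draws, seed = seed, stratum = stratum),
    class = "parameter_draws"
  )
}

#' @export
print.parameter_draws <- function(x, ...) {
  cat(sprintf("<parameter_draws> %d draws x %d parameters (stratum %s, seed %d)\n",
              x$n_draws, ncol(x$draws), x$stratum, x$seed))
  invisible(x)
}

#' Value-of-information groups of a parameter set
#'
#' @inheritParams resolve_parameters
#' @return Named list mapping group id (`"1"`..`"4"`) to the parameter names
#'   in that group after stratum resolution. Parameters without a group label
#'   belong to no group.
#' @export
voi_groups <- function(set, stratum = "base") {
  resolved <- resolve_parameters(set, stratum)
  grp <- vapply(resolved, function(p) as.integer(p$voi_group), integer(1))
  out <- lapply(1:4, function(g) names(grp)[!is.na(grp) & grp == g])
  names(out) <- as.character(1:4)
  out
}
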