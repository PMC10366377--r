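#' @importFrom stats rbeta rgamma rlnorm setNames
#' @importFrom utils read.csv write.csv
NULL

# Parameter identifiers the transition engine and reward schedules reference.
# load_parameters() refuses a file that does not define all of them.
required_parameter_names <- function() {
  c(
    "p_low_pce", "p_mod_pce", "p_high_pce", "enrollment",
    "risk_cad_high_pce", "risk_cad_mod_pce", "or_cad_high_prs",
    "hr_cad_diabetes", "risk_cad_after_istroke", "risk_ischemic_stroke",
    "risk_istroke_after_cad", "risk_recurrent_cad",
    "risk_recurrent_istroke", "hr_istroke_diabetes",
    "risk_istroke_post_hstroke", "hr_statin_cad", "hr_statin_istroke",
    "adherence", "risk_myopathy", "risk_statin_diabetes",
    "risk_statin_hstroke", "mort_acute_cad", "mort_chronic_cad",
    "hr_mort_cad_diabetes", "mort_stroke_cad", "mort_acute_istroke",
    "mort_chronic_stroke", "rr_mort_istroke_diabetes", "mort_acute_hstroke",
    "hr_mort_diabetes", "u_cad", "u_myopathy", "u_diabetes", "u_stroke",
    "du_acute_cad", "du_acute_stroke", "du_age", "cost_prs_test",
    "cost_standard_whp", "cost_mobile_app", "cost_primary_care_visit",
    "cost_statin", "cost_background", "cost_acute_cad_nonfatal",
    "cost_acute_cad_fatal", "cost_acute_istroke_nonfatal",
    "cost_acute_istroke_fatal", "cost_acute_hstroke_nonfatal",
    "cost_acute_hstroke_fatal", "cost_fu_cad", "cost_fu_stroke",
    "cost_fu_myopathy", "cost_fu_diabetes", "cost_prod_first_year",
    "cost_prod_followup", "cost_prod_diabetes", "cost_prod_myopathy"
  )
}

parameter_columns <- c(
  "name", "baseline", "low", "high", "dist_family", "shape_a", "shape_b",
  "units", "role", "source", "calibration"
)

#' Validate a table of model parameters
#'
#' Checks the invariants every parameter row must satisfy: ranges bracket the
#' baseline, probability/utility/disutility baselines lie in `[0, 1]`, costs
#' are non-negative, and the sampling distribution family is compatible with
#' the parameter's role (beta for probabilities, utilities and disutilities;
#' gamma for costs; lognormal for relative effects).
#'
#' @param entries data frame with columns `name`, `baseline`, `low`, `high`,
#'   `dist_family`, `shape_a`, `shape_b`, `units`, `role` (and optionally
#'   `source`, `calibration`).
#' @param complete if `TRUE`, additionally require that every identifier the
#'   engine references is present.
#' @param check_range if `TRUE`, require `low <= baseline <= high` where a
#'   range is given (dropped for sampled values, which may legitimately fall
#'   outside the deterministic range).
#' @return `entries`, invisibly, if valid; otherwise an error naming the
#'   offending parameter.
#' @export
validate_parameters <- function(entries, complete = TRUE, check_range = TRUE) {
  need <- c("name", "baseline", "role")
  miss <- setdiff(need, names(entries))
  if (length(miss) > 0) {
    stop("parameter table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(entries$name)) {
    stop("duplicated parameter name: ",
         entries$name[duplicated(entries$name)][1])
  }
  bad_role <- setdiff(unique(entries$role),
                      c("probability", "relative_effect", "utility",
                        "disutility", "cost"))
  if (length(bad_role) > 0) stop("unknown parameter role: ", bad_role[1])
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    ctx <- function(msg) stop("parameter '", e$name, "': ", msg, call. = FALSE)
    if (!is.finite(e$baseline)) ctx("baseline is not a number")
    if (e$role %in% c("probability", "utility", "disutility") &&
        (e$baseline < 0 || e$baseline > 1)) {
      ctx("baseline outside [0, 1]")
    }
    if (e$role == "cost" && e$baseline < 0) ctx("negative cost")
    if (e$role == "relative_effect" && e$baseline <= 0) {
      ctx("relative effect must be positive")
    }
    has_rng <- !is.na(e$low) && !is.na(e$high)
    if (check_range && has_rng &&
        !(e$low <= e$baseline && e$baseline <= e$high)) {
      ctx("range does not bracket the baseline")
    }
    fam <- if (is.null(e$dist_family) || is.na(e$dist_family)) "fixed"
           else e$dist_family
    ok <- switch(fam,
      beta = e$role %in% c("probability", "utility", "disutility"),
      gamma = e$role == "cost",
      lognormal = e$role == "relative_effect",
      fixed = TRUE,
      FALSE
    )
    if (!ok) ctx(paste0("distribution family '", fam,
                        "' incompatible with role '", e$role, "'"))
    if (fam != "fixed") {
      shapes_ok <- is.finite(e$shape_a) && is.finite(e$shape_b) &&
        if (fam == "lognormal") e$shape_b > 0 else
          (e$shape_a > 0 && e$shape_b > 0)
      if (!shapes_ok) ctx("invalid shape parameters for its distribution family")
    }
  }
  if (complete) {
    absent <- setdiff(required_parameter_names(), entries$name)
    if (length(absent) > 0) {
      stop("parameter set incomplete; missing: ",
           paste(absent, collapse = ", "))
    }
  }
  invisible(entries)
}

new_parameter_set <- function(entries, provenance = "in-memory") {
  validate_parameters(entries)
  structure(list(entries = tibble::as_tibble(entries),
                 provenance = provenance),
            class = "parameter_set")
}

#' Load a model parameter set from CSV or YAML
#'
#' The file must have one row per parameter with columns `name`, `baseline`,
#' `low`, `high`, `dist_family`, `shape_a`, `shape_b`, `units`, `role`,
#' `source` (and optionally `calibration`). A YAML file carries the same
#' fields as a list of mappings under a top-level `parameters:` key; both
#' formats round-trip losslessly through [write_parameters()].
#'
#' @param path path to a `.csv` or `.yaml`/`.yml` file.
#' @return a `parameter_set` object.
#' @seealso [default_parameters()] for the packaged annual input table.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    raw <- yaml::read_yaml(path)
    if (is.null(raw$parameters)) stop("YAML parameter file lacks 'parameters:'")
    entries <- do.call(rbind, lapply(raw$parameters, function(p) {
      p <- p[parameter_columns]
      names(p) <- parameter_columns
      p[vapply(p, is.null, logical(1))] <- NA
      as.data.frame(p, stringsAsFactors = FALSE)
    }))
  } else {
    entries <- read.csv(path, stringsAsFactors = FALSE)
  }
  for (col in parameter_columns) {
    if (!col %in% names(entries)) entries[[col]] <- NA
  }
  num <- c("baseline", "low", "high", "shape_a", "shape_b")
  for (col in num) entries[[col]] <- as.numeric(entries[[col]])
  bad <- is.na(entries$baseline) | !nzchar(trimws(as.character(entries$name)))
  if (any(bad)) {
    stop("malformed parameter row ", which(bad)[1],
         " (name or baseline missing)")
  }
  new_parameter_set(entries[, parameter_columns], provenance = path)
}

#' Write a parameter set to CSV or YAML
#'
#' @param ps a `parameter_set`.
#' @param path destination; format chosen by extension (`.csv` or `.yaml`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(ps, path) {
  stopifnot(inherits(ps, "parameter_set"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    rows <- lapply(seq_len(nrow(ps$entries)), function(i) {
      r <- as.list(ps$entries[i, parameter_columns])
      r[vapply(r, function(x) is.na(x) || (is.character(x) && !nzchar(x)),
               logical(1))] <- NULL
      r
    })
    yaml::write_yaml(list(parameters = rows), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    write.csv(as.data.frame(ps$entries[, parameter_columns]), con,
              row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(path)
}

#' Packaged annual parameter inputs
#'
#' Returns the packaged table of annual model inputs: initial PCE risk
#' distribution, program enrollment, annual event risks, relative effects,
#' statin side-effect risks, state-specific mortality, utility and disutility
#' weights, and all medical, program and lost-productivity costs, each with
#' its uncertainty range and sampling distribution. Rows whose printed
#' distribution shapes do not reproduce the baseline mean are recalibrated
#' (keeping the first shape parameter) and flagged in the `calibration`
#' column; see the package vignette.
#'
#' @return a `parameter_set`.
#' @export
default_parameters <- function() {
  load_parameters(system.file("extdata", "annual_parameters.csv",
                              package = "prscea", mustWork = TRUE))
}

#' Copy the packaged default parameter file
#'
#' Writes the packaged parameter CSV byte-identically to `path`, so that a
#' run can be reproduced from a plain-text input under version control.
#'
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_default_parameters <- function(path) {
  src <- system.file("extdata", "annual_parameters.csv",
                     package = "prscea", mustWork = TRUE)
  if (!file.copy(src, path, overwrite = TRUE)) {
    stop("could not write ", path)
  }
  invisible(path)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> ", nrow(x$entries), " parameters (",
      x$provenance, ")\n", sep = "")
  print(x$entries, n = 8)
  invisible(x)
}

#' Get one parameter value
#'
#' @param ps a `parameter_set`.
#' @param name parameter identifier.
#' @return the baseline (or currently set) value.
#' @export
param_value <- function(ps, name) {
  i <- match(name, ps$entries$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  ps$entries$baseline[i]
}

#' Set parameter values
#'
#' Returns a copy of `ps` with the given baselines replaced; used by the
#' sensitivity analyses and by tests.
#'
#' @param ps a `parameter_set`.
#' @param ... `name = value` pairs.
#' @return a new `parameter_set`.
#' @export
set_params <- function(ps, ...) {
  vals <- list(...)
  idx <- match(names(vals), ps$entries$name)
  if (anyNA(idx)) stop("unknown parameter: ", names(vals)[is.na(idx)][1])
  ps$entries$baseline[idx] <- as.numeric(unlist(vals))
  ps
}

as_param_vector <- function(ps) {
  setNames(ps$entries$baseline, ps$entries$name)
}

#' Convert a risk over a multi-year horizon to an annual probability
#'
#' Assumes a constant hazard over the horizon:
#' `1 - (1 - p_horizon)^(1/years)`. Used to turn 10-year PCE risk thresholds
#' (20% high, 12.5% moderate) into the model's annual CAD probabilities
#' (0.022 and 0.013).
#'
#' @param p_horizon cumulative probability over `years`, in `[0, 1)`.
#' @param years horizon length in years (positive).
#' @return annual probability.
#' @export
annualize_risk <- function(p_horizon, years) {
  if (any(p_horizon < 0 | p_horizon >= 1)) {
    stop("p_horizon must lie in [0, 1)")
  }
  if (any(years <= 0)) stop("years must be positive")
  1 - (1 - p_horizon)^(1 / years)
}

#' Apply a relative effect to a probability
#'
#' `hazard` rescales on the hazard scale, `1 - (1 - p)^effect`, and is used
#' for all hazard-ratio effects (statin risk reductions, diabetes hazard
#' ratios, mortality multipliers). `direct` multiplies the probability and
#' caps at 1; it is used for the 1.9-fold PRS risk increase, which the
#' source describes as a fold increase in the risk itself. `odds` transforms
#' on the odds scale and is provided for completeness.
#'
#' @param p probability in `[0, 1]`.
#' @param effect positive multiplier (HR, RR, OR or fold-change).
#' @param method one of `"hazard"`, `"odds"`, `"direct"`.
#' @return transformed probability in `[0, 1]`.
#' @export
apply_relative_effect <- function(p, effect,
                                  method = c("hazard", "odds", "direct")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(effect <= 0)) stop("effect must be positive")
  switch(method,
    hazard = 1 - (1 - p)^effect,
    direct = pmin(p * effect, 1),
    odds = {
      o <- p / (1 - p) * effect
      ifelse(p >= 1, 1, o / (1 + o))
    }
  )
}

# Deterministic per-parameter random substream: the draw stream of one
# parameter does not move when another parameter is added or removed.
param_stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * (seq_len(nchar(name)) %% 31L + 1L))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 1000003L)
}

draw_one <- function(fam, a, b, n) {
  switch(fam,
    beta = rbeta(n, a, b),
    gamma = rgamma(n, shape = a, rate = b),
    lognormal = rlnorm(n, meanlog = a, sdlog = b),
    stop("cannot sample family: ", fam)
  )
}

#' Draw parameter values from their sampling distributions
#'
#' One independent draw per non-fixed parameter from its stated family
#' (beta, lognormal or gamma) and shape parameters; `fixed` entries keep
#' their baseline. Draws are reproducible under `rng_seed` and use one
#' substream per parameter, so no cross-parameter correlation is induced
#' and the stream of one parameter is unaffected by the presence of others.
#'
#' @param ps a `parameter_set`.
#' @param rng_seed integer seed.
#' @param n number of draws per parameter.
#' @return for `n = 1` (default) a new `parameter_set` with drawn baselines;
#'   for `n > 1` an `n` x `P` matrix of draws with parameters as columns.
#' @export
sample_parameters <- function(ps, rng_seed, n = 1) {
  stopifnot(inherits(ps, "parameter_set"), n >= 1)
  e <- ps$entries
  draws <- matrix(rep(e$baseline, each = n), nrow = n,
                  dimnames = list(NULL, e$name))
  for (i in seq_len(nrow(e))) {
    fam <- e$dist_family[i]
    if (is.na(fam) || fam == "fixed") next
    set.seed(param_stream_seed(rng_seed, e$name[i]))
    draws[, i] <- draw_one(fam, e$shape_a[i], e$shape_b[i], n)
  }
  if (n == 1) {
    ps$entries$baseline <- draws[1, ]
    validate_parameters(ps$entries, check_range = FALSE)
    ps$provenance <- paste0(ps$provenance, " [sampled, seed ", rng_seed, "]")
    return(ps)
  }
  draws
}
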