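# Scenario analysis: annual migration of the event-free cohort across PCE
# risk categories (low, moderate, high), mixing the natural drift of
# cardiovascular risk with the more favourable in-program drift according
# to enrollment. Migration relabels risk category only — it moves no mass
# into or out of the event-free block — starting after the first model
# year; PCE rescreening is annual, eligibility is re-evaluated from the
# current category, and the PRS tag (and the one-time PRS cost) is not
# re-administered.

#' Annual natural migration percentages
#'
#' Off-diagonal percentages, in order (low to mod, low to high, mod to low,
#' mod to high, high to low, high to mod), for a cohort outside any
#' workplace program.
#' @return numeric vector of six percentages.
#' @export
natural_migration_pct <- function() c(25, 5, 35, 20, 6, 31)

#' Annual in-program migration percentages
#'
#' The same six off-diagonals for employees enrolled in a workplace health
#' program, whose risk-factor control shifts migration toward lower PCE
#' categories.
#' @return numeric vector of six percentages.
#' @export
whp_migration_pct <- function() c(12.05, 0.62, 46.35, 7.66, 15.65, 48.70)

#' Build a PCE risk-category migration matrix
#'
#' @param offdiag six off-diagonal annual migration percentages in order
#'   (low to mod, low to high, mod to low, mod to high, high to low,
#'   high to mod); diagonals are the complements.
#' @return a row-stochastic 3 x 3 `migration_matrix` over
#'   \{low, mod, high\} (probabilities, not percentages).
#' @export
make_migration <- function(offdiag) {
  if (length(offdiag) != 6 || any(offdiag < 0)) {
    stop("offdiag must be six non-negative percentages")
  }
  p <- offdiag / 100
  rows <- list(c(NA, p[1], p[2]), c(p[3], NA, p[4]), c(p[5], p[6], NA))
  m <- matrix(0, 3, 3, dimnames = list(strata3, strata3))
  for (r in 1:3) {
    off <- sum(rows[[r]], na.rm = TRUE)
    if (off > 1 + 1e-12) {
      stop("row ", strata3[r], ": off-diagonal migration exceeds 100%")
    }
    m[r, ] <- replace(rows[[r]], is.na(rows[[r]]), 1 - off)
  }
  structure(m, class = c("migration_matrix", "matrix", "array"))
}

#' Blend natural and in-program migration
#'
#' Entrywise convex combination `w_natural * natural + (1 - w_natural) *
#' whp`. The default weight 0.52 on the natural matrix is the one that
#' reproduces the published enrollment-weighted vector (18.780, 2.900,
#' 40.450, 14.080, 10.630, 39.500)% to three decimals; callers preferring
#' to weight the natural matrix by the non-enrolled share can pass
#' `w_natural = 1 - enrollment` instead.
#'
#' @param natural,whp row-stochastic 3 x 3 migration matrices.
#' @param w_natural weight on the natural matrix, in `[0, 1]`.
#' @return a `migration_matrix`.
#' @export
blend_migration <- function(natural = make_migration(natural_migration_pct()),
                            whp = make_migration(whp_migration_pct()),
                            w_natural = 0.52) {
  if (w_natural < 0 || w_natural > 1) stop("w_natural must lie in [0, 1]")
  stopifnot(all(dim(natural) == c(3, 3)), all(dim(whp) == c(3, 3)))
  m <- w_natural * unclass(natural) + (1 - w_natural) * unclass(whp)
  structure(m, class = c("migration_matrix", "matrix", "array"))
}

#' Run the risk-migration scenario
#'
#' Reruns the three-strategy comparison with annual PCE risk-category
#' migration from `migration_start` (default: after the first year). In the
#' workplace strategies the enrolled fraction follows the
#' enrollment-weighted (blended) matrix and the non-enrolled remainder the
#' natural matrix; the no-program strategy follows the natural matrix
#' throughout. Annual PCE screening costs continue and the PRS test is not
#' repeated.
#'
#' @inheritParams run_cohort
#' @param migration_whp migration matrix for the enrolled fraction of the
#'   two workplace strategies.
#' @param migration_nowhp migration matrix for the no-program strategy and
#'   the non-enrolled remainder.
#' @param wtp willingness-to-pay per QALY for the comparison.
#' @return list with `traces` (per-strategy `cohort_trace`) and `cea`
#'   (a `cea_result` with CardioriskSCORE as focal strategy).
#' @export
run_scenario <- function(ps, life_table,
                         migration_whp = blend_migration(),
                         migration_nowhp = make_migration(natural_migration_pct()),
                         migration_start = 1, wtp = 50000, ...) {
  whp_mig <- list(enrolled = migration_whp, nonenrolled = migration_nowhp)
  migs <- list(CardioriskSCORE = whp_mig, StandardWHP = whp_mig,
               NoWHP = migration_nowhp)
  traces <- run_strategies(ps, life_table, migration = migs,
                           migration_start = migration_start, ...)
  list(traces = traces,
       cea = compare_strategies(traces, wtp = wtp, focal = "CardioriskSCORE"))
}
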