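# Strategy comparison: incremental costs and QALYs, dominance, ICER and
# (incremental) net monetary benefit at a willingness-to-pay threshold.

totals_of <- function(x) {
  if (inherits(x, "cohort_trace")) return(total_outcomes(x))
  if (is.list(x) && all(c("total_cost", "total_qalys") %in% names(x))) return(x)
  stop("expected a cohort_trace or a list(total_cost, total_qalys)")
}

#' Compare strategies on cost and effectiveness
#'
#' Computes pairwise incrementals of the focal strategy against every other
#' strategy, classifies dominance before any ICER division (an ICER is only
#' reported when the increments share a meaningful sign pattern), and
#' evaluates net monetary benefit `NMB = WTP x QALYs - cost` per strategy
#' and incremental NMB `INMB = WTP x dE - dC` per comparison.
#'
#' @param results named list of `cohort_trace` objects or
#'   `list(total_cost, total_qalys)` totals; at least two.
#' @param wtp willingness-to-pay threshold in US$ per QALY.
#' @param focal name of the strategy compared against the others (defaults
#'   to the first entry).
#' @return a `cea_result`: list with `summary` (per-strategy costs, QALYs,
#'   incrementals relative to the focal strategy, ICER label, NMB) and
#'   `comparisons` (focal-minus-comparator increments, ICER, INMB).
#' @export
compare_strategies <- function(results, wtp = 50000, focal = NULL) {
  if (length(results) < 2) stop("need at least 2 strategies to compare")
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    stop("'results' must be a named list")
  }
  tot <- lapply(results, totals_of)
  if (is.null(focal)) focal <- names(tot)[1]
  if (!focal %in% names(tot)) stop("unknown focal strategy: ", focal)
  cost <- vapply(tot, `[[`, numeric(1), "total_cost")
  qaly <- vapply(tot, `[[`, numeric(1), "total_qalys")
  comps <- setdiff(names(tot), focal)
  cmp <- tibble::tibble(
    comparison = paste(focal, "vs", comps),
    comparator = comps,
    delta_cost = unname(cost[[focal]] - cost[comps]),
    delta_qalys = unname(qaly[[focal]] - qaly[comps])
  )
  lab <- character(nrow(cmp))
  icer <- rep(NA_real_, nrow(cmp))
  for (i in seq_len(nrow(cmp))) {
    dc <- cmp$delta_cost[i]
    de <- cmp$delta_qalys[i]
    if (dc < 0 && de > 0) {
      lab[i] <- "Dominant"
    } else if (dc > 0 && de < 0) {
      lab[i] <- "Dominated"
    } else if (de == 0 && dc == 0) {
      lab[i] <- "Equivalent"
    } else {
      icer[i] <- dc / de
      lab[i] <- format(round(icer[i]), big.mark = ",")
    }
  }
  cmp$icer <- icer
  cmp$icer_label <- lab
  cmp$inmb <- wtp * cmp$delta_qalys - cmp$delta_cost
  inc_cost <- unname(cost - cost[[focal]])
  inc_qaly <- unname(qaly - qaly[[focal]])
  summary <- tibble::tibble(
    strategy = names(tot),
    cost = unname(cost),
    qalys = unname(qaly),
    incremental_cost = inc_cost,
    qalys_gained = inc_qaly,
    nmb = unname(wtp * qaly - cost)
  )
  summary$icer_label <- ifelse(
    summary$strategy == focal,
    if (all(lab == "Dominant")) "Dominant" else "-",
    "-")
  structure(list(summary = summary, comparisons = cmp, wtp = wtp,
                 focal = focal),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result> focal strategy: ", x$focal, " (WTP $",
      format(x$wtp, big.mark = ","), "/QALY)\n", sep = "")
  print(x$summary)
  cat("\nPairwise (focal minus comparator):\n")
  print(x$comparisons[, c("comparison", "delta_cost", "delta_qalys",
                          "icer_label", "inmb")])
  invisible(x)
}

#' Incremental net monetary benefit
#'
#' @param delta_qalys QALYs gained by the focal strategy.
#' @param delta_cost incremental cost of the focal strategy.
#' @param wtp willingness-to-pay per QALY.
#' @return `wtp * delta_qalys - delta_cost`.
#' @export
inmb <- function(delta_qalys, delta_cost, wtp = 50000) {
  wtp * delta_qalys - delta_cost
}
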