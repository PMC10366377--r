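# Strategy definitions.
#
# Three strategies are compared. All of them face the same underlying
# disease process: the strata at elevated CAD/stroke risk (high PCE, or
# moderate PCE with top-quintile CAD-PRS) incur events whether or not a
# program exists. The strategies differ in who is identified and treated:
#
# * CardioriskSCORE — PCE plus a one-time CAD-PRS test; every enrolled
#   employee in an at-risk stratum is recommended statins.
# * StandardWHP — PCE alone; only enrolled employees with high PCE risk
#   are recommended statins.
# * NoWHP — no screening, no treatment, no program costs.
#
# Enrollment (52% at baseline) splits the cohort into an enrolled fraction
# that faces screening costs and treatment rules and a non-enrolled
# remainder that behaves exactly as under NoWHP. Half of statin initiators
# are adherent; adherence is a persistent trait fixed at model start, and
# only adherent initiators receive the statin effect, side-effect risks
# and therapy cost.

strategy_names <- c("CardioriskSCORE", "StandardWHP", "NoWHP")

#' Strategy configuration
#'
#' @param name one of `"CardioriskSCORE"`, `"StandardWHP"`, `"NoWHP"`.
#' @param ps a `parameter_set` supplying enrollment and cost inputs.
#' @return a `strategy_config` with the enrollment probability, eligibility
#'   rule, statin initiation and adherence fractions, and the per-cycle
#'   screening-cost schedule.
#' @export
strategy_config <- function(name = strategy_names, ps = default_parameters()) {
  name <- match.arg(name)
  pv <- as_param_vector(ps)
  cfg <- list(
    name = name,
    enrollment = if (name == "NoWHP") 0 else pv[["enrollment"]],
    statin_initiation = if (name == "NoWHP") 0 else 1,
    adherence = pv[["adherence"]],
    # eligibility for statin recommendation, by (PCE stratum, PRS stratum)
    eligible = switch(name,
      CardioriskSCORE = function(stratum, prs) {
        (prs == "high" & stratum %in% c("mod", "high")) |
          (prs == "low" & stratum == "high")
      },
      StandardWHP = function(stratum, prs) stratum == "high",
      NoWHP = function(stratum, prs) rep(FALSE, length(stratum))
    ),
    # per-person screening/program cost for an enrolled employee, by cycle;
    # the PRS test is a one-time first-year cost, the genetic-consultation
    # visit applies to the high-PRS subset only, the PCE screen is annual,
    # and the mobile app runs from the second year onward
    screening_cost = switch(name,
      CardioriskSCORE = function(cycle, prs) {
        pv[["cost_standard_whp"]] +
          (cycle == 0) * (pv[["cost_prs_test"]] +
                            (prs == "high") * pv[["cost_primary_care_visit"]]) +
          (cycle > 0) * pv[["cost_mobile_app"]]
      },
      StandardWHP = function(cycle, prs) {
        rep_len(pv[["cost_standard_whp"]], length(cycle))
      },
      NoWHP = function(cycle, prs) rep_len(0, length(cycle))
    )
  )
  structure(cfg, class = "strategy_config")
}

#' @export
print.strategy_config <- function(x, ...) {
  cat("<strategy_config> ", x$name,
      " | enrollment ", signif(x$enrollment, 3),
      " | adherence ", signif(x$adherence, 3), "\n", sep = "")
  invisible(x)
}

# strata whose occupants can develop CAD/ischemic stroke at all (identical
# across strategies): high PCE, or moderate PCE with high PRS
at_risk_stratum <- function(stratum, prs) {
  stratum == "high" | (stratum == "mod" & prs == "high")
}
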