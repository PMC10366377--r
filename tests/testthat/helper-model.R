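# Shared fixtures, memoised so expensive runs happen once per suite.

.fixtures <- new.env(parent = emptyenv())

base_ps <- function() {
  if (is.null(.fixtures$ps)) .fixtures$ps <- default_parameters()
  .fixtures$ps
}

base_lt <- function() {
  if (is.null(.fixtures$lt)) .fixtures$lt <- synth_life_table()
  .fixtures$lt
}

base_traces <- function() {
  if (is.null(.fixtures$traces)) {
    .fixtures$traces <- run_strategies(base_ps(), base_lt())
  }
  .fixtures$traces
}

base_cea <- function() {
  if (is.null(.fixtures$cea)) {
    .fixtures$cea <- compare_strategies(base_traces(),
                                        focal = "CardioriskSCORE")
  }
  .fixtures$cea
}

# parameter set with every event risk (primary events and statin side
# effects) zeroed: the cohort then reduces to background survival
no_event_ps <- function() {
  set_params(base_ps(),
             risk_cad_high_pce = 0, risk_cad_mod_pce = 0,
             risk_ischemic_stroke = 0, risk_myopathy = 0,
             risk_statin_diabetes = 0, risk_statin_hstroke = 0)
}

delta_of <- function(cea, comparator, what = "delta_cost") {
  cmp <- cea$comparisons
  cmp[[what]][match(comparator, cmp$comparator)]
}
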