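# Individual-level Monte Carlo simulator.
#
# An independent cross-check of the deterministic cohort propagation: it
# walks simulated persons through the same per-cycle transition kernels
# and tallies occupancy. The cohort trace is the expectation of this
# process, so simulated occupancy must agree with the trace to within
# binomial Monte Carlo error at every cycle.

#' Simulate the cohort person-by-person
#'
#' @inheritParams run_cohort
#' @param n number of simulated persons.
#' @param seed integer seed.
#' @return list with `occupancy` (`(horizon+1)` x 22 matrix of occupancy
#'   fractions at cycle start) and `n`.
#' @export
simulate_cohort_mc <- function(strategy, ps, life_table, n = 100000,
                               seed = 1, horizon = 5, start_age = 50,
                               stroke_scope = c("population", "at_risk")) {
  stroke_scope <- match.arg(stroke_scope)
  stopifnot(n >= 1)
  if (!inherits(strategy, "strategy_config")) {
    strategy <- strategy_config(strategy, ps)
  }
  set.seed(seed)
  pv <- as_param_vector(ps)
  shares <- c(pv[["p_low_pce"]], pv[["p_mod_pce"]], pv[["p_high_pce"]])
  shares <- shares / sum(shares)
  qs <- life_table_q(life_table, start_age + 0:(horizon - 1))
  cells <- cohort_cells(strategy)
  w <- vapply(cells, `[[`, numeric(1), "w")
  alloc <- as.vector(stats::rmultinom(1, n, w))
  ss_ids <- build_state_space()$id
  occ <- matrix(0, horizon + 1, 22, dimnames = list(NULL, ss_ids))
  for (ci in seq_along(cells)) {
    if (alloc[ci] == 0) next
    cell <- cells[[ci]]
    ctx <- cell_context(pv, cell$prs, cell$treat, stroke_scope)
    kernels <- cell_kernels(ctx, qs)
    counts <- numeric(N_INTERNAL)
    counts[1:3] <- as.vector(stats::rmultinom(1, alloc[ci], shares))
    map <- match(internal_to_nominal(cell$prs), ss_ids)
    for (t in seq_len(horizon + 1)) {
      for (j in seq_len(N_INTERNAL)) {
        occ[t, map[j]] <- occ[t, map[j]] + counts[j]
      }
      if (t > horizon) break
      K <- kernels[[t]]$K
      nxt <- numeric(N_INTERNAL)
      for (s in which(counts > 0)) {
        nxt <- nxt + as.vector(stats::rmultinom(1, counts[s], K[s, ]))
      }
      counts <- nxt
    }
  }
  list(occupancy = occ / n, n = n)
}
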