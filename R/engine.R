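# Cohort transition engine.
#
# The cohort is decomposed into cells that share one set of transition
# dynamics: PRS stratum (top quintile vs bottom 80%) x treatment group
# (enrolled-adherent under the strategy's eligibility rule, or untreated).
# Within a cell the chain runs on the 64-state internal expansion (3
# event-free PCE strata; 5 conditions x acute/chronic x 3 retained strata;
# 10 pairs x {acute-new-first, acute-new-second, chronic}; death).
#
# The acute phase is a one-cycle tunnel: every event entrant occupies the
# acute copy of the entered state for the entry year (accruing the
# non-fatal acute cost, acute disutility and first-year productivity
# loss); the acute case fatality (0.228 CAD, 0.100 ischemic, 0.390
# hemorrhagic stroke) is the acute state's own mortality applied on exit,
# and the fatal acute event cost attaches to those deaths. Competing risks
# use independent probabilities, renormalised proportionally only if they
# sum past 1 (never at baseline values).

hz <- function(p, e) 1 - (1 - p)^e

cond_i <- c(cad = 1L, istroke = 2L, hstroke = 3L, diabetes = 4L,
            myopathy = 5L)

# Per-cell epidemiology context: untreated stratum risks and the constants
# every row builder needs. CAD incidence is restricted to the at-risk
# strata (high PCE, or moderate PCE with top-quintile PRS); the ischemic
# stroke risk is the general-population rate and by default applies to
# every event-free stratum (`stroke_scope = "at_risk"` restricts it).
cell_context <- function(pv, prs, treat, stroke_scope = "population") {
  at_risk <- at_risk_stratum(strata3, prs)
  p_cad <- c(0, pv[["risk_cad_mod_pce"]], pv[["risk_cad_high_pce"]])
  if (prs == "high") {
    p_cad <- apply_relative_effect(p_cad, pv[["or_cad_high_prs"]], "direct")
  }
  p_cad[!at_risk] <- 0
  p_ist <- if (stroke_scope == "population") {
    rep(pv[["risk_ischemic_stroke"]], 3)
  } else {
    ifelse(at_risk, pv[["risk_ischemic_stroke"]], 0)
  }
  list(pv = pv, prs = prs, treat = treat, at_risk = at_risk,
       p_cad_strat = p_cad, p_ist_strat = p_ist,
       stroke_scope = stroke_scope)
}

# acute-phase (first-cycle) mortality of a newly entered condition; NA for
# conditions without an acute case fatality
acute_mortality <- function(ci, pv) {
  switch(ci,
    pv[["mort_acute_cad"]],
    pv[["mort_acute_istroke"]],
    pv[["mort_acute_hstroke"]],
    NA_real_,
    NA_real_)
}

# transition row (length 64) for one event-free stratum; the fatal vector
# splits the row's death flow by fatal acute event type (none here: event
# entrants survive into the acute tunnel and face its case fatality there)
ef_row <- function(ctx, s, q) {
  pv <- ctx$pv
  tr <- ctx$treat[s]
  e_cad <- ctx$p_cad_strat[s]
  e_ist <- ctx$p_ist_strat[s]
  if (tr) {
    e_cad <- hz(e_cad, pv[["hr_statin_cad"]])
    e_ist <- hz(e_ist, pv[["hr_statin_istroke"]])
  }
  e_dia <- if (tr) pv[["risk_statin_diabetes"]] else 0
  e_myo <- if (tr) pv[["risk_myopathy"]] else 0
  e_hst <- if (tr) pv[["risk_statin_hstroke"]] else 0
  ev <- c(e_cad, e_ist, e_hst, e_dia, e_myo)
  tot <- sum(ev) + q
  sc <- if (tot > 1) 1 / tot else 1
  ev <- ev * sc
  d_bg <- q * sc
  row <- numeric(N_INTERNAL)
  for (k in 1:5) row[single_i(k, 1L, s)] <- ev[k]
  row[DEATH_I] <- d_bg
  row[ef_i(s)] <- 1 - sum(ev) - d_bg
  list(row = row, fatal = numeric(3))
}

# row for a single-condition state. In the acute phase of CAD/stroke the
# state's mortality is the acute case fatality and deaths carry the fatal
# acute event cost; afterwards the chronic (follow-up) mortality applies.
# The no-event fraction lands in the chronic copy.
single_row <- function(ctx, ci, phase, s, q) {
  pv <- ctx$pv
  # statin is stopped after its own adverse events (hemorrhagic stroke,
  # myopathy); it continues as ongoing therapy otherwise
  on_statin <- ctx$treat[s] && ci != 3L && ci != 5L
  p2_cad <- switch(ci,
    0,                                              # cad
    pv[["risk_cad_after_istroke"]],                 # post ischemic stroke
    ctx$p_cad_strat[s],                             # post hemorrhagic: unchanged
    hz(ctx$p_cad_strat[s], pv[["hr_cad_diabetes"]]),# with diabetes
    ctx$p_cad_strat[s])                             # myopathy: unchanged
  p2_ist <- switch(ci,
    pv[["risk_istroke_after_cad"]],
    0,
    pv[["risk_istroke_post_hstroke"]],
    hz(ctx$p_ist_strat[s], pv[["hr_istroke_diabetes"]]),
    ctx$p_ist_strat[s])
  if (on_statin) {
    p2_cad <- hz(p2_cad, pv[["hr_statin_cad"]])
    p2_ist <- hz(p2_ist, pv[["hr_statin_istroke"]])
  }
  e_dia <- if (on_statin && ci != 4L) pv[["risk_statin_diabetes"]] else 0
  e_myo <- if (on_statin) pv[["risk_myopathy"]] else 0
  e_hst <- if (on_statin && ci != 3L) pv[["risk_statin_hstroke"]] else 0
  am <- acute_mortality(ci, pv)
  d <- if (phase == 1L && !is.na(am)) {
    am
  } else {
    switch(ci,
      pv[["mort_chronic_cad"]],
      pv[["mort_chronic_stroke"]],
      pv[["mort_chronic_stroke"]],
      hz(q, pv[["hr_mort_diabetes"]]),
      q)
  }
  ev <- c(cad = p2_cad, istroke = p2_ist, hstroke = e_hst, diabetes = e_dia,
          myopathy = e_myo)
  ev[ci] <- 0  # cannot re-acquire the owned condition
  tot <- sum(ev) + d
  sc <- if (tot > 1) 1 / tot else 1
  ev <- ev * sc
  d <- d * sc
  row <- numeric(N_INTERNAL)
  fat <- numeric(3)
  if (phase == 1L && !is.na(am)) fat[ci] <- d
  for (k in 1:5) {
    if (ev[k] <= 0) next
    p <- pair_no[ci, k]
    variant <- if (k < ci) 1L else 2L  # which pair member is newly entered
    row[pair_i(p, variant)] <- row[pair_i(p, variant)] + ev[k]
  }
  row[DEATH_I] <- d
  row[single_i(ci, 2L, s)] <- 1 - sum(ev) - d
  list(row = row, fatal = fat)
}

# comorbidity mortality rule per pair, precomputed once:
# 1 CAD+stroke, 2 CAD+diabetes, 3 CAD+myopathy, 4 stroke pair or
# stroke+myopathy, 5 stroke+diabetes, 6 diabetes+myopathy
pair_mort_rule <- local({
  rule <- NULL
  function() {
    if (is.null(rule)) {
      pr <- cond_pairs()
      rule <<- vapply(seq_len(10), function(p) {
        cs <- c(pr$c1i[p], pr$c2i[p])
        if (1L %in% cs && any(c(2L, 3L) %in% cs)) 1L
        else if (1L %in% cs && 4L %in% cs) 2L
        else if (1L %in% cs) 3L
        else if (4L %in% cs && any(c(2L, 3L) %in% cs)) 5L
        else if (any(c(2L, 3L) %in% cs)) 4L
        else 6L
      }, integer(1))
    }
    rule
  }
})

# row for a comorbid pair state: no third condition can be acquired, so
# the row is mortality vs stay. In an acute variant the newly entered
# CAD/stroke's case fatality governs the year (deaths carry its fatal
# cost); chronic pairs use the comorbidity mortality rules.
pair_row <- function(ctx, p, variant, q) {
  pv <- ctx$pv
  pr <- cond_pairs()
  new_i <- if (variant == 1L) pr$c1i[p] else if (variant == 2L) pr$c2i[p]
           else 0L
  fat <- numeric(3)
  am <- if (new_i > 0L) acute_mortality(new_i, pv) else NA_real_
  d <- if (!is.na(am)) {
    fat[new_i] <- am
    am
  } else {
    switch(pair_mort_rule()[p],
      pv[["mort_stroke_cad"]],
      hz(pv[["mort_chronic_cad"]], pv[["hr_mort_cad_diabetes"]]),
      pv[["mort_chronic_cad"]],
      pv[["mort_chronic_stroke"]],
      hz(pv[["mort_chronic_stroke"]], pv[["rr_mort_istroke_diabetes"]]),
      hz(q, pv[["hr_mort_diabetes"]]))
  }
  row <- numeric(N_INTERNAL)
  row[DEATH_I] <- d
  row[pair_i(p, 3L)] <- 1 - d
  list(row = row, fatal = fat)
}

# assemble the full kernel (K: 64 x 64; F: 64 x 3 fatal-event split of the
# death flow, columns cad/istroke/hstroke) for one cell and one cycle
build_cell_kernel <- function(ctx, q) {
  K <- matrix(0, N_INTERNAL, N_INTERNAL)
  F <- matrix(0, N_INTERNAL, 3)
  for (s in 1:3) {
    r <- ef_row(ctx, s, q)
    K[ef_i(s), ] <- r$row
    F[ef_i(s), ] <- r$fatal
  }
  for (ci in 1:5) for (s in 1:3) for (ph in 1:2) {
    r <- single_row(ctx, ci, ph, s, q)
    K[single_i(ci, ph, s), ] <- r$row
    F[single_i(ci, ph, s), ] <- r$fatal
  }
  for (p in 1:10) for (v in 1:3) {
    r <- pair_row(ctx, p, v, q)
    K[pair_i(p, v), ] <- r$row
    F[pair_i(p, v), ] <- r$fatal
  }
  K[DEATH_I, DEATH_I] <- 1
  list(K = K, F = F)
}

# rows whose content depends on the background mortality of the cycle
q_dependent_rows <- function() {
  list(ef = 1:3,
       myo = expand.grid(s = 1:3), dia = expand.grid(s = 1:3),
       diamyo = pair_no[4, 5])
}

# kernels for every cycle of a cell, rebuilding only mortality-dependent
# rows after the first cycle
cell_kernels <- function(ctx, qs) {
  base <- build_cell_kernel(ctx, qs[1])
  out <- vector("list", length(qs))
  out[[1]] <- base
  if (length(qs) > 1) {
    for (t in 2:length(qs)) {
      K <- base$K
      F <- base$F
      q <- qs[t]
      for (s in 1:3) {
        r <- ef_row(ctx, s, q)
        K[ef_i(s), ] <- r$row
        F[ef_i(s), ] <- r$fatal
      }
      for (ci in c(4L, 5L)) for (s in 1:3) for (ph in 1:2) {
        r <- single_row(ctx, ci, ph, s, q)
        K[single_i(ci, ph, s), ] <- r$row
        F[single_i(ci, ph, s), ] <- r$fatal
      }
      p <- pair_no[4, 5]
      for (v in 1:3) {
        r <- pair_row(ctx, p, v, q)
        K[pair_i(p, v), ] <- r$row
        F[pair_i(p, v), ] <- r$fatal
      }
      out[[t]] <- list(K = K, F = F)
    }
  }
  out
}

internal_state_labels <- function() {
  it <- internal_states()
  vapply(seq_len(N_INTERNAL), function(i) {
    r <- it[i, ]
    switch(r$kind,
      ef = paste0("ef_", r$stratum),
      single = paste0(r$c1, ".", r$phase, ".", r$stratum),
      pair = paste0(r$c1, "_", r$c2, ".",
                    if (r$phase == "chronic") "chronic"
                    else paste0("acute_new_", r$newcond)),
      death = "death")
  }, character(1))
}

#' Build the per-cycle transition kernel for one treatment sub-stratum
#'
#' Returns the row-stochastic transition matrix over the engine's internal
#' state expansion for a given strategy, cycle, PRS stratum and treatment
#' group. The `treated` group of a strategy applies that strategy's
#' eligibility rule (statin hazard ratios on CAD/ischemic-stroke risk plus
#' side-effect risks in eligible strata); the `untreated` group faces the
#' natural history. The matrix carries a `fatal` attribute splitting each
#' state's death flow into fatal acute CAD / ischemic / hemorrhagic stroke
#' events (used to attach fatal event costs).
#'
#' @param strategy a strategy name or [strategy_config()].
#' @param ps a `parameter_set`.
#' @param life_table a `life_table` for background mortality.
#' @param cycle model cycle (0-based; sets the cohort age).
#' @param prs `"low"` or `"high"` PRS stratum.
#' @param group `"treated"` (enrolled, adherent initiators) or
#'   `"untreated"`.
#' @param start_age cohort age at cycle 0.
#' @param stroke_scope `"population"` (default: the general-population
#'   ischemic stroke risk applies to every event-free stratum) or
#'   `"at_risk"` (restricted to the CAD at-risk strata).
#' @return a labelled 64 x 64 `transition_kernel` matrix.
#' @export
build_kernel <- function(strategy, ps, life_table, cycle = 0,
                         prs = c("high", "low"),
                         group = c("treated", "untreated"),
                         start_age = 50,
                         stroke_scope = c("population", "at_risk")) {
  prs <- match.arg(prs)
  group <- match.arg(group)
  stroke_scope <- match.arg(stroke_scope)
  if (!inherits(strategy, "strategy_config")) {
    strategy <- strategy_config(strategy, ps)
  }
  pv <- as_param_vector(ps)
  treat <- if (group == "treated") strategy$eligible(strata3, prs)
           else rep(FALSE, 3)
  ctx <- cell_context(pv, prs, treat, stroke_scope)
  q <- life_table_q(life_table, start_age + cycle)
  kern <- build_cell_kernel(ctx, q)
  lab <- internal_state_labels()
  K <- kern$K
  dimnames(K) <- list(lab, lab)
  bad <- abs(rowSums(K) - 1) > 1e-9
  if (any(bad)) {
    stop("internal consistency error: kernel row(s) not stochastic: ",
         paste(lab[bad], collapse = ", "))
  }
  structure(K, fatal = kern$F, class = c("transition_kernel", "matrix",
                                         "array"))
}

# --- reward vectors ----------------------------------------------------------

# state-level base rewards for one cell; age disutility and discounting are
# applied per cycle. Mirrors state_utility()/state_cost(), vectorised over
# the internal expansion (agreement is asserted in the test suite).
cell_rewards <- function(ctx) {
  pv <- ctx$pv
  m <- istate_meta()
  u_cond <- c(pv[["u_cad"]], pv[["u_stroke"]], pv[["u_stroke"]],
              pv[["u_diabetes"]], pv[["u_myopathy"]])
  du_ac <- c(pv[["du_acute_cad"]], pv[["du_acute_stroke"]],
             pv[["du_acute_stroke"]], 0, 0)
  ac_cost <- c(pv[["cost_acute_cad_nonfatal"]],
               pv[["cost_acute_istroke_nonfatal"]],
               pv[["cost_acute_hstroke_nonfatal"]],
               pv[["cost_fu_diabetes"]], pv[["cost_fu_myopathy"]])
  fu_cost <- vapply(conditions5, followup_cost, numeric(1), pv = pv)
  pick <- function(vals, idx) ifelse(idx > 0L, vals[pmax(idx, 1L)], 0)
  u1 <- ifelse(m$c1i > 0L, u_cond[pmax(m$c1i, 1L)], 1)
  u2 <- ifelse(m$c2i > 0L, u_cond[pmax(m$c2i, 1L)], 1)
  u0 <- ifelse(m$kind == 4L, 0, u1 * u2 - pick(du_ac, m$newi))
  cost_of <- function(ci) {
    ifelse(ci == 0L, 0,
           ifelse(ci == m$newi, ac_cost[pmax(ci, 1L)],
                  fu_cost[pmax(ci, 1L)]))
  }
  med0 <- cost_of(m$c1i) + cost_of(m$c2i)
  prod0 <- ifelse(m$has_cvd,
                  ifelse(m$new_cvd, pv[["cost_prod_first_year"]],
                         pv[["cost_prod_followup"]]), 0) +
    m$has_dia * pv[["cost_prod_diabetes"]] +
    m$has_myo * pv[["cost_prod_myopathy"]]
  treat_s <- ifelse(m$stratum > 0L, ctx$treat[pmax(m$stratum, 1L)], FALSE)
  statin <- (m$kind == 1L & treat_s) |
    (m$kind == 2L & treat_s & !(m$c1i %in% c(3L, 5L)))
  fatal_costs <- c(pv[["cost_acute_cad_fatal"]],
                   pv[["cost_acute_istroke_fatal"]],
                   pv[["cost_acute_hstroke_fatal"]])
  list(u0 = u0, med0 = med0, prod0 = prod0, alive = m$alive, statin = statin,
       fatal_costs = fatal_costs)
}

# --- cell chain --------------------------------------------------------------

# run one cell: returns the internal occupancy trace plus per-cycle
# undiscounted reward components
run_cell <- function(ctx, qs, init_strata, horizon, migration = NULL,
                     migration_start = 1, reward_timing = "cycle_end") {
  kernels <- cell_kernels(ctx, qs)
  rew <- cell_rewards(ctx)
  pv <- ctx$pv
  x <- matrix(0, horizon + 1, N_INTERNAL)
  x[1, 1:3] <- init_strata
  qaly <- numeric(horizon)
  bg <- numeric(horizon)
  med <- numeric(horizon)
  prod_c <- numeric(horizon)
  statin_c <- numeric(horizon)
  alive_start <- numeric(horizon)
  du <- pv[["du_age"]]
  for (t in seq_len(horizon)) {
    if (!is.null(migration) && (t - 1) >= migration_start) {
      x[t, 1:3] <- as.vector(x[t, 1:3] %*% migration)
    }
    alive_start[t] <- 1 - x[t, DEATH_I]
    kt <- kernels[[t]]
    x[t + 1, ] <- as.vector(x[t, ] %*% kt$K)
    fatal_flow <- as.vector(x[t, ] %*% kt$F)
    z <- if (reward_timing == "cycle_end") x[t + 1, ] else x[t, ]
    tau <- if (reward_timing == "cycle_end") t else t - 1
    u_t <- pmax(rew$u0 - du * tau, 0)
    u_t[!rew$alive] <- 0
    qaly[t] <- sum(z * u_t)
    bg[t] <- sum(z[rew$alive]) * pv[["cost_background"]]
    med[t] <- sum(z * rew$med0) + sum(fatal_flow * rew$fatal_costs)
    prod_c[t] <- sum(z * rew$prod0)
    statin_c[t] <- sum(z[rew$statin]) * pv[["cost_statin"]]
  }
  list(x = x, qaly = qaly, background = bg, medical = med,
       productivity = prod_c, statin = statin_c, alive_start = alive_start)
}

# --- cohort run --------------------------------------------------------------

# Decompose the cohort into cells sharing one set of dynamics: PRS stratum
# (20% top quintile / 80% bottom) x {enrolled-adherent initiators (treated
# per the strategy's eligibility rule), enrolled non-adherent, non-enrolled}.
# Non-enrolled cells face no program costs and no treatment — the
# no-program natural history.
cohort_cells <- function(strategy) {
  e <- strategy$enrollment
  adh <- strategy$adherence * strategy$statin_initiation
  cells <- list()
  for (prs in c("low", "high")) {
    w_prs <- if (prs == "high") 0.2 else 0.8
    untreated <- rep(FALSE, 3)
    elig <- strategy$eligible(strata3, prs)
    if (e > 0) {
      cells[[length(cells) + 1]] <- list(prs = prs, treat = elig,
                                         w = w_prs * e * adh, program = TRUE)
      cells[[length(cells) + 1]] <- list(prs = prs, treat = untreated,
                                         w = w_prs * e * (1 - adh),
                                         program = TRUE)
    }
    cells[[length(cells) + 1]] <- list(prs = prs, treat = untreated,
                                       w = w_prs * (1 - e), program = FALSE)
  }
  cells[vapply(cells, function(c) c$w > 0, logical(1))]
}

#' Run the cohort simulation for one strategy
#'
#' Iterates the closed cohort through the annual transition kernels over the
#' horizon, accumulating discounted costs (split into program, medical,
#' productivity and background ledgers) and QALYs. Enrollment mixes program
#' dynamics with no-program dynamics for the non-enrolled remainder, and
#' adherence splits statin initiators into a persistent treated sub-stratum
#' at model start. Rewards accrue on end-of-cycle occupancy and cycle `t`
#' (0-based) is discounted by `(1 + discount)^-t`; screening costs attach to
#' the start-of-cycle living cohort.
#'
#' @param strategy a strategy name or [strategy_config()].
#' @param ps a `parameter_set`.
#' @param life_table a `life_table`.
#' @param horizon number of annual cycles (default 5).
#' @param discount annual discount rate for both costs and QALYs.
#' @param start_age cohort age at model start.
#' @param migration optional PCE risk-category migration (see
#'   [make_migration()]), composed before event transitions from cycle
#'   `migration_start` onward: either one 3 x 3 matrix for the whole
#'   cohort, or `list(enrolled = , nonenrolled = )` applying different
#'   matrices to the enrolled and non-enrolled fractions.
#' @param migration_start first cycle (0-based) in which migration acts.
#' @param reward_timing occupancy snapshot carrying state rewards:
#'   `"cycle_end"` (default; the cycle's events are reflected) or
#'   `"cycle_start"`.
#' @param stroke_scope `"population"` (default) applies the
#'   general-population ischemic stroke risk to every event-free stratum;
#'   `"at_risk"` restricts it to the CAD at-risk strata.
#' @param cache optional environment reusing cell chains across strategies.
#' @return a `cohort_trace`: list with `occupancy` (cycle-start occupancy of
#'   the 22 nominal states, `(horizon+1)` rows), `cycles` (per-cycle
#'   discounted QALYs and cost ledgers), and `totals`.
#' @export
run_cohort <- function(strategy, ps, life_table, horizon = 5,
                       discount = 0.03, start_age = 50, migration = NULL,
                       migration_start = 1,
                       reward_timing = c("cycle_end", "cycle_start"),
                       stroke_scope = c("population", "at_risk"),
                       cache = NULL) {
  reward_timing <- match.arg(reward_timing)
  stroke_scope <- match.arg(stroke_scope)
  if (horizon < 1) stop("horizon must be at least 1 cycle")
  if (!inherits(strategy, "strategy_config")) {
    strategy <- strategy_config(strategy, ps)
  }
  pv <- as_param_vector(ps)
  shares <- c(pv[["p_low_pce"]], pv[["p_mod_pce"]], pv[["p_high_pce"]])
  shares <- shares / sum(shares)
  qs <- life_table_q(life_table, start_age + 0:(horizon - 1))
  disc <- (1 + discount)^-(0:(horizon - 1))
  if (is.null(cache)) cache <- new.env(parent = emptyenv())

  if (!is.null(migration) && !is.matrix(migration) &&
      !all(c("enrolled", "nonenrolled") %in% names(migration))) {
    stop("migration must be a 3x3 matrix or list(enrolled =, nonenrolled =)")
  }
  cell_migration <- function(enrolled) {
    if (is.null(migration) || is.matrix(migration)) return(migration)
    if (enrolled) migration$enrolled else migration$nonenrolled
  }
  get_chain <- function(prs, treat, mig) {
    key <- paste(prs, paste(as.integer(treat), collapse = ""),
                 if (is.null(mig)) "nomig"
                 else paste(c(mig, migration_start), collapse = ","),
                 reward_timing, stroke_scope, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    ctx <- cell_context(pv, prs, treat, stroke_scope)
    ch <- run_cell(ctx, qs, shares, horizon, mig, migration_start,
                   reward_timing)
    cache[[key]] <- ch
    ch
  }

  cells <- cohort_cells(strategy)

  occ <- matrix(0, horizon + 1, 22)
  ss_ids <- build_state_space()$id
  colnames(occ) <- ss_ids
  qaly <- bgc <- medc <- prodc <- progc <- numeric(horizon)
  for (cell in cells) {
    if (cell$w <= 0) next
    ch <- get_chain(cell$prs, cell$treat, cell_migration(cell$program))
    map <- match(internal_to_nominal(cell$prs), ss_ids)
    for (j in seq_len(N_INTERNAL)) {
      occ[, map[j]] <- occ[, map[j]] + cell$w * ch$x[, j]
    }
    qaly <- qaly + cell$w * ch$qaly * disc
    bgc <- bgc + cell$w * ch$background * disc
    medc <- medc + cell$w * ch$medical * disc
    prodc <- prodc + cell$w * ch$productivity * disc
    prog_t <- cell$w * ch$statin * disc
    if (cell$program) {
      sched <- strategy$screening_cost(0:(horizon - 1), cell$prs)
      prog_t <- prog_t + cell$w * ch$alive_start * sched * disc
    }
    progc <- progc + prog_t
  }
  cycles <- tibble::tibble(
    cycle = 0:(horizon - 1),
    discount_factor = disc,
    qalys = qaly,
    cost_program = progc,
    cost_medical = medc,
    cost_productivity = prodc,
    cost_background = bgc,
    cost_total = progc + medc + prodc + bgc
  )
  structure(list(
    strategy = strategy$name,
    occupancy = occ,
    cycles = cycles,
    totals = list(cost = sum(cycles$cost_total), qalys = sum(cycles$qalys)),
    settings = list(horizon = horizon, discount = discount,
                    start_age = start_age, reward_timing = reward_timing,
                    migration = migration, migration_start = migration_start)
  ), class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace> ", x$strategy, ": ",
      x$settings$horizon, "-year horizon | total cost $",
      format(round(x$totals$cost), big.mark = ","), " | ",
      sprintf("%.3f", x$totals$qalys), " QALYs per employee\n", sep = "")
  invisible(x)
}

#' Total discounted outcomes of a cohort trace
#'
#' @param trace a `cohort_trace` from [run_cohort()].
#' @return list with `total_cost` (US$) and `total_qalys`, per cohort
#'   member.
#' @export
total_outcomes <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  list(total_cost = trace$totals$cost, total_qalys = trace$totals$qalys)
}

#' Run all strategies on one parameter set
#'
#' Cell chains shared between strategies (e.g. untreated natural history)
#' are computed once.
#'
#' @inheritParams run_cohort
#' @param strategies character vector of strategy names.
#' @param migration optional named list of per-strategy migration matrices.
#' @return named list of `cohort_trace` objects.
#' @export
run_strategies <- function(ps, life_table,
                           strategies = strategy_names, migration = NULL,
                           ...) {
  cache <- new.env(parent = emptyenv())
  out <- list()
  for (s in strategies) {
    mig <- if (is.null(migration)) NULL else migration[[s]]
    out[[s]] <- run_cohort(s, ps, life_table, migration = mig, cache = cache,
                           ...)
  }
  out
}

#' Export a cohort trace as a long table
#'
#' @param trace a `cohort_trace`.
#' @return tibble with columns `cycle`, `state`, `occupancy` (cycle-start
#'   occupancy fractions).
#' @export
trace_occupancy <- function(trace) {
  occ <- trace$occupancy
  tibble::tibble(
    cycle = rep(seq_len(nrow(occ)) - 1L, times = ncol(occ)),
    state = rep(colnames(occ), each = nrow(occ)),
    occupancy = as.vector(occ)
  )
}
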