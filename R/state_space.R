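# Health-state enumeration.
#
# The nominal model has 22 mutually exclusive states: 6 event-free risk
# strata ({low, moderate, high} PCE x {bottom-80%, top-20%} PRS), 5
# single-condition states (CAD, ischemic stroke, hemorrhagic stroke,
# diabetes, myopathy), the 10 unordered pairs of those conditions, and
# death. Triple comorbidity is not modelled: a pair state that would
# acquire a third condition stays where it is, which is the unique
# enumeration consistent with 6 + 5 + 10 + 1 = 22.
#
# Internally the engine expands this to 64 states per cohort cell so that
# (i) the PCE stratum is retained on single-condition states (their
# residual CAD/stroke risks are stratum-specific) and (ii) the cycle in
# which a condition is entered is distinguishable (acute-phase case
# fatality, costs and disutility apply only then; equivalent to one-cycle
# tunnel states).

conditions5 <- c("cad", "istroke", "hstroke", "diabetes", "myopathy")
strata3 <- c("low", "mod", "high")

cond_pairs <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      idx <- utils::combn(5, 2)
      tab <<- data.frame(c1 = conditions5[idx[1, ]],
                         c2 = conditions5[idx[2, ]],
                         c1i = idx[1, ], c2i = idx[2, ],
                         stringsAsFactors = FALSE)
    }
    tab
  }
})

#' Enumerate the 22 model health states
#'
#' @return a tibble with one row per state: `id`, `risk_stratum` (PCE
#'   stratum of event-free states, `NA` elsewhere), `prs` (PRS stratum of
#'   event-free states), `conditions` (list column of condition tags, up to
#'   two), and `is_death`.
#' @export
build_state_space <- function() {
  ef <- expand.grid(prs = c("lowprs", "highprs"), stratum = strata3,
                    stringsAsFactors = FALSE)
  ef_ids <- paste0("ef_", ef$stratum, "_", ef$prs)
  pr <- cond_pairs()
  tibble::tibble(
    id = c(ef_ids, conditions5, paste0(pr$c1, "_", pr$c2), "death"),
    risk_stratum = c(ef$stratum, rep(NA_character_, 16)),
    prs = c(ef$prs, rep(NA_character_, 16)),
    conditions = c(rep(list(character(0)), 6),
                   as.list(conditions5),
                   mapply(c, pr$c1, pr$c2, SIMPLIFY = FALSE,
                          USE.NAMES = FALSE),
                   list(character(0))),
    is_death = c(rep(FALSE, 21), TRUE)
  )
}

#' Write the state space as a JSON document
#'
#' Dumps state ids, tags and the reward hooks that apply to each state, for
#' documentation and fixtures.
#'
#' @param path destination `.json` file.
#' @return `path`, invisibly.
#' @export
dump_state_space <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("dump_state_space() requires the jsonlite package")
  }
  ss <- build_state_space()
  out <- lapply(seq_len(nrow(ss)), function(i) {
    conds <- ss$conditions[[i]]
    list(
      id = ss$id[i],
      risk_stratum = if (is.na(ss$risk_stratum[i])) NULL else ss$risk_stratum[i],
      prs = if (is.na(ss$prs[i])) NULL else ss$prs[i],
      conditions = if (length(conds)) conds else list(),
      is_death = ss$is_death[i],
      reward_hooks = if (ss$is_death[i]) {
        list("fatal acute event cost on entry cycle")
      } else if (length(conds) == 0) {
        list("utility 1 minus age disutility", "background healthcare cost",
             "program costs per strategy schedule")
      } else {
        list("product of condition utility weights minus acute and age disutility",
             "acute event cost in entry cycle, follow-up costs thereafter",
             "lost productivity (absenteeism + presenteeism)",
             "background healthcare cost")
      }
    )
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# --- internal expanded state table ------------------------------------------

# index helpers for the 64-state expansion (per cohort cell)
ef_i <- function(s) s
single_i <- function(cond, phase, s) {
  # cond, phase, s integer; phase 1 = acute (entered this cycle), 2 = chronic
  3L + (cond - 1L) * 6L + (phase - 1L) * 3L + s
}
pair_no <- local({
  m <- matrix(0L, 5, 5)
  k <- 0L
  for (a in 1:4) for (b in (a + 1):5) { k <- k + 1L; m[a, b] <- k; m[b, a] <- k }
  m
})
pair_i <- function(p, variant) 33L + (p - 1L) * 3L + variant
DEATH_I <- 64L
N_INTERNAL <- 64L

# variant: 1 = acute, new condition is the pair's first member; 2 = acute,
# new condition is the second member; 3 = chronic
internal_states <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    pr <- cond_pairs()
    rows <- vector("list", N_INTERNAL)
    for (s in 1:3) {
      rows[[ef_i(s)]] <- data.frame(kind = "ef", c1 = NA, c2 = NA,
                                    phase = NA, newcond = NA,
                                    stratum = strata3[s])
    }
    for (ci in 1:5) for (ph in 1:2) for (s in 1:3) {
      rows[[single_i(ci, ph, s)]] <- data.frame(
        kind = "single", c1 = conditions5[ci], c2 = NA,
        phase = c("acute", "chronic")[ph],
        newcond = if (ph == 1) conditions5[ci] else NA,
        stratum = strata3[s])
    }
    for (p in 1:10) for (v in 1:3) {
      rows[[pair_i(p, v)]] <- data.frame(
        kind = "pair", c1 = pr$c1[p], c2 = pr$c2[p],
        phase = if (v == 3) "chronic" else "acute",
        newcond = if (v == 1) pr$c1[p] else if (v == 2) pr$c2[p] else NA,
        stratum = NA)
    }
    rows[[DEATH_I]] <- data.frame(kind = "death", c1 = NA, c2 = NA,
                                  phase = NA, newcond = NA, stratum = NA)
    tab <<- do.call(rbind, rows)
    tab$idx <- seq_len(N_INTERNAL)
    tab
  }
})

# integer metadata for the internal expansion, for vectorised reward and
# kernel construction: kind (1 ef, 2 single, 3 pair, 4 death), condition
# codes (0 = none), newly-entered condition code, stratum index
istate_meta <- local({
  meta <- NULL
  function() {
    if (!is.null(meta)) return(meta)
    it <- internal_states()
    kind <- match(it$kind, c("ef", "single", "pair", "death"))
    c1i <- ifelse(is.na(it$c1), 0L, match(it$c1, conditions5))
    c2i <- ifelse(is.na(it$c2), 0L, match(it$c2, conditions5))
    newi <- ifelse(is.na(it$newcond), 0L, match(it$newcond, conditions5))
    si <- ifelse(is.na(it$stratum), 0L, match(it$stratum, strata3))
    meta <<- list(kind = kind, c1i = c1i, c2i = c2i, newi = newi,
                  stratum = si,
                  has_cvd = (c1i %in% 1:3) | (c2i %in% 1:3),
                  new_cvd = newi %in% 1:3,
                  has_dia = c1i == 4L | c2i == 4L,
                  has_myo = c1i == 5L | c2i == 5L,
                  alive = kind != 4L)
    meta
  }
})

# map internal state -> nominal 22-state id, given the cell's PRS stratum
internal_to_nominal <- local({
  cache <- list()
  function(prs) {
    if (!is.null(cache[[prs]])) return(cache[[prs]])
    it <- internal_states()
    ids <- character(N_INTERNAL)
    for (i in seq_len(N_INTERNAL)) {
      r <- it[i, ]
      ids[i] <- switch(r$kind,
        ef = paste0("ef_", r$stratum, "_",
                    if (prs == "high") "highprs" else "lowprs"),
        single = r$c1,
        pair = paste0(r$c1, "_", r$c2),
        death = "death")
    }
    cache[[prs]] <<- ids
    ids
  }
})

# --- reward composition ------------------------------------------------------

cond_utility <- function(cond, pv) {
  switch(cond,
    cad = pv[["u_cad"]],
    istroke = pv[["u_stroke"]],
    hstroke = pv[["u_stroke"]],
    diabetes = pv[["u_diabetes"]],
    myopathy = pv[["u_myopathy"]])
}

acute_disutility <- function(cond, pv) {
  switch(cond,
    cad = pv[["du_acute_cad"]],
    istroke = pv[["du_acute_stroke"]],
    hstroke = pv[["du_acute_stroke"]],
    0)
}

acute_cost <- function(cond, pv, fatal = FALSE) {
  if (fatal) {
    switch(cond,
      cad = pv[["cost_acute_cad_fatal"]],
      istroke = pv[["cost_acute_istroke_fatal"]],
      hstroke = pv[["cost_acute_hstroke_fatal"]],
      0)
  } else {
    switch(cond,
      cad = pv[["cost_acute_cad_nonfatal"]],
      istroke = pv[["cost_acute_istroke_nonfatal"]],
      hstroke = pv[["cost_acute_hstroke_nonfatal"]],
      diabetes = pv[["cost_fu_diabetes"]],
      myopathy = pv[["cost_fu_myopathy"]])
  }
}

# Follow-up years price chronic management plus recurrent events: the
# expected recurrence cost is the annual recurrence risk times the acute
# treatment cost (a cost adjustment, not a modelled state).
followup_cost <- function(cond, pv) {
  switch(cond,
    cad = pv[["cost_fu_cad"]] +
      pv[["risk_recurrent_cad"]] * pv[["cost_acute_cad_nonfatal"]],
    istroke = pv[["cost_fu_stroke"]] +
      pv[["risk_recurrent_istroke"]] * pv[["cost_acute_istroke_nonfatal"]],
    hstroke = pv[["cost_fu_stroke"]],
    diabetes = pv[["cost_fu_diabetes"]],
    myopathy = pv[["cost_fu_myopathy"]])
}

#' Utility weight of a health state
#'
#' Death has utility 0 and event-free states utility 1. Condition states
#' combine condition utility weights multiplicatively (CAD 0.790, stroke
#' 0.630, diabetes 0.800, myopathy 0.917 at baseline). An acute disutility
#' (CAD 0.041, stroke 0.220) is subtracted in the cycle a condition is
#' entered, and an aging disutility of 0.004 per elapsed model year is
#' subtracted for every living state. The result is floored at 0.
#'
#' @param state a state id from [build_state_space()] (e.g. `"cad"`,
#'   `"cad_diabetes"`, `"ef_high_highprs"`, `"death"`).
#' @param ps a `parameter_set`.
#' @param cycle elapsed model years (0 at model start).
#' @param new_condition condition entered this cycle (`NULL` if none), for
#'   the acute-phase disutility.
#' @return utility in `[0, 1]`.
#' @export
state_utility <- function(state, ps, cycle = 0, new_condition = NULL) {
  pv <- as_param_vector(ps)
  if (state == "death") return(0)
  conds <- state_conditions(state)
  u <- prod(vapply(conds, cond_utility, numeric(1), pv = pv), 1)
  if (!is.null(new_condition)) u <- u - acute_disutility(new_condition, pv)
  max(u - pv[["du_age"]] * cycle, 0)
}

state_conditions <- function(state) {
  if (state %in% conditions5) return(state)
  if (grepl("^ef_", state) || state == "death") return(character(0))
  parts <- strsplit(state, "_", fixed = TRUE)[[1]]
  if (!all(parts %in% conditions5)) stop("unknown state: ", state)
  parts
}

#' Annual cost of occupying a health state
#'
#' Decomposes the annual cost into the ledger the cohort trace reports:
#' * `background`: background healthcare cost for everyone alive;
#' * `medical`: acute event cost in the entry cycle (fatal variant if
#'   `died_this_cycle`), follow-up condition costs in later cycles, and
#'   statin therapy cost when `on_statin`;
#' * `productivity`: absenteeism plus presenteeism — `cost_prod_first_year`
#'   in the year a CAD or stroke is diagnosed, `cost_prod_followup`
#'   thereafter (and for myopathy), `cost_prod_diabetes` annually with
#'   diabetes.
#'
#' Program costs (screening, PRS test, app, genetic-consultation visit) are
#' strategy-level schedules and attach to the cohort trace, not to a state;
#' see [strategy_config()].
#'
#' @param state a state id from [build_state_space()].
#' @param ps a `parameter_set`.
#' @param cycle elapsed model years (unused by costs, kept for symmetry).
#' @param new_condition condition entered this cycle, if any.
#' @param died_this_cycle if `TRUE` with `state = "death"` and a
#'   `new_condition`, returns the fatal acute event cost.
#' @param on_statin whether the occupant takes statin therapy this cycle.
#' @return a list with components `background`, `medical`, `productivity`
#'   and their `total`.
#' @export
state_cost <- function(state, ps, cycle = 0, new_condition = NULL,
                       died_this_cycle = FALSE, on_statin = FALSE) {
  pv <- as_param_vector(ps)
  if (state == "death") {
    med <- if (died_this_cycle && !is.null(new_condition)) {
      acute_cost(new_condition, pv, fatal = TRUE)
    } else 0
    return(list(background = 0, medical = med, productivity = 0, total = med))
  }
  conds <- state_conditions(state)
  medical <- 0
  for (cn in conds) {
    medical <- medical + if (!is.null(new_condition) && cn == new_condition) {
      acute_cost(cn, pv)
    } else {
      followup_cost(cn, pv)
    }
  }
  if (on_statin) medical <- medical + pv[["cost_statin"]]
  cvd <- intersect(conds, c("cad", "istroke", "hstroke"))
  prod_cost <- 0
  if (length(cvd) > 0) {
    prod_cost <- if (!is.null(new_condition) && new_condition %in% cvd) {
      pv[["cost_prod_first_year"]]
    } else {
      pv[["cost_prod_followup"]]
    }
  }
  if ("diabetes" %in% conds) prod_cost <- prod_cost + pv[["cost_prod_diabetes"]]
  if ("myopathy" %in% conds) prod_cost <- prod_cost + pv[["cost_prod_myopathy"]]
  bg <- pv[["cost_background"]]
  list(background = bg, medical = medical, productivity = prod_cost,
       total = bg + medical + prod_cost)
}
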