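test_that("the state space enumerates 22 states with the published structure", {
  ss <- build_state_space()
  expect_equal(nrow(ss), 22)
  expect_false(anyDuplicated(ss$id) > 0)
  n_cond <- vapply(ss$conditions, length, integer(1))
  expect_equal(sum(n_cond == 0 & !ss$is_death), 6)   # event-free strata
  expect_equal(sum(n_cond == 1), 5)                  # single conditions
  expect_equal(sum(n_cond == 2), 10)                 # all C(5,2) pairs
  expect_equal(sum(ss$is_death), 1)
  # event-free strata cross 3 PCE categories with 2 PRS strata
  ef <- ss[!is.na(ss$risk_stratum), ]
  expect_equal(sort(unique(ef$risk_stratum)), c("high", "low", "mod"))
  expect_equal(sort(unique(ef$prs)), c("highprs", "lowprs"))
})

test_that("state utilities compose multiplicatively with acute and age decrements", {
  ps <- base_ps()
  expect_equal(state_utility("death", ps), 0)
  expect_equal(state_utility("cad", ps, cycle = 0), 0.790)
  expect_equal(state_utility("cad_diabetes", ps), 0.790 * 0.800)
  expect_equal(state_utility("cad", ps, new_condition = "cad"),
               0.790 - 0.041)
  expect_equal(state_utility("istroke", ps, new_condition = "istroke"),
               0.630 - 0.220)
  expect_equal(state_utility("ef_high_highprs", ps, cycle = 3),
               1 - 3 * 0.004)
  # floored at zero far beyond the horizon
  expect_equal(state_utility("diabetes_myopathy", ps, cycle = 400), 0)
  # a comorbid state is never better than its worst component
  singles <- c("cad", "istroke", "hstroke", "diabetes", "myopathy")
  for (a in seq_along(singles)) for (b in seq_along(singles)) {
    if (a >= b) next
    pair_id <- paste0(singles[a], "_", singles[b])
    expect_lte(state_utility(pair_id, ps),
               min(state_utility(singles[a], ps),
                   state_utility(singles[b], ps)))
  }
})

test_that("state costs decompose into background, medical and productivity", {
  ps <- base_ps()
  ef <- state_cost("ef_low_lowprs", ps)
  expect_equal(ef$total, 4941)
  expect_equal(ef$medical + ef$productivity, 0)
  # acute CAD year: admission cost plus first-year lost productivity
  ac <- state_cost("cad", ps, new_condition = "cad")
  expect_equal(ac$medical, 65442)
  expect_equal(ac$productivity, 73492)
  # follow-up CAD year prices chronic care plus expected recurrence
  fu <- state_cost("cad", ps)
  expect_equal(fu$medical, 11815 + 0.20 * 65442)
  expect_equal(fu$productivity, 9056)
  # statin therapy cost rides on the medical component
  expect_equal(state_cost("cad", ps, on_statin = TRUE)$medical -
                 fu$medical, 132)
  # comorbid pair sums both channels
  pr <- state_cost("cad_diabetes", ps)
  expect_equal(pr$medical, 11815 + 0.20 * 65442 + 10026)
  expect_equal(pr$productivity, 9056 + 9242)
  # death accrues nothing except a fatal acute event cost in the entry cycle
  expect_equal(state_cost("death", ps)$total, 0)
  expect_equal(state_cost("death", ps, new_condition = "cad",
                          died_this_cycle = TRUE)$medical, 18246)
  # the ledger always sums to the total
  for (id in c("ef_high_highprs", "cad", "istroke_myopathy", "death")) {
    cc <- state_cost(id, ps)
    expect_equal(cc$total, cc$background + cc$medical + cc$productivity)
  }
})

test_that("engine reward vectors agree with the state-level reward functions", {
  ps <- base_ps()
  pv <- prscea:::as_param_vector(ps)
  ctx <- prscea:::cell_context(pv, "high", c(FALSE, TRUE, TRUE))
  rew <- prscea:::cell_rewards(ctx)
  it <- prscea:::internal_states()
  ids <- prscea:::internal_to_nominal("high")
  for (i in sample(seq_len(nrow(it)), 25)) {
    new <- if (is.na(it$newcond[i])) NULL else it$newcond[i]
    expect_equal(rew$u0[i],
                 state_utility(ids[i], ps, cycle = 0, new_condition = new),
                 info = ids[i])
    cc <- state_cost(ids[i], ps, new_condition = new)
    expect_equal(rew$med0[i], cc$medical, info = ids[i])
    expect_equal(rew$prod0[i], cc$productivity, info = ids[i])
  }
})

test_that("the state space dumps to JSON", {
  skip_if_not_installed("jsonlite")
  path <- tempfile(fileext = ".json")
  dump_state_space(path)
  parsed <- jsonlite::read_json(path)
  expect_length(parsed, 22)
  expect_equal(parsed[[22]]$id, "death")
})
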