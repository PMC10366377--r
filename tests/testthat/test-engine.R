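test_that("transition kernels are row-stochastic for every configuration", {
  ps <- base_ps()
  lt <- base_lt()
  for (strat in c("CardioriskSCORE", "StandardWHP", "NoWHP")) {
    for (prs in c("low", "high")) for (grp in c("treated", "untreated")) {
      k <- build_kernel(strat, ps, lt, cycle = 0, prs = prs, group = grp)
      expect_lt(max(abs(rowSums(k) - 1)), 1e-9)
      expect_true(all(k >= 0 & k <= 1))
    }
  }
  # and under sampled parameter sets (probabilistic inputs)
  for (seed in 1:10) {
    psi <- sample_parameters(ps, rng_seed = seed)
    k <- build_kernel("CardioriskSCORE", psi, lt, cycle = 2, prs = "high",
                      group = "treated")
    expect_lt(max(abs(rowSums(k) - 1)), 1e-9)
  }
})

test_that("kernel event probabilities compose PRS and statin effects", {
  ps <- base_ps()
  k <- build_kernel("CardioriskSCORE", ps, base_lt(), prs = "high",
                    group = "treated")
  # treated high-PCE/high-PRS: direct 1.9-fold then statin hazard ratio
  p_cad <- sum(k["ef_high", grepl("^cad\\.acute", colnames(k))])
  expect_equal(p_cad, 1 - (1 - 0.022 * 1.9)^0.560)
  # untreated low-PCE stratum develops no CAD
  ku <- build_kernel("NoWHP", ps, base_lt(), prs = "low",
                     group = "untreated")
  expect_equal(sum(ku["ef_low", grepl("^cad\\.acute", colnames(ku))]), 0)
  # its ischemic stroke risk is the general-population rate by default,
  # and zero when restricted to the at-risk strata
  expect_equal(sum(ku["ef_low", grepl("^istroke\\.acute", colnames(ku))]),
               0.004)
  kr <- build_kernel("NoWHP", ps, base_lt(), prs = "low",
                     group = "untreated", stroke_scope = "at_risk")
  expect_equal(sum(kr["ef_low", grepl("^istroke\\.acute", colnames(kr))]), 0)
})

test_that("cohort mass is conserved and death is absorbing", {
  for (tr in base_traces()) {
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-9)
    expect_true(all(tr$occupancy >= -1e-15))
    expect_true(all(diff(tr$occupancy[, "death"]) >= -1e-12))
  }
  # also under migration
  sc <- run_scenario(base_ps(), base_lt())
  for (tr in sc$traces) {
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-9)
    expect_true(all(diff(tr$occupancy[, "death"]) >= -1e-12))
  }
})

test_that("the discounted QALY stream matches its closed form without events", {
  ps <- no_event_ps()
  lt <- base_lt()
  tr <- run_cohort("NoWHP", ps, lt, horizon = 5, discount = 0.03)
  expect_equal(tr$cycles$discount_factor[3], 1 / 1.03^2)
  q <- lt$qx[match(50:54, lt$age)]
  surv <- cumprod(1 - q)
  # end-of-cycle accrual: cycle t (0-based) carries survivors to t+1 at
  # utility 1 - 0.004 (t+1), discounted by 1.03^-t
  oracle <- sum(surv * (1 - 0.004 * (1:5)) / 1.03^(0:4))
  expect_equal(tr$totals$qalys, oracle)
  # a costless parameter set accrues no costs
  ps0 <- ps
  ps0$entries$baseline[ps0$entries$role == "cost"] <- 0
  tr0 <- run_cohort("NoWHP", ps0, lt)
  expect_equal(tr0$totals$cost, 0)
})

test_that("zero adherence collapses clinical outcomes across strategies", {
  ps <- set_params(base_ps(), adherence = 0)
  tr <- run_strategies(ps, base_lt())
  q <- vapply(tr, function(t) t$totals$qalys, numeric(1))
  expect_equal(unname(diff(range(q))), 0)
  expect_equal(tr$CardioriskSCORE$occupancy, tr$NoWHP$occupancy,
               tolerance = 1e-12)
  # only program costs differ once nobody takes the statin
  med <- vapply(tr, function(t) sum(t$cycles$cost_medical +
                                      t$cycles$cost_productivity +
                                      t$cycles$cost_background), numeric(1))
  expect_equal(unname(diff(range(med))), 0)
  expect_gt(sum(tr$CardioriskSCORE$cycles$cost_program), 0)
})

test_that("stronger statin effectiveness never lowers CardioriskSCORE QALYs", {
  lt <- base_lt()
  qalys <- vapply(c(0.40, 0.56, 0.78, 1.00), function(hr) {
    ps <- set_params(base_ps(), hr_statin_cad = hr)
    run_cohort("CardioriskSCORE", ps, lt)$totals$qalys
  }, numeric(1))
  expect_true(all(diff(qalys) <= 1e-12))
})

test_that("an individual-level simulation reproduces the cohort trace", {
  tr <- run_cohort("CardioriskSCORE", base_ps(), base_lt())
  mc <- simulate_cohort_mc("CardioriskSCORE", base_ps(), base_lt(),
                           n = 100000, seed = 7)
  p <- tr$occupancy
  se <- sqrt(pmax(p * (1 - p), 0) / mc$n)
  expect_true(all(abs(mc$occupancy - p) <= 3 * se + 1e-4))
})

test_that("traces expose totals, ledgers and long-format occupancy", {
  tr <- base_traces()$CardioriskSCORE
  out <- total_outcomes(tr)
  expect_equal(out$total_cost, sum(tr$cycles$cost_total))
  expect_equal(out$total_qalys, sum(tr$cycles$qalys))
  # the cost ledger decomposes the total exactly
  expect_equal(tr$cycles$cost_total,
               tr$cycles$cost_program + tr$cycles$cost_medical +
                 tr$cycles$cost_productivity + tr$cycles$cost_background)
  long <- trace_occupancy(tr)
  expect_equal(nrow(long), 6 * 22)
  expect_equal(sum(long$occupancy), 6, tolerance = 1e-9)
  expect_error(run_cohort("NoWHP", base_ps(), base_lt(), horizon = 0),
               "horizon")
})
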