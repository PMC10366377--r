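test_that("migration matrices are row-stochastic with complement diagonals", {
  nat <- make_migration(natural_migration_pct())
  expect_equal(rowSums(nat), c(low = 1, mod = 1, high = 1))
  expect_equal(nat["low", "low"], 0.70)
  expect_equal(nat["low", "mod"], 0.25)
  whp <- make_migration(whp_migration_pct())
  expect_equal(whp["high", "high"], 1 - 0.1565 - 0.4870)
  expect_equal(rowSums(whp), c(low = 1, mod = 1, high = 1))
  # no migration at all is the identity
  expect_equal(unclass(make_migration(rep(0, 6))), diag(3),
               ignore_attr = TRUE)
  expect_error(make_migration(c(60, 50, 0, 0, 0, 0)), "exceeds")
  expect_error(make_migration(c(-1, 0, 0, 0, 0, 0)), "non-negative")
})

test_that("the 0.52-natural blend reproduces the published weighted vector", {
  offdiag <- function(m) {
    100 * c(m[1, 2], m[1, 3], m[2, 1], m[2, 3], m[3, 1], m[3, 2])
  }
  published <- c(18.780, 2.900, 40.450, 14.080, 10.630, 39.500)
  b52 <- blend_migration(w_natural = 0.52)
  expect_true(all(abs(offdiag(b52) - published) < 0.005))
  # the alternative weight assignment is not self-consistent with the text
  b48 <- blend_migration(w_natural = 0.48)
  expect_false(all(abs(offdiag(b48) - published) < 0.005))
  # convex-combination limits
  nat <- make_migration(natural_migration_pct())
  expect_equal(blend_migration(w_natural = 1), nat, ignore_attr = TRUE)
  expect_error(blend_migration(w_natural = 1.2), "\\[0, 1\\]")
  expect_equal(rowSums(b52), c(low = 1, mod = 1, high = 1))
})

test_that("identity migration reproduces the base case bit-for-bit", {
  id <- make_migration(rep(0, 6))
  sc <- run_scenario(base_ps(), base_lt(), migration_whp = id,
                     migration_nowhp = id)
  base <- base_traces()
  for (s in names(base)) {
    expect_identical(sc$traces[[s]]$totals, base[[s]]$totals)
    expect_identical(sc$traces[[s]]$occupancy, base[[s]]$occupancy)
  }
})

test_that("migration relabels risk categories without moving cohort mass", {
  # with events and mortality switched off, migration only shuffles the
  # event-free block: total mass 1 in the strata, drifting across them
  ps <- set_params(no_event_ps(), du_age = 0)
  lt <- structure(data.frame(age = 50:60, qx = 1e-12),
                  class = c("life_table", "data.frame"))
  sc <- run_scenario(ps, lt, wtp = 50000)
  occ <- sc$traces$NoWHP$occupancy
  ef_cols <- grepl("^ef_", colnames(occ))
  expect_equal(unname(rowSums(occ[, ef_cols])), rep(1, 6),
               tolerance = 1e-9)
  # natural migration moves the no-program cohort across categories from
  # the second year on (cycle-start occupancy reflects that year's
  # rescreening)
  expect_gt(max(abs(occ[2, ef_cols] - occ[1, ef_cols])), 0.01)
})

test_that("risk migration strengthens the case for polygenic screening", {
  sc <- run_scenario(base_ps(), base_lt())
  cea <- sc$cea
  expect_equal(cea$comparisons$icer_label, c("Dominant", "Dominant"))
  # more favourable risk drift among the enrolled widens both increments
  base <- base_cea()
  expect_gt(-delta_of(cea, "NoWHP"), -delta_of(base, "NoWHP"))
  expect_gt(delta_of(cea, "NoWHP", "delta_qalys"),
            delta_of(base, "NoWHP", "delta_qalys"))
  # the no-program cohort, drifting naturally, is no cheaper than at base
  expect_gte(sc$traces$NoWHP$totals$cost, base_traces()$NoWHP$totals$cost)
})
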