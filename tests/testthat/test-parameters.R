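test_that("packaged parameter table carries the published inputs", {
  ps <- base_ps()
  e <- ps$entries
  statin <- e[e$name == "hr_statin_cad", ]
  expect_equal(statin$baseline, 0.560)
  expect_equal(c(statin$low, statin$high), c(0.400, 0.780))
  expect_equal(statin$dist_family, "lognormal")
  expect_equal(c(statin$shape_a, statin$shape_b), c(-0.580, 0.090))
  expect_equal(param_value(ps, "cost_prs_test"), 145)
  expect_equal(param_value(ps, "risk_ischemic_stroke"), 0.004)
  expect_equal(param_value(ps, "u_stroke"), 0.630)
  # initial PCE shares form a probability vector
  expect_equal(param_value(ps, "p_low_pce") + param_value(ps, "p_mod_pce") +
                 param_value(ps, "p_high_pce"), 1)
  expect_true(all(required_parameter_names() %in% e$name))
})

test_that("parameter validation rejects broken tables", {
  e <- base_ps()$entries
  expect_error(validate_parameters(e[e$name != "risk_ischemic_stroke", ]),
               "risk_ischemic_stroke")
  bad <- e
  bad$baseline[bad$name == "u_cad"] <- 1.2
  expect_error(validate_parameters(bad), "u_cad")
  bad <- e
  bad$low[bad$name == "cost_statin"] <- 500
  expect_error(validate_parameters(bad), "bracket")
  bad <- e
  bad$dist_family[bad$name == "cost_statin"] <- "beta"
  expect_error(validate_parameters(bad), "incompatible")
})

test_that("risk annualisation follows the constant-hazard formula", {
  expect_equal(annualize_risk(0.20, 10), 1 - 0.8^0.1)
  # the published annual CAD risks are the rounded annualised 10-year risks
  expect_equal(round(annualize_risk(0.20, 10), 3), 0.022)
  expect_equal(round(annualize_risk(0.125, 10), 3), 0.013)
  expect_equal(annualize_risk(0, 7), 0)
  expect_error(annualize_risk(1, 10), "\\[0, 1\\)")
  # identity at one year and monotonicity in the horizon risk
  p <- seq(0, 0.95, by = 0.05)
  expect_equal(annualize_risk(p, 1), p)
  expect_true(all(diff(annualize_risk(p, 10)) > 0))
})

test_that("relative effects transform probabilities on the stated scales", {
  expect_equal(apply_relative_effect(0.022, 1.9, "direct"), 0.0418)
  expect_equal(apply_relative_effect(0.004, 2.27, "hazard"),
               1 - 0.996^2.27)
  expect_equal(round(apply_relative_effect(0.004, 2.27, "hazard"), 5),
               0.00906)
  # identity effect, capping, odds transform
  expect_equal(apply_relative_effect(0.3, 1, "hazard"), 0.3)
  expect_equal(apply_relative_effect(0.3, 1, "direct"), 0.3)
  expect_equal(apply_relative_effect(0.9, 5, "direct"), 1)
  expect_equal(apply_relative_effect(0.5, 2, "odds"), 2 / 3)
  expect_error(apply_relative_effect(0.5, 0, "hazard"), "positive")
  # hazard-scale multiplicativity: e1 then e2 equals e1 * e2
  for (p in c(0.004, 0.022, 0.3)) {
    for (e1 in c(0.56, 1.9)) {
      once <- apply_relative_effect(p, e1 * 2.27, "hazard")
      twice <- apply_relative_effect(
        apply_relative_effect(p, e1, "hazard"), 2.27, "hazard")
      expect_equal(twice, once)
    }
  }
})

test_that("shipped distribution shapes reproduce the printed baselines", {
  e <- base_ps()$entries
  imp <- ifelse(e$dist_family == "beta", e$shape_a / (e$shape_a + e$shape_b),
                ifelse(e$dist_family == "gamma", e$shape_a / e$shape_b, NA))
  chk <- e$dist_family %in% c("beta", "gamma")
  expect_true(all(abs(imp[chk] - e$baseline[chk]) / e$baseline[chk] < 0.02))
})

test_that("parameter sampling is reproducible, bounded and well-calibrated", {
  ps <- base_ps()
  a <- sample_parameters(ps, rng_seed = 11)
  b <- sample_parameters(ps, rng_seed = 11)
  expect_identical(a$entries$baseline, b$entries$baseline)
  draws <- sample_parameters(ps, rng_seed = 3, n = 200)
  e <- ps$entries
  prob_cols <- e$name[e$role %in% c("probability", "utility", "disutility")]
  expect_true(all(draws[, prob_cols] >= 0 & draws[, prob_cols] <= 1))
  expect_true(all(draws[, e$name[e$role == "cost"]] >= 0))
  # distribution means match their closed forms
  big <- sample_parameters(ps, rng_seed = 5, n = 10000)
  expect_equal(mean(big[, "p_low_pce"]), 8.66 / (8.66 + 12.46),
               tolerance = 0.01)
  expect_equal(mean(big[, "hr_statin_cad"]), exp(-0.58 + 0.09^2 / 2),
               tolerance = 0.01)
  # a fixed entry never moves
  fx <- ps
  fx$entries$dist_family[fx$entries$name == "cost_statin"] <- "fixed"
  dfx <- sample_parameters(fx, rng_seed = 3, n = 50)
  expect_true(all(dfx[, "cost_statin"] == 132))
})

test_that("per-parameter substreams are unaffected by other parameters", {
  ps <- base_ps()
  full <- sample_parameters(ps, rng_seed = 9, n = 100)
  sub <- ps
  sub$entries <- sub$entries[sub$entries$name != "cost_mobile_app", ]
  reduced <- sample_parameters(sub, rng_seed = 9, n = 100)
  expect_identical(full[, "hr_statin_cad"], reduced[, "hr_statin_cad"])
  expect_identical(full[, "p_high_pce"], reduced[, "p_high_pce"])
})

test_that("parameter files round-trip through CSV and YAML", {
  ps <- base_ps()
  csv <- tempfile(fileext = ".csv")
  yml <- tempfile(fileext = ".yaml")
  write_parameters(ps, csv)
  write_parameters(ps, yml)
  back_csv <- load_parameters(csv)
  back_yml <- load_parameters(yml)
  expect_equal(as.data.frame(back_csv$entries), as.data.frame(ps$entries))
  expect_equal(as.data.frame(back_yml$entries), as.data.frame(ps$entries))
  # the default writer emits the packaged file byte-identically
  golden <- tempfile(fileext = ".csv")
  write_default_parameters(golden)
  packaged <- system.file("extdata", "annual_parameters.csv",
                          package = "prscea")
  expect_identical(readBin(golden, "raw", file.size(golden)),
                   readBin(packaged, "raw", file.size(packaged)))
})
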