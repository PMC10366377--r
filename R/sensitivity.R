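# Uncertainty analyses: one-way (tornado) and probabilistic sensitivity
# analysis over the parameter table's distributions.

init_share_names <- c("p_low_pce", "p_mod_pce", "p_high_pce")

# Keep the perturbed initial-distribution share at its set value and
# rescale the other two to fill the simplex (probabilities must sum to 1).
renormalize_shares <- function(ps, varied) {
  v <- vapply(init_share_names, function(n) param_value(ps, n), numeric(1))
  others <- setdiff(init_share_names, varied)
  rest <- 1 - v[[varied]]
  tot <- sum(v[others])
  if (tot > 0) {
    for (n in others) {
      ps <- do.call(set_params, c(list(ps), setNames(v[[n]] / tot * rest, n)))
    }
  }
  ps
}

#' One-way sensitivity analysis (tornado)
#'
#' Reruns the full model with each parameter set to the low and then the
#' high endpoint of its published range, all others held at baseline, and
#' records the incremental net monetary benefit of the focal strategy
#' against each comparator. Parameters without a range are skipped with a
#' warning. Perturbed initial-distribution shares are renormalised so the
#' three shares still sum to 1.
#'
#' @param ps a `parameter_set`.
#' @param life_table a `life_table`.
#' @param wtp willingness-to-pay per QALY.
#' @param focal focal strategy name.
#' @param comparators comparator strategy names.
#' @param parameters optional subset of parameter names to vary (default:
#'   every parameter with a range).
#' @param ... passed to [run_cohort()].
#' @return tibble with one row per (parameter, comparator): endpoints,
#'   `inmb_low`, `inmb_high` and `bar_width = |inmb_high - inmb_low|`,
#'   sorted by descending width within comparator.
#' @export
one_way <- function(ps, life_table, wtp = 50000, focal = "CardioriskSCORE",
                    comparators = c("StandardWHP", "NoWHP"),
                    parameters = NULL, ...) {
  e <- ps$entries
  if (is.null(parameters)) parameters <- e$name
  base <- run_strategies(ps, life_table, ...)
  base_cea <- compare_strategies(base[c(focal, comparators)], wtp = wtp,
                                 focal = focal)
  rows <- list()
  for (nm in parameters) {
    i <- match(nm, e$name)
    if (is.na(i)) stop("unknown parameter: ", nm)
    if (is.na(e$low[i]) || is.na(e$high[i])) {
      warning("parameter '", nm, "' has no range; skipped", call. = FALSE)
      next
    }
    inmb_at <- function(value) {
      psi <- do.call(set_params, c(list(ps), setNames(value, nm)))
      if (nm %in% init_share_names) psi <- renormalize_shares(psi, nm)
      tr <- run_strategies(psi, life_table, ...)
      cea <- compare_strategies(tr[c(focal, comparators)], wtp = wtp,
                                focal = focal)
      setNames(cea$comparisons$inmb, cea$comparisons$comparator)
    }
    lo <- inmb_at(e$low[i])
    hi <- inmb_at(e$high[i])
    rows[[nm]] <- tibble::tibble(
      parameter = nm, comparator = comparators,
      value_low = e$low[i], value_high = e$high[i],
      inmb_low = unname(lo[comparators]), inmb_high = unname(hi[comparators]),
      inmb_base = unname(setNames(base_cea$comparisons$inmb,
                                  base_cea$comparisons$comparator)[comparators])
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(invisible(NULL))
  out$bar_width <- abs(out$inmb_high - out$inmb_low)
  out <- out[order(out$comparator, -out$bar_width), ]
  class(out) <- c("tornado", class(out))
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets from the table's beta/lognormal/gamma
#' distributions (independent draws, one reproducible substream per
#' parameter), reruns the cohort model for every draw, and records the
#' incremental cost and QALY cloud of the focal strategy against each
#' comparator together with cost-effectiveness acceptability curves. The
#' three initial-distribution shares are renormalised to the simplex
#' within each draw by the engine.
#'
#' @param ps a `parameter_set`.
#' @param life_table a `life_table`.
#' @param n number of Monte Carlo draws.
#' @param seed integer seed.
#' @param wtp willingness-to-pay per QALY at which `prob_ce` is reported.
#' @param wtp_grid thresholds at which the acceptability curve is
#'   evaluated.
#' @param focal focal strategy name.
#' @param comparators comparator strategy names.
#' @param ... passed to [run_cohort()].
#' @return a `psa_result`: list with `draws` (tibble: draw, comparator,
#'   `delta_cost`, `delta_qalys`), `ceac` (tibble: comparator, wtp,
#'   probability cost-effective), `prob_ce` at `wtp`, `n`, `seed`.
#' @export
psa <- function(ps, life_table, n = 10000, seed = 1, wtp = 50000,
                wtp_grid = seq(0, 100000, by = 5000),
                focal = "CardioriskSCORE",
                comparators = c("StandardWHP", "NoWHP"), ...) {
  stopifnot(n >= 1)
  draws <- sample_parameters(ps, rng_seed = seed, n = n)
  if (n == 1) {
    # sample_parameters returns a parameter_set for n = 1
    draws <- matrix(as_param_vector(draws), nrow = 1,
                    dimnames = list(NULL, ps$entries$name))
  }
  strategies <- c(focal, comparators)
  dc <- matrix(0, n, length(comparators),
               dimnames = list(NULL, comparators))
  de <- dc
  psi <- ps
  for (i in seq_len(n)) {
    psi$entries$baseline <- draws[i, ]
    tr <- run_strategies(psi, life_table, strategies = strategies, ...)
    tf <- total_outcomes(tr[[focal]])
    for (cm in comparators) {
      tc <- total_outcomes(tr[[cm]])
      dc[i, cm] <- tf$total_cost - tc$total_cost
      de[i, cm] <- tf$total_qalys - tc$total_qalys
    }
  }
  draws_tbl <- tibble::tibble(
    draw = rep(seq_len(n), times = length(comparators)),
    comparator = rep(comparators, each = n),
    delta_cost = as.vector(dc),
    delta_qalys = as.vector(de)
  )
  if (!wtp %in% wtp_grid) wtp_grid <- sort(c(wtp_grid, wtp))
  ceac <- do.call(rbind, lapply(comparators, function(cm) {
    tibble::tibble(
      comparator = cm,
      wtp = wtp_grid,
      prob_ce = vapply(wtp_grid, function(w) {
        mean(w * de[, cm] - dc[, cm] > 0)
      }, numeric(1))
    )
  }))
  prob_ce <- vapply(comparators, function(cm) {
    mean(wtp * de[, cm] - dc[, cm] > 0)
  }, numeric(1))
  structure(list(draws = draws_tbl, ceac = ceac, prob_ce = prob_ce,
                 n = n, seed = seed, wtp = wtp, focal = focal),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> ", x$n, " draws (seed ", x$seed, "), focal ", x$focal,
      "\nProbability cost-effective at WTP $",
      format(x$wtp, big.mark = ","), "/QALY:\n", sep = "")
  print(round(x$prob_ce, 3))
  invisible(x)
}
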