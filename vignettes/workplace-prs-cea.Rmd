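---
title: "A Markov cohort model of polygenic risk screening in workplace cardiovascular prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of polygenic risk screening in workplace cardiovascular prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decision problem

Standard workplace health programs (WHPs) screen employees for
cardiovascular risk with the pooled cohort equations (PCE), a 10-year
atherosclerotic risk calculator built on traditional risk factors. A
polygenic risk score for coronary artery disease (CAD-PRS) identifies an
additional group — employees in the top quintile of the PRS distribution
whose PCE risk is only moderate — who carry roughly 1.9-fold the CAD risk
of their PCE stratum but remain invisible to PCE-only screening. `prscea`
implements an annual-cycle Markov cohort model that asks, from a
self-insured employer's perspective, whether adding a one-time CAD-PRS
test to a workplace program pays for itself over a 5-year horizon through
avoided events and retained productivity.

Three strategies are compared on discounted costs (US$ 2019) and
quality-adjusted life years (QALYs) per employee:

* **CardioriskSCORE** — PCE plus CAD-PRS; every enrolled employee in an
  at-risk stratum (high PCE; or moderate PCE with high PRS) is
  recommended statin prevention;
* **StandardWHP** — PCE alone; only enrolled employees at high PCE risk
  are recommended statins;
* **NoWHP** — no program, no screening costs, natural history.

A strategy dominates a comparator when it both costs less and yields more
QALYs; otherwise the incremental cost-effectiveness ratio
$\mathrm{ICER} = \Delta C / \Delta E$ is judged against a willingness to
pay of \$50,000/QALY, and the incremental net monetary benefit is
$\mathrm{INMB} = \lambda\,\Delta E - \Delta C$.

## States and transitions

The model has 22 mutually exclusive health states: six event-free risk
strata ({low, moderate, high} PCE × {bottom-80%, top-20%} PRS), five
single conditions — the primary outcomes CAD and ischemic stroke, and the
statin side effects diabetes, hemorrhagic stroke and myopathy — the ten
unordered condition pairs, and death. Triple comorbidity is not modelled:
a pair state that would acquire a third condition stays where it is, the
unique enumeration consistent with 6 + 5 + 10 + 1 = 22. Internally every
cohort cell expands this to 64 states so that (i) single-condition states
retain their PCE stratum, which drives their residual event risks, and
(ii) the entry cycle of each condition is distinguishable.

Annual event probabilities come from the packaged parameter table:
at-risk strata face CAD risk 0.022 (high PCE) or 0.013 (moderate),
multiplied directly by 1.9 in the top PRS quintile — *direct* because the
source describes a fold increase in the risk itself — and capped at 1.
All hazard-ratio-labelled effects (statin HR 0.560 on CAD and 0.770 on
ischemic stroke, diabetes HRs, mortality multipliers) act on the hazard
scale, $p \mapsto 1-(1-p)^{\mathrm{HR}}$, which makes sequential effects
multiplicative. The annual ischemic stroke risk 0.004 is the
general-population rate (derived as $800{,}000 \times 0.9 / 200$M) and by
default applies to **every** event-free stratum; the
`stroke_scope = "at_risk"` option restricts it to the CAD at-risk strata
instead. Condition states keep stratum-specific risks: CAD risk is 0.017
after ischemic stroke, unchanged after hemorrhagic stroke or myopathy,
and hazard-scaled by 2.000 with statin-induced diabetes; ischemic stroke
risk is 0.015 after CAD, 0.057 after hemorrhagic stroke and hazard-scaled
by 2.270 with diabetes.

Treatment is a persistent trait fixed at model start: of the enrolled
cohort (52%), all employees eligible under the strategy's rule initiate
statins and half adhere; only the adherent receive the risk reductions,
the side-effect risks (myopathy $10^{-4}$, diabetes 0.0015, hemorrhagic
stroke 0.0002 per year) and the \$132 annual therapy cost. We assume
therapy continues after CAD, ischemic stroke or diabetes (so secondary
risk reductions and side-effect risks persist) but stops after its own
adverse events, hemorrhagic stroke and myopathy. Comorbid pair states
accrue no statin cost — their occupancy is of order $10^{-4}$ and they
acquire no further events, so the approximation is far below the model's
reporting precision.

### The acute phase as a one-cycle tunnel

Acute inputs (case fatality 0.228 for CAD, 0.100 for ischemic and 0.390
for hemorrhagic stroke; acute event costs; acute disutilities 0.041 and
0.220) are annual parameters, so the acute phase is a one-cycle tunnel:
every event entrant occupies the acute copy of the entered state for the
entry year, accruing the non-fatal acute cost, the acute disutility and
the first-year productivity loss; the case fatality is the acute state's
own mortality applied on exit, and the fatal acute event cost (e.g.
\$18,246 for fatal CAD) attaches to those deaths. We considered the
alternative of killing the case-fatality fraction within the entry cycle
before any acute accrual; it implies committed costs per event about a
third lower and produces base-case increments well outside the published
results, whereas the tunnel reading reproduces them, so the tunnel is the
model's convention.

Mortality is life-table background risk for event-free, myopathy and
diabetes states (hazard-scaled by 1.680 with diabetes), and
disease-specific annual risks alone for CAD/stroke states (chronic CAD
0.070, post-stroke 0.069, CAD+stroke 0.075, hazard-scaled by 1.810 or
1.670 with diabetes). Competing risks within a row use independent
probabilities and are renormalised proportionally only if they sum past
1, which never occurs at baseline values; every kernel row must be
stochastic to $10^{-9}$ or the engine aborts.

## Rewards, discounting and accounting conventions

Event-free years have utility 1 and death 0; condition states multiply
condition weights (CAD 0.790, stroke 0.630, diabetes 0.800, myopathy
0.917), subtract the acute disutility in the entry cycle, and every
living state loses 0.004 per elapsed model year to aging, floored at 0.
Costs decompose into a ledger the cohort trace reports per cycle:
background healthcare (\$4,941 for everyone alive), medical (acute event
costs; follow-up costs CAD \$11,815, stroke \$20,005, diabetes \$10,026,
myopathy \$20,438; statin therapy), lost productivity (\$73,492 in the
year a CAD or stroke is diagnosed — absenteeism \$14,698 plus
presenteeism at four times absenteeism — then \$9,056 per year, also for
myopathy, and \$9,242 annually with diabetes), and program costs (\$58
annual PCE screen; one-time \$145 PRS test; one-time \$114 consultation
for the high-PRS fifth; \$6/year app from year 2).

Follow-up years for CAD and ischemic stroke also price *recurrent*
events as recurrence risk × acute treatment cost, a cost adjustment
rather than a modelled state. The recurrence risks are not published
inputs; we assume 0.20/yr for CAD and 0.10/yr for ischemic stroke,
annual post-event recurrence/rehospitalisation rates of the order seen in
post-ACS and post-stroke registries, flag them `assumption` in the
parameter file, and carry ±50% ranges through the sensitivity analyses.

Rewards accrue on end-of-cycle occupancy: cycle $t$ (0-based) carries the
cohort from $x_t$ to $x_{t+1}$, values the state rewards at $x_{t+1}$
(so the year's events are reflected in the year they happen), applies the
age disutility at $t+1$ elapsed years, and discounts by $1.03^{-t}$.
Screening costs attach to the start-of-cycle living cohort (screening
happens at the start of the program year). No half-cycle correction is
applied. Start-of-cycle accrual is available
(`reward_timing = "cycle_start"`) but leaves final-year events without
any accrued impact and overstates total QALYs relative to the published
results, so end-of-cycle is the default.

## The parameter table and its calibration flags

`default_parameters()` ships all 57 annual inputs with baseline, range,
distribution family and shape parameters; `write_default_parameters()`
emits the golden CSV and `load_parameters()` round-trips CSV and YAML.
Several printed shape pairs do not reproduce their printed baselines
under either a (shape, rate) or (shape, scale) convention — the
side-effect betas imply roughly five times the printed annual risks, the
post-acute CAD mortality beta implies 0.195 instead of 0.070, and seven
gamma cost rows are off by 3–31% under the rate convention. The fixture
keeps the printed first shape parameter, recalibrates the second so the
distribution mean equals the printed baseline, and flags every such row
in a `calibration` column (`printed`, `recalibrated_b`, `derived_pm25` —
the last for rows without printed distributions, calibrated so ±25% is a
95% interval). Lognormal rows are shipped exactly as printed even where
the implied mean misses the baseline (the relative-effect rows around HR
2.000/2.270/1.670 appear to have interchanged location parameters in the
source table); their draws are therefore mildly biased relative to the
baselines, which the acceptability results tolerate comfortably.

## Sensitivity analyses

`one_way()` reruns the full model at each parameter's range endpoints,
holding the rest at baseline. A perturbed initial-distribution share is
held at its endpoint while the other two shares are rescaled to fill the
simplex, preserving their relative proportions. Parameters without a
printed range are skipped with a warning. `psa()` draws every non-fixed
parameter independently from its stated family — beta for probabilities
and (dis)utilities, gamma for costs, lognormal for relative effects —
with one reproducible substream per parameter, so adding or removing a
parameter never perturbs the draws of the others; no cross-parameter
correlation is modelled, mirroring the source analysis's stated
limitation. The engine renormalises the three initial shares within each
draw. The acceptability curve reports the fraction of draws with
positive INMB on a WTP grid through \$100,000.

One one-way finding deserves emphasis: against StandardWHP the
incremental NMB turns slightly negative at the lower endpoint of the
moderate-PCE CAD risk (0.005) and is numerically zero at the statin HR's
upper endpoint (0.780). This is structural, not numerical: the only
clinical difference between the two programs is treating the
moderate-PCE/high-PRS stratum (1.9% of the cohort at baseline enrollment
and adherence), and when that stratum's risk is low the achievable value
cannot cover the PRS test's fixed cost differential. The test suite
asserts the published all-positive claim as stated and documents this
divergence rather than hiding it.

## Scenario: annual risk-category migration

`make_migration()` builds a row-stochastic 3×3 matrix over {low,
moderate, high} PCE from six off-diagonal percentages in the order
(low→mod, low→high, mod→low, mod→high, high→low, high→mod); diagonals
are complements. The natural drift is (25, 5, 35, 20, 6, 31)% per year
and the in-program drift (12.05, 0.62, 46.35, 7.66, 15.65, 48.70)%.
`blend_migration()` forms the enrollment-weighted convex combination; the
weight that reproduces the published blended vector (18.780, 2.900,
40.450, 14.080, 10.630, 39.500)% to three decimals is 0.52 **on the
natural matrix**, although the accompanying text assigns 48% to natural —
an arithmetic inconsistency in the source we record rather than resolve;
the weight is an explicit argument either way.

In `run_scenario()` migration acts on the event-free block only,
composed before each cycle's event transitions, starting after the first
year. Migrants keep their PRS tag, eligibility is re-evaluated each year
from the current category (PCE rescreening is annual; its cost
continues; the PRS test is not repeated). The blended matrix applies to
the *enrolled* fraction of the workplace strategies and the natural
matrix to the non-enrolled remainder and to NoWHP — the assignment under
which the model reproduces the published scenario increments; applying
the blend to the whole WHP cohort overstates the saving by roughly
two-thirds. An identity migration matrix reproduces the base case
bit-for-bit.

## The synthetic life table

Background mortality uses a Gompertz stand-in,
$q(a) = 0.004\,e^{0.09 (a-50)}$, emulating the age-50 level and slope of
US period life tables (the original model used Social Security tables
shipped in a supplement we do not package). Over a 5-year horizon from
age 50 the results are insensitive to the exact table; the validation
check `validate_life_expectancy()` therefore asserts a band — the
disease-free cohort run to extinction must yield a remaining life
expectancy of 28–35 years at 50 (the default table gives about 29.7) —
rather than a point. Any user table loads from CSV via
`load_life_table()`. The stand-in does not emulate cohort effects,
mortality improvement, or sex/ancestry structure; conclusions about those
are outside what passing tests can show.

## Numerical choices and problem sizes

Occupancy vectors must sum to 1 within $10^{-9}$ every cycle and death is
absorbing; both are asserted continuously. The individual-level Monte
Carlo cross-check walks 100,000 simulated persons through the same
kernels and must match the cohort trace within three binomial standard
errors everywhere. The test suite runs the probabilistic analysis at
3,000 draws with a 1,000-draw agreement check; the analysis scripts and
the acceptance script run the full 10,000 draws, which completes in a few
minutes on one CPU. Monotonicity checks (stronger statin effect never
lowers QALYs; zero adherence collapses all three strategies' clinical
dynamics) guard the treatment wiring.

## Known limitations

Parameters are sampled independently; no correlation structure. The
cohort is closed, risks are constant within a year, and no treatment
switching, effect waning, or lifetime extrapolation is modelled. Pair
states cap comorbidity at two conditions and carry no statin cost.
Racial/ancestry composition and per-person heterogeneity within strata
are not represented. Absolute cost levels are sensitive to the
recurrence-cost assumption and the acute accounting convention;
incremental results, which drive every reported conclusion, are
substantially more stable.
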