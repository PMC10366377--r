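# Background (all-cause) mortality for event-free employees.
#
# The model consumes any period life table supplied as (age, qx) rows. The
# packaged default is a synthetic Gompertz table whose age-50 level and
# exponential age slope are of the order of published US period tables; over
# a 5-year horizon starting at age 50 results are insensitive to the exact
# table, and the life-expectancy validation below uses a band, not a point.

#' Synthetic Gompertz life table
#'
#' Annual all-cause death probability
#' `q(age) = base_q * exp(growth * (age - start_age))`, capped below 1.
#' Defaults (`base_q = 0.004`, `growth = 0.09`) emulate US period-table
#' mortality around age 50.
#'
#' @param start_age first age covered.
#' @param span number of ages covered beyond `start_age`.
#' @param base_q annual death probability at `start_age`, in `(0, 0.1)`.
#' @param growth exponential growth rate per year of age, `>= 0`.
#' @return a `life_table`: data frame with columns `age` and `qx`.
#' @export
synth_life_table <- function(start_age = 50, span = 70, base_q = 0.004,
                             growth = 0.09) {
  if (base_q <= 0 || base_q >= 0.1) stop("base_q must lie in (0, 0.1)")
  if (growth < 0) stop("growth must be >= 0")
  if (span < 1) stop("span must be at least 1")
  age <- start_age + 0:span
  qx <- pmin(base_q * exp(growth * (age - start_age)), 1)
  structure(data.frame(age = age, qx = qx), class = c("life_table",
                                                      "data.frame"))
}

#' Load a life table from CSV
#'
#' @param path CSV with columns `age` and `qx` (annual death probability).
#' @return a `life_table`.
#' @export
load_life_table <- function(path) {
  lt <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(lt))) {
    stop("life table needs columns 'age' and 'qx'")
  }
  if (any(lt$qx <= 0 | lt$qx > 1)) stop("qx values must lie in (0, 1]")
  lt <- lt[order(lt$age), c("age", "qx")]
  structure(lt, class = c("life_table", "data.frame"))
}

# annual death probability at a given age; beyond the table the last row
# applies (relevant only for runs far past the covered span)
life_table_q <- function(lt, age) {
  i <- findInterval(age, lt$age)
  i[i < 1L] <- 1L
  i[i > nrow(lt)] <- nrow(lt)
  lt$qx[i]
}

#' Life expectancy of the disease-free cohort
#'
#' Runs the event-free cohort to extinction on the life table alone (all
#' event risks zero) and returns the undiscounted expectation of whole
#' years lived from `start_age` — the reduction of the cohort model when
#' only background mortality acts, used to validate the mortality input
#' against general-population longevity. With the model's end-of-cycle
#' reward accrual this is the curtate expectation
#' `sum_t prod_{k<t} (1 - q(start_age + k))`.
#'
#' @param lt a `life_table`.
#' @param start_age starting age (default 50, the cohort's mean age).
#' @return life expectancy in years (truncated at the table's last age).
#' @export
validate_life_expectancy <- function(lt, start_age = 50) {
  ages <- lt$age[lt$age >= start_age]
  if (length(ages) == 0) stop("life table does not cover start_age")
  q <- life_table_q(lt, ages)
  surv <- cumprod(1 - q)
  sum(surv)
}
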