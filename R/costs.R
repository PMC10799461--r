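#' Unit costs and the discount rate
#'
#' Per-cycle drug and administration costs (2022 KRW), per-event fracture
#' treatment costs, and the annual discount rate applied to both costs and
#' health consequences. Defaults are the published Korean inputs: HIRA
#' weighted-average drug prices (2021), HIRA fee-for-service administration
#' prices (2022), and fracture treatment costs from the national
#' osteoporosis fact-sheet research.
#'
#' @param drug_cost_per_cycle named KRW per 6-month cycle by drug.
#' @param admin_cost_per_cycle named KRW per cycle by drug.
#' @param fracture_event_cost named KRW per incident event (`vf`, `nvf`).
#' @param discount_rate_annual annual discount rate (default 0.045, the
#'   Korean pharmacoeconomic-guideline rate).
#' @return object of class `cost_book`.
#' @export
cost_book <- function(drug_cost_per_cycle = c(denosumab = 177650,
                                              bp_oral = 125112,
                                              bp_iv = 107296,
                                              serm = 120050),
                      admin_cost_per_cycle = c(denosumab = 4843,
                                               bp_oral = 20226,
                                               bp_iv = 2422,
                                               serm = 45705),
                      fracture_event_cost = c(vf = 2717095, nvf = 2684098),
                      discount_rate_annual = 0.045) {
  if (any(c(drug_cost_per_cycle, admin_cost_per_cycle, fracture_event_cost) < 0))
    stop("costs must be nonnegative")
  if (discount_rate_annual < 0) stop("discount rate must be nonnegative")
  stopifnot(all(c("vf", "nvf") %in% names(fracture_event_cost)))
  structure(list(drug_cost_per_cycle = drug_cost_per_cycle,
                 admin_cost_per_cycle = admin_cost_per_cycle,
                 fracture_event_cost = fracture_event_cost,
                 discount_rate_annual = discount_rate_annual),
            class = "cost_book")
}

#' Discount factor at the end of a model cycle
#'
#' `(1 + rate)^(-cycle_index * cycle_length_years)`. The same factor is
#' applied to costs and to event counts (consequences are discounted too).
#'
#' @param cycle_index 1-based cycle number (vectorised).
#' @param rate_annual annual discount rate.
#' @param cycle_length_years cycle length in years.
#' @return discount factor(s).
#' @export
discount_factor <- function(cycle_index, rate_annual = 0.045,
                            cycle_length_years = 0.5) {
  stopifnot(rate_annual >= 0)
  (1 + rate_annual)^(-cycle_index * cycle_length_years)
}

#' Per-cycle cost of a drug (drug + administration)
#'
#' @param book a `cost_book`.
#' @param drug drug label.
#' @return KRW per cycle.
#' @export
drug_cycle_cost <- function(book, drug) {
  if (!drug %in% names(book$drug_cost_per_cycle) ||
      !drug %in% names(book$admin_cost_per_cycle))
    stop("unknown drug label: ", drug)
  unname(book$drug_cost_per_cycle[drug] + book$admin_cost_per_cycle[drug])
}

#' Market-share-weighted per-cycle cost of subsequent therapy
#'
#' @param book a `cost_book`.
#' @param mix named drug shares summing to 1.
#' @return KRW per cycle.
#' @export
subsequent_cycle_cost <- function(book, mix = default_subsequent_mix()) {
  if (abs(sum(mix) - 1) > 1e-9) stop("mix shares must sum to 1")
  sum(vapply(names(mix), function(d) mix[[d]] * drug_cycle_cost(book, d),
             numeric(1)))
}

#' Age-specific income and employment profile
#'
#' Inputs for the human-capital valuation of productivity lost to
#' fracture-related death: average annual income and employment rate by age,
#' with employment forced to zero at and beyond the retirement age.
#'
#' @param income_by_age named (by integer age) KRW per year.
#' @param employment_rate_by_age named (by the same ages) rates in \[0,1\].
#' @param retirement_age years; no productivity is lost at or after it.
#' @return object of class `productivity_profile`.
#' @export
productivity_profile <- function(income_by_age, employment_rate_by_age,
                                 retirement_age = 65) {
  ages_i <- as.integer(names(income_by_age))
  ages_e <- as.integer(names(employment_rate_by_age))
  if (!identical(ages_i, ages_e))
    stop("income and employment profiles must cover identical ages")
  if (any(income_by_age < 0)) stop("incomes must be nonnegative")
  if (any(employment_rate_by_age < 0 | employment_rate_by_age > 1))
    stop("employment rates must lie in [0, 1]")
  emp <- employment_rate_by_age
  emp[ages_e >= retirement_age] <- 0
  structure(list(income_by_age = income_by_age,
                 employment_rate_by_age = emp,
                 retirement_age = retirement_age,
                 ages = ages_i),
            class = "productivity_profile")
}

#' Productivity loss from fracture-related deaths (human capital approach)
#'
#' Each fracture-related death at age `a` before the retirement age forfeits,
#' for every whole year of age from `floor(a)` up to (but excluding) the
#' retirement age, that year's average income times the employment rate.
#' Each forfeited year is discounted at the model rate to the model start,
#' anchored at the end of the cycle in which the death occurs.
#'
#' @param deaths data.frame with columns `age` (age at death, years),
#'   `mass` (fracture-related death mass per patient) and `time_years`
#'   (model time at end of the death cycle).
#' @param profile a `productivity_profile`.
#' @param rate_annual annual discount rate (0 for the undiscounted value).
#' @return KRW per patient.
#' @export
productivity_loss <- function(deaths, profile, rate_annual = 0.045) {
  stopifnot(inherits(profile, "productivity_profile"))
  total <- 0
  for (i in seq_len(nrow(deaths))) {
    a <- floor(deaths$age[i])
    if (a >= profile$retirement_age || deaths$mass[i] <= 0) next
    yrs <- seq(a, profile$retirement_age - 1L)
    idx <- match(yrs, profile$ages)
    if (anyNA(idx))
      stop("productivity profile has a gap: age ",
           paste(yrs[is.na(idx)], collapse = ", "), " missing")
    offsets <- yrs - a
    val <- sum(profile$income_by_age[idx] *
                 profile$employment_rate_by_age[idx] *
                 (1 + rate_annual)^(-(deaths$time_years[i] + offsets)))
    total <- total + deaths$mass[i] * val
  }
  total
}

#' Fraction of the per-patient fracture cost burden offset by a saving
#'
#' Expresses a per-patient saving as a percentage of a per-patient cost
#' burden (e.g. the additional lifetime healthcare cost of a patient with
#' at least one fracture relative to the fracture-free population).
#'
#' @param saving_per_patient KRW.
#' @param burden_per_patient KRW.
#' @return percentage (0-100 scale).
#' @export
saving_burden_ratio <- function(saving_per_patient, burden_per_patient) {
  100 * saving_per_patient / burden_per_patient
}

#' National budget impact of a per-patient saving
#'
#' @param saving_per_patient KRW saved per patient.
#' @param n_patients number of eligible patients nationally.
#' @return total KRW.
#' @export
national_budget_impact <- function(saving_per_patient, n_patients) {
  saving_per_patient * n_patients
}
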