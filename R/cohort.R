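#' Cohort occupancy state
#'
#' Distribution of the cohort over the main health states `S` (starting
#' state), `D` (T-score decrease), `I_mid` / `I_high` (T-score increase
#' bands) and `dead`, together with the current age and cycle index.
#' Occupancy masses must sum to 1.
#'
#' @param occupancy named numeric vector over
#'   `c("S","D","I_mid","I_high","dead")` summing to 1.
#' @param age age in years at the start of the current cycle.
#' @param cycle_index 0-based count of completed cycles.
#' @return object of class `cohort_state`.
#' @export
cohort_state <- function(occupancy = c(S = 1, D = 0, I_mid = 0, I_high = 0, dead = 0),
                         age = 55, cycle_index = 0L) {
  states <- c("S", "D", "I_mid", "I_high", "dead")
  if (!identical(names(occupancy), states))
    stop("occupancy must be named ", paste(states, collapse = ","))
  if (abs(sum(occupancy) - 1) > 1e-9 || any(occupancy < 0))
    stop("occupancy masses must be nonnegative and sum to 1")
  structure(list(occupancy = occupancy, age = age,
                 cycle_index = as.integer(cycle_index)),
            class = "cohort_state")
}

#' Advance the cohort by one model cycle
#'
#' Event order within a cycle:
#' 1. background death at the life-table per-cycle probability (floor of the
#'    current age; constant-hazard annual-to-cycle conversion);
#' 2. among survivors, an incident vertebral or non-vertebral fracture as
#'    mutually exclusive sub-states (at most one incident fracture per
#'    cycle; the residual sub-state is "well");
#' 3. fracture-related excess death among incident-fracture patients,
#'    `incidence * (min(1, q*SMR) - q)`;
#' 4. main-state transitions among the remaining survivors, per the
#'    schedule row for this cycle. Incident fractures are attributed to the
#'    state occupied at cycle start.
#'
#' Total mass is conserved to 1e-12; violation raises an error naming the
#' cycle.
#'
#' @param state a [cohort_state()].
#' @param schedule a `transition_schedule` from [build_transition_schedule()];
#'   the row for `state$cycle_index + 1` is used.
#' @param fm a [fracture_model()].
#' @param lt a [life_table()].
#' @param arm fracture-probability arm, `"treated"` or `"discontinued"`.
#' @param sex `"female"` or `"male"` (single-sex cohort; mixed cohorts are
#'   run per sex and weighted by [run_cohort()]).
#' @param cycle_length_years cycle length (default 0.5).
#' @return list with elements `state` (the advanced `cohort_state`) and
#'   `ledger` (named numeric: incident events, deaths, end occupancy).
#' @export
step_cycle <- function(state, schedule, fm, lt, arm = "treated",
                       sex = "female", cycle_length_years = 0.5) {
  stopifnot(inherits(state, "cohort_state"), inherits(fm, "fracture_model"))
  cyc <- state$cycle_index + 1L
  if (cyc > nrow(schedule)) stop("cycle ", cyc, " beyond compiled schedule")
  row <- schedule[cyc, ]
  q <- annual_to_cycle(lookup_q(lt, state$age, sex), cycle_length_years)

  occ <- state$occupancy
  live <- occ[c("S", "D", "I_mid", "I_high")]
  p_vf <- fm$p_vf[, arm]
  p_nvf <- fm$p_nvf[, arm]

  deaths_bg <- sum(live) * q
  surv <- live * (1 - q)
  inc_vf_s <- surv * p_vf
  inc_nvf_s <- surv * p_nvf
  ex_vf <- pmin(1, q * fm$smr_vf[[sex]]) - q
  ex_nvf <- pmin(1, q * fm$smr_nvf[[sex]]) - q
  deaths_fr <- sum(inc_vf_s) * ex_vf + sum(inc_nvf_s) * ex_nvf
  rem <- surv - inc_vf_s * ex_vf - inc_nvf_s * ex_nvf

  if (any(rem < -1e-12))
    stop("negative occupancy produced in cycle ", cyc)

  out_S <- rem[["S"]] * (row$p_S_to_D + row$p_S_to_I)
  out_D <- rem[["D"]] * row$p_D_to_I
  new <- c(
    S = rem[["S"]] - out_S,
    D = rem[["D"]] - out_D + rem[["S"]] * row$p_S_to_D,
    I_mid = rem[["I_mid"]] + rem[["D"]] * row$p_D_to_I,
    I_high = rem[["I_high"]] + rem[["S"]] * row$p_S_to_I,
    dead = occ[["dead"]] + deaths_bg + deaths_fr
  )
  if (abs(sum(new) - 1) > 1e-12)
    stop("mass not conserved in cycle ", cyc,
         " (drift ", format(sum(new) - 1), ")")

  # two reporting conventions for the fracture-death sub-state: the excess
  # component only, or all deaths attributed to incident-fracture patients
  # (excess + their background share inc*q); dynamics use the excess, so
  # all-cause mortality always matches the life table
  deaths_fr_all <- sum(inc_vf_s) * pmin(1, q * fm$smr_vf[[sex]]) +
    sum(inc_nvf_s) * pmin(1, q * fm$smr_nvf[[sex]])
  ledger <- c(inc_vf = sum(inc_vf_s), inc_nvf = sum(inc_nvf_s),
              deaths_background = deaths_bg,
              deaths_fracture_excess = deaths_fr,
              deaths_fracture_all = deaths_fr_all,
              q_cycle = unname(q))
  list(state = cohort_state(new, age = state$age + cycle_length_years,
                            cycle_index = cyc),
       ledger = ledger)
}

#' Accrue one cycle's cost components
#'
#' Continuous drug + administration cost accrues to the mass occupying S at
#' the cycle end during the on-treatment window; subsequent-therapy cost
#' accrues to the mass occupying D at the cycle end, at the
#' market-share-weighted per-cycle cost; fracture treatment cost accrues
#' once per incident event. Patients in the T-score-increase states incur
#' no drug cost.
#'
#' @param end_occupancy named occupancy vector at cycle end.
#' @param inc_vf,inc_nvf incident fracture masses this cycle (per patient).
#' @param on_treatment logical: is this cycle inside the treatment window?
#' @param spec the `strategy_spec`.
#' @param book a `cost_book`.
#' @return named numeric: `cost_continuous`, `cost_subsequent`,
#'   `cost_fracture` (KRW per patient, undiscounted).
#' @export
accrue_cycle_costs <- function(end_occupancy, inc_vf, inc_nvf,
                               on_treatment, spec, book) {
  cont <- if (isTRUE(on_treatment) && !is.na(spec$on_treatment_drug))
    end_occupancy[["S"]] * drug_cycle_cost(book, spec$on_treatment_drug)
  else 0
  subs <- end_occupancy[["D"]] * subsequent_cycle_cost(book, spec$subsequent_mix)
  frac <- inc_vf * book$fracture_event_cost[["vf"]] +
    inc_nvf * book$fracture_event_cost[["nvf"]]
  c(cost_continuous = unname(cont), cost_subsequent = unname(subs),
    cost_fracture = unname(frac))
}

#' Number of cycles spanned by a horizon
#'
#' @param horizon `"lifetime"` or a horizon in years.
#' @param start_age cohort starting age.
#' @param max_age life-table terminal age.
#' @param cycle_length_years cycle length.
#' @return integer cycle count.
#' @export
horizon_cycles <- function(horizon, start_age, max_age = 110,
                           cycle_length_years = 0.5) {
  if (identical(horizon, "lifetime"))
    as.integer(ceiling((max_age + 1 - start_age) / cycle_length_years))
  else {
    stopifnot(is.numeric(horizon), horizon >= 0)
    as.integer(round(horizon / cycle_length_years))
  }
}

#' Run the cohort model for one strategy
#'
#' Iterates [step_cycle()] from the starting age until the horizon (or until
#' the terminal age under a lifetime horizon), accruing costs each cycle and
#' recording a per-cycle trace. All patients start in state S. Mixed-sex
#' cohorts are run per sex and combined with the `sex_mix` weights (sex is
#' fixed per patient, so this is exact).
#'
#' @param spec a [strategy_spec()].
#' @param fm a [fracture_model()].
#' @param lt a [life_table()].
#' @param book a [cost_book()].
#' @param start_age starting age in years (may be fractional; life-table
#'   lookups floor the mid-cycle age).
#' @param cycle_length_years cycle length (default 0.5).
#' @param horizon `"lifetime"` or years.
#' @param sex_mix named shares over `female`/`male` summing to 1
#'   (default 100% female, a postmenopausal-osteoporosis cohort).
#' @return object of class `cca_trace`: a data.frame with one row per cycle
#'   (occupancy, incident events, deaths, cost components, discount factor),
#'   with attributes `spec`, `final_state`s and run settings. Events are per
#'   patient; multiply by 100 for per-100-patient reporting.
#' @export
run_cohort <- function(spec, fm, lt, book = cost_book(),
                       start_age = 55, cycle_length_years = 0.5,
                       horizon = "lifetime", sex_mix = c(female = 1)) {
  stopifnot(inherits(spec, "strategy_spec"), inherits(lt, "life_table"))
  if (abs(sum(sex_mix) - 1) > 1e-9) stop("sex_mix shares must sum to 1")
  max_age <- attr(lt, "max_age")
  n_cycles <- horizon_cycles(horizon, start_age, max_age, cycle_length_years)
  empty <- trace_frame(0, spec, book, start_age, cycle_length_years,
                       horizon, sex_mix)
  if (n_cycles == 0) return(empty)
  schedule <- build_transition_schedule(spec, n_cycles)

  combined <- NULL
  finals <- list()
  for (sx in names(sex_mix)) {
    w <- sex_mix[[sx]]
    if (w == 0) next
    st <- cohort_state(age = start_age)
    rows <- vector("list", n_cycles)
    for (t in seq_len(n_cycles)) {
      stp <- step_cycle(st, schedule, fm, lt, arm = spec$fracture_arm,
                        sex = sx, cycle_length_years = cycle_length_years)
      st <- stp$state
      costs <- accrue_cycle_costs(st$occupancy, stp$ledger[["inc_vf"]],
                                  stp$ledger[["inc_nvf"]],
                                  schedule$on_treatment[t], spec, book)
      rows[[t]] <- c(occ_S = st$occupancy[["S"]], occ_D = st$occupancy[["D"]],
                     occ_I_mid = st$occupancy[["I_mid"]],
                     occ_I_high = st$occupancy[["I_high"]],
                     occ_dead = st$occupancy[["dead"]],
                     stp$ledger, costs)
    }
    m <- do.call(rbind, rows) * w  # q_cycle column becomes the mix-weighted rate
    combined <- if (is.null(combined)) m else combined + m
    finals[[sx]] <- st
  }

  tr <- as.data.frame(combined)
  tr <- cbind(cycle = seq_len(n_cycles),
              age_start = start_age + (seq_len(n_cycles) - 1) * cycle_length_years,
              time_years = seq_len(n_cycles) * cycle_length_years,
              tr)
  tr$df <- discount_factor(tr$cycle, book$discount_rate_annual,
                           cycle_length_years)
  for (col in c("inc_vf", "inc_nvf", "deaths_fracture_excess",
                "deaths_fracture_all",
                "cost_continuous", "cost_subsequent", "cost_fracture"))
    tr[[paste0(col, "_disc")]] <- tr[[col]] * tr$df

  structure(tr, class = c("cca_trace", "data.frame"),
            spec = spec, book = book, final_states = finals,
            start_age = start_age, cycle_length_years = cycle_length_years,
            horizon = horizon, sex_mix = sex_mix)
}

# zero-cycle trace with the right columns and attributes
trace_frame <- function(n, spec, book, start_age, cycle_length_years,
                        horizon, sex_mix) {
  cols <- c("cycle", "age_start", "time_years", "occ_S", "occ_D", "occ_I_mid",
            "occ_I_high", "occ_dead", "inc_vf", "inc_nvf",
            "deaths_background", "deaths_fracture_excess",
            "deaths_fracture_all", "q_cycle",
            "cost_continuous", "cost_subsequent", "cost_fracture", "df",
            "inc_vf_disc", "inc_nvf_disc", "deaths_fracture_excess_disc",
            "deaths_fracture_all_disc", "cost_continuous_disc",
            "cost_subsequent_disc", "cost_fracture_disc")
  tr <- as.data.frame(matrix(numeric(0), nrow = n, ncol = length(cols),
                             dimnames = list(NULL, cols)))
  structure(tr, class = c("cca_trace", "data.frame"),
            spec = spec, book = book, final_states = list(),
            start_age = start_age, cycle_length_years = cycle_length_years,
            horizon = horizon, sex_mix = sex_mix)
}
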