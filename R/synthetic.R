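#' Generate a synthetic national-style life table
#'
#' Builds annual death probabilities for both sexes from a Gompertz-Makeham
#' hazard (see [gompertz_makeham_q()]), optionally with seeded multiplicative
#' log-normal noise, and returns a validated [life_table()]. The default
#' parameters are calibrated to the shape of published Korean female
#' mortality (q around 0.0014 at age 55, roughly 0.04-0.05 by age 85), with
#' male mortality scaled up; they are a synthetic stand-in, not a copy of
#' any published table vintage.
#'
#' Deterministic given (seed, parameters): the same call writes identical
#' file bytes.
#'
#' @param seed integer seed (only consequential when `noise_sd > 0`).
#' @param makeham age-independent annual hazard.
#' @param gompertz_scale,gompertz_shape Gompertz hazard parameters.
#' @param male_scale_mult multiplier on `gompertz_scale` for men.
#' @param min_age,max_age covered age range; `max_age` is absorbing.
#' @param noise_sd sd of log-normal noise on q (default 0: smooth table).
#' @param path optional CSV path; when given the table is also written via
#'   [write_life_table()].
#' @return a `life_table`.
#' @export
make_life_table <- function(seed = 1L, makeham = 1e-4,
                            gompertz_scale = 1.8e-6, gompertz_shape = 0.12,
                            male_scale_mult = 2.0,
                            min_age = 40L, max_age = 110L,
                            noise_sd = 0, path = NULL) {
  ages <- seq(min_age, max_age - 1L)
  qf <- gompertz_makeham_q(ages, makeham, gompertz_scale, gompertz_shape)
  qm <- gompertz_makeham_q(ages, makeham, gompertz_scale * male_scale_mult,
                           gompertz_shape)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    qf <- pmin(qf * exp(stats::rnorm(length(qf), 0, noise_sd)), 1 - 1e-9)
    qm <- pmin(qm * exp(stats::rnorm(length(qm), 0, noise_sd)), 1 - 1e-9)
  }
  lt <- life_table(data.frame(
    age = rep(c(ages, max_age), 2),
    sex = rep(c("female", "male"), each = length(ages) + 1L),
    q_annual = c(qf, 1, qm, 1)), max_age = max_age)
  if (!is.null(path)) write_life_table(lt, path)
  lt
}

#' Generate a synthetic age-income / employment profile
#'
#' Produces an average-wage and employment-rate profile by single year of
#' age for the human-capital productivity-loss calculation: income follows
#' a broad hump peaking in the late 40s, employment declines towards the
#' retirement age and is zero at and beyond it. Deterministic given the
#' seed. A synthetic stand-in for national wage/employment statistics.
#'
#' @param seed integer seed (only consequential when `noise_sd > 0`).
#' @param mean_income average annual income (KRW) across working ages.
#' @param retirement_age no earnings at or after this age.
#' @param min_age first covered age.
#' @param noise_sd sd of log-normal noise on income.
#' @return a [productivity_profile()].
#' @export
make_productivity_profile <- function(seed = 1L, mean_income = 40e6,
                                      retirement_age = 65, min_age = 20L,
                                      noise_sd = 0) {
  ages <- seq(min_age, retirement_age)
  peak <- 48
  shape <- exp(-((ages - peak) / 18)^2)      # hump-shaped age-wage curve
  income <- mean_income * shape / mean(shape)
  emp <- 0.75 - 0.006 * pmax(0, ages - 50)   # slow decline after 50
  emp <- pmin(pmax(emp, 0), 1)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    income <- income * exp(stats::rnorm(length(income), 0, noise_sd))
  }
  names(income) <- names(emp) <- ages
  productivity_profile(income, emp, retirement_age = retirement_age)
}

#' Sample a random, valid model parameterisation
#'
#' Draws a complete model configuration — strategy transition inputs,
#' fracture probabilities and SMRs, unit costs, discount rate — from
#' plausible ranges, constructed so that every draw passes all type
#' invariants (probabilities in range, VF + non-VF at most 1, discontinued
#' fracture risk at least the treated risk, shares summing to 1). The
#' packaged base-case inputs are one fixed, non-random member of this
#' family. Used by the property-based validation harness.
#'
#' @param seed integer seed; the same seed reproduces the draw exactly.
#' @return list with elements `strategies` (list of two [strategy_spec()]s:
#'   a treated and a discontinued arm), `fracture`, `costs`, `start_age`
#'   and `sex_mix`, ready to splice into [cca()].
#' @export
sample_params <- function(seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ru <- function(lo, hi) stats::runif(1, lo, hi)

  p_vf_t <- stats::runif(4, 0, 0.05)
  p_nvf_t <- stats::runif(4, 0, 0.05)
  rr_vf <- ru(1, 4)
  rr_nvf <- ru(1, 4)
  p_vf <- cbind(treated = p_vf_t, discontinued = pmin(p_vf_t * rr_vf, 0.4))
  p_nvf <- cbind(treated = p_nvf_t, discontinued = pmin(p_nvf_t * rr_nvf, 0.4))
  rownames(p_vf) <- rownames(p_nvf) <- c("S", "D", "I_mid", "I_high")

  fm <- fracture_model(
    p_vf = p_vf, p_nvf = p_nvf,
    smr_vf = c(female = ru(1, 6), male = ru(1, 6)),
    smr_nvf = c(female = ru(1, 6), male = ru(1, 6)))

  book <- cost_book(
    drug_cost_per_cycle = c(denosumab = ru(5e4, 5e5), bp_oral = ru(5e4, 5e5),
                            bp_iv = ru(5e4, 5e5), serm = ru(5e4, 5e5)),
    admin_cost_per_cycle = c(denosumab = ru(0, 5e4), bp_oral = ru(0, 5e4),
                             bp_iv = ru(0, 5e4), serm = ru(0, 5e4)),
    fracture_event_cost = c(vf = ru(5e5, 5e6), nvf = ru(5e5, 5e6)),
    discount_rate_annual = ru(0, 0.06))

  dur <- sample(0:10, 1)
  offset <- sample(c(1, 2, 3), 1)
  mix_raw <- stats::runif(4)
  mix <- mix_raw / sum(mix_raw)
  names(mix) <- c("denosumab", "bp_oral", "bp_iv", "serm")
  treated <- strategy_spec("sampled_treated",
                           treatment_duration_cycles = max(dur, 1L),
                           offset_years = offset,
                           cumulative_rebound = ru(0.9, 0.9999),
                           tp_S_to_I = ru(0, 0.3),
                           tp_D_to_I = ru(0, 0.2),
                           on_treatment_drug = "denosumab",
                           subsequent_mix = mix,
                           fracture_arm = "treated")
  discont <- strategy_spec("sampled_discontinued",
                           treatment_duration_cycles = 0L,
                           offset_years = offset,
                           cumulative_rebound = treated$cumulative_rebound,
                           tp_S_to_I = 0,
                           tp_D_to_I = treated$tp_D_to_I,
                           on_treatment_drug = NA_character_,
                           subsequent_mix = mix,
                           fracture_arm = "discontinued")
  list(strategies = list(treated = treated, discontinued = discont),
       fracture = fm, costs = book,
       start_age = ru(50, 80), sex_mix = c(female = 1))
}
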