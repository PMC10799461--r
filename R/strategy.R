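#' Define a treatment strategy
#'
#' A strategy fixes the per-cycle T-score transition behaviour of the cohort:
#' how long active treatment suppresses the rebound from the starting state
#' (S) to the T-score-decrease state (D), the offset window over which the
#' protective effect wanes after stopping, the probability of T-score
#' improvement while on treatment (S to I), the weighted probability of
#' improvement under subsequent therapy (D to I), and which drug cost applies
#' while on treatment.
#'
#' The two packaged base-case strategies are [dmab_c()] (continue denosumab
#' until the T-score exceeds -2.0) and [dmab_d()] (discontinue all
#' osteoporosis drugs once the T-score exceeds -2.5).
#'
#' @param name strategy label.
#' @param treatment_duration_cycles number of on-treatment cycles (nonnegative
#'   integer), or `"lifetime"` for treatment that never stops.
#' @param offset_years length of the offset window (years) over which the
#'   treatment effect wanes after stopping; must be positive when the
#'   treatment duration is finite.
#' @param cumulative_rebound calibration constant: total probability of
#'   rebounding from S to D across the whole offset window (default 0.999;
#'   see [rebound_cycle_prob()]).
#' @param tp_S_to_I per-cycle probability of moving from S to the
#'   high T-score-increase state while on treatment.
#' @param tp_D_to_I per-cycle probability of moving from D to the mid
#'   T-score-increase state under subsequent therapy.
#' @param rr_D_to_I optional risk-ratio multiplier on `tp_D_to_I`
#'   (default 1).
#' @param on_treatment_drug drug label charged while on treatment and
#'   occupying S (`"denosumab"`, `"bp_oral"`, `"bp_iv"`, `"serm"`), or
#'   `NA` for no active treatment.
#' @param subsequent_mix named shares of drugs used as subsequent therapy in
#'   state D; must sum to 1. Default: denosumab 50.9% market share, the
#'   remaining 49.1% split equally between oral bisphosphonate, IV
#'   bisphosphonate and SERM.
#' @param fracture_arm which fracture-probability column of the
#'   [fracture_model()] this strategy uses: `"treated"` or `"discontinued"`.
#' @param cycle_length_years model cycle length (default 0.5 = 6 months).
#' @return object of class `strategy_spec`.
#' @export
strategy_spec <- function(name,
                          treatment_duration_cycles,
                          offset_years = 2,
                          cumulative_rebound = 0.999,
                          tp_S_to_I = 0,
                          tp_D_to_I = 0.033,
                          rr_D_to_I = 1,
                          on_treatment_drug = NA_character_,
                          subsequent_mix = default_subsequent_mix(),
                          fracture_arm = c("treated", "discontinued"),
                          cycle_length_years = 0.5) {
  fracture_arm <- match.arg(fracture_arm)
  lifetime <- identical(treatment_duration_cycles, "lifetime") ||
    is.infinite(treatment_duration_cycles)
  if (!lifetime) {
    stopifnot(treatment_duration_cycles >= 0,
              treatment_duration_cycles == round(treatment_duration_cycles))
    if (offset_years <= 0)
      stop("offset_years must be positive when the treatment duration is finite")
  }
  probs <- c(cumulative_rebound, tp_S_to_I, tp_D_to_I)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (abs(sum(subsequent_mix) - 1) > 1e-9)
    stop("subsequent_mix shares must sum to 1")
  structure(list(
    name = name,
    treatment_duration_cycles = if (lifetime) Inf else as.integer(treatment_duration_cycles),
    offset_years = offset_years,
    cumulative_rebound = cumulative_rebound,
    tp_S_to_I = tp_S_to_I,
    tp_D_to_I = tp_D_to_I * rr_D_to_I,
    on_treatment_drug = on_treatment_drug,
    subsequent_mix = subsequent_mix,
    fracture_arm = fracture_arm,
    cycle_length_years = cycle_length_years
  ), class = "strategy_spec")
}

#' Default market-share mix of subsequent therapy in state D
#'
#' Denosumab holds 50.9% of the market among patients whose T-score has
#' fallen back below -2.5; the remaining 49.1% (bisphosphonate/SERM) is
#' split equally between the three non-denosumab drugs, the split itself
#' not being published.
#'
#' @return named numeric vector of shares summing to 1.
#' @export
default_subsequent_mix <- function() {
  c(denosumab = 0.509,
    bp_oral = 0.491 / 3, bp_iv = 0.491 / 3, serm = 0.491 / 3)
}

#' Continuous-denosumab strategy (Dmab-C)
#'
#' Denosumab continues for 3 years (6 six-month cycles); during treatment the
#' S-to-D rebound probability is 0 and the per-cycle S-to-I improvement
#' probability is 0.108. After treatment stops, the effect wanes over the
#' offset window and S-to-I improvement ceases.
#'
#' @param treatment_duration_cycles on-treatment cycles (default 6 = 3 years),
#'   or `"lifetime"`.
#' @param offset_years offset window (default 2 years).
#' @param ... passed to [strategy_spec()].
#' @return a `strategy_spec`.
#' @export
dmab_c <- function(treatment_duration_cycles = 6L, offset_years = 2, ...) {
  strategy_spec("dmab_c",
                treatment_duration_cycles = treatment_duration_cycles,
                offset_years = offset_years,
                tp_S_to_I = 0.108,
                on_treatment_drug = "denosumab",
                fracture_arm = "treated", ...)
}

#' Denosumab-discontinuation strategy (Dmab-D)
#'
#' All osteoporosis drugs stop at model start, so the rebound from S to D
#' applies from cycle 1 and no improvement from S occurs (S-to-I = 0).
#' Patients who fall to state D still receive market-share-weighted
#' subsequent therapy.
#'
#' @param offset_years offset window (default 2 years).
#' @param ... passed to [strategy_spec()].
#' @return a `strategy_spec`.
#' @export
dmab_d <- function(offset_years = 2, ...) {
  strategy_spec("dmab_d",
                treatment_duration_cycles = 0L,
                offset_years = offset_years,
                tp_S_to_I = 0,
                on_treatment_drug = NA_character_,
                fracture_arm = "discontinued", ...)
}

#' Generic continuous-comparator strategy (BP-C / SERM-C)
#'
#' Structure for the continuous oral-bisphosphonate, IV-bisphosphonate and
#' SERM comparator strategies. Their transition and fracture inputs are not
#' packaged (they come from a supplement); supply them explicitly.
#'
#' @param name one of `"bp_c_oral"`, `"bp_c_iv"`, `"serm_c"`.
#' @param tp_S_to_I per-cycle S-to-I probability under the comparator drug.
#' @param drug drug label for on-treatment costing.
#' @param treatment_duration_cycles default 6 (3 years), as in the base case.
#' @param ... passed to [strategy_spec()].
#' @return a `strategy_spec`.
#' @export
comparator_c <- function(name = c("bp_c_oral", "bp_c_iv", "serm_c"),
                         tp_S_to_I,
                         drug = c("bp_oral", "bp_iv", "serm"),
                         treatment_duration_cycles = 6L, ...) {
  name <- match.arg(name)
  drug <- match.arg(drug)
  strategy_spec(name,
                treatment_duration_cycles = treatment_duration_cycles,
                tp_S_to_I = tp_S_to_I,
                on_treatment_drug = drug,
                fracture_arm = "treated", ...)
}

#' Per-cycle rebound probability over the offset window
#'
#' After active treatment stops, the protective effect wanes over
#' `offset_years`, during which nearly the whole surviving S population
#' rebounds to state D. The per-cycle probability is chosen so that the
#' cumulative rebound probability across the window equals
#' `cumulative_rebound`:
#' `1 - (1 - cumulative_rebound)^(cycle_length_years / offset_years)`.
#' With the default calibration constant 0.999 and a 2-year window this
#' gives 0.822 per 6-month cycle, the published per-cycle value.
#'
#' @param offset_years positive; must be a whole number of cycles.
#' @param cumulative_rebound in (0, 1).
#' @param cycle_length_years cycle length (default 0.5).
#' @return per-cycle rebound probability.
#' @export
rebound_cycle_prob <- function(offset_years, cumulative_rebound = 0.999,
                               cycle_length_years = 0.5) {
  stopifnot(offset_years > 0, cumulative_rebound > 0, cumulative_rebound < 1)
  n_cycles <- offset_years / cycle_length_years
  if (abs(n_cycles - round(n_cycles)) > 1e-9)
    stop("offset_years must be a whole number of cycles")
  1 - (1 - cumulative_rebound)^(cycle_length_years / offset_years)
}

#' Market-share-weighted transition probability of subsequent therapy
#'
#' @param shares named drug shares summing to 1.
#' @param per_drug_tp named per-drug transition probabilities; must cover
#'   every drug in `shares`.
#' @return the share-weighted mean probability.
#' @export
weighted_subsequent_tp <- function(shares, per_drug_tp) {
  if (abs(sum(shares) - 1) > 1e-9) stop("shares must sum to 1")
  missing <- setdiff(names(shares), names(per_drug_tp))
  if (length(missing))
    stop("no transition probability for drug(s): ",
         paste(missing, collapse = ", "))
  sum(shares * per_drug_tp[names(shares)])
}

#' Compile a strategy into a per-cycle transition schedule
#'
#' Returns one row per cycle with the main-state transition probabilities
#' `p_S_to_D`, `p_S_to_I` (into the high T-score-increase state) and
#' `p_D_to_I` (into the mid T-score-increase state), plus an `on_treatment`
#' flag controlling drug-cost eligibility. The T-score-increase states are
#' absorbing apart from death. For every cycle the outgoing probabilities
#' from S sum to at most 1; the residual is "remain in S".
#'
#' @param spec a `strategy_spec`.
#' @param n_cycles number of cycles to compile (positive integer).
#' @return data.frame of class `transition_schedule`.
#' @export
build_transition_schedule <- function(spec, n_cycles) {
  stopifnot(inherits(spec, "strategy_spec"))
  if (n_cycles < 1) stop("n_cycles must be at least 1")
  n_cycles <- as.integer(n_cycles)
  cyc <- seq_len(n_cycles)
  on_trt <- cyc <= spec$treatment_duration_cycles
  p_reb <- rebound_cycle_prob(spec$offset_years, spec$cumulative_rebound,
                              spec$cycle_length_years)
  sched <- data.frame(
    cycle = cyc,
    p_S_to_D = ifelse(on_trt, 0, p_reb),
    p_S_to_I = ifelse(on_trt, spec$tp_S_to_I, 0),
    p_D_to_I = spec$tp_D_to_I,
    on_treatment = on_trt
  )
  if (any(sched$p_S_to_D + sched$p_S_to_I > 1 + 1e-12))
    stop("outgoing probabilities from S exceed 1")
  class(sched) <- c("transition_schedule", "data.frame")
  sched
}
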