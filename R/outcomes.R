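#' Assemble a cost-consequence outcome block
#'
#' A block is one column of the cost-consequence summary layout: event
#' counts (per 100 patients) and per-patient costs (KRW). The two totals are
#' computed here and only here, so the layout identities
#' `total_fractures = vf + nvf` and
#' `cost_total = continuous + subsequent + fracture + productivity`
#' hold exactly for every block, including blocks of pairwise differences.
#'
#' @param vf,nvf vertebral / non-vertebral fractures per 100 patients.
#' @param fracture_deaths fracture-related deaths per 100 patients.
#' @param cost_continuous,cost_subsequent,cost_fracture,cost_productivity
#'   per-patient KRW components.
#' @return named numeric vector with the components plus `total_fractures`
#'   and `cost_total`.
#' @export
outcome_block <- function(vf, nvf, fracture_deaths,
                          cost_continuous, cost_subsequent, cost_fracture,
                          cost_productivity = 0) {
  c(vf = vf, nvf = nvf, total_fractures = vf + nvf,
    fracture_deaths = fracture_deaths,
    cost_continuous = cost_continuous,
    cost_subsequent = cost_subsequent,
    cost_fracture = cost_fracture,
    cost_productivity = cost_productivity,
    cost_total = cost_continuous + cost_subsequent + cost_fracture +
      cost_productivity)
}

#' Summarize a cohort trace into lifetime aggregates
#'
#' Sums the per-cycle ledger over the whole trace, in undiscounted and
#' discounted form: cumulative vertebral and non-vertebral fractures and
#' fracture-related deaths per 100 patients, and per-patient cost
#' components. Under the societal perspective a productivity-loss component
#' (human capital approach) is added from the trace's fracture-related
#' deaths.
#'
#' @param trace a `cca_trace` from [run_cohort()].
#' @param productivity optional [productivity_profile()]; when supplied the
#'   productivity-loss component is computed, otherwise it is 0.
#' @param events_per event scale (default 100 patients).
#' @param fracture_deaths reporting convention for the fracture-related-death
#'   sub-state: `"all"` (default) counts every death attributed to an
#'   incident-fracture patient during the fracture cycle
#'   (`incidence * min(1, q*SMR)`), `"excess"` counts only the SMR excess
#'   over background. The convention affects reporting (and the
#'   productivity-loss base) only, never the cohort dynamics.
#' @return object of class `cca_summary`: list with `strategy`, `n_cycles`,
#'   `events_per`, and `discounted` / `undiscounted` outcome blocks.
#' @export
summarize_trace <- function(trace, productivity = NULL, events_per = 100,
                            fracture_deaths = c("all", "excess")) {
  stopifnot(inherits(trace, "cca_trace"))
  fracture_deaths <- match.arg(fracture_deaths)
  fd_col <- paste0("deaths_fracture_", fracture_deaths)
  book <- attr(trace, "book")
  s <- function(col) if (nrow(trace)) sum(trace[[col]]) else 0

  prod_u <- prod_d <- 0
  if (!is.null(productivity) && nrow(trace)) {
    deaths <- data.frame(age = trace$age_start, mass = trace[[fd_col]],
                         time_years = trace$time_years)
    prod_u <- productivity_loss(deaths, productivity, rate_annual = 0)
    prod_d <- productivity_loss(deaths, productivity,
                                rate_annual = book$discount_rate_annual)
  }

  undisc <- outcome_block(
    vf = events_per * s("inc_vf"), nvf = events_per * s("inc_nvf"),
    fracture_deaths = events_per * s(fd_col),
    cost_continuous = s("cost_continuous"),
    cost_subsequent = s("cost_subsequent"),
    cost_fracture = s("cost_fracture"),
    cost_productivity = prod_u)
  disc <- outcome_block(
    vf = events_per * s("inc_vf_disc"), nvf = events_per * s("inc_nvf_disc"),
    fracture_deaths = events_per * s(paste0(fd_col, "_disc")),
    cost_continuous = s("cost_continuous_disc"),
    cost_subsequent = s("cost_subsequent_disc"),
    cost_fracture = s("cost_fracture_disc"),
    cost_productivity = prod_d)

  structure(list(strategy = attr(trace, "spec")$name,
                 n_cycles = nrow(trace), events_per = events_per,
                 discounted = disc, undiscounted = undisc),
            class = "cca_summary")
}

#' Pairwise difference of two cost-consequence summaries
#'
#' Componentwise `a - b`, discounted and undiscounted. Because the totals in
#' each block are exact sums of their components, each difference total
#' equals the sum of the component differences exactly.
#'
#' @param a,b `cca_summary` objects on the same event scale.
#' @return object of class `cca_comparison` with `discounted` and
#'   `undiscounted` difference blocks.
#' @export
compare_summaries <- function(a, b) {
  stopifnot(inherits(a, "cca_summary"), inherits(b, "cca_summary"),
            a$events_per == b$events_per)
  structure(list(strategies = c(a$strategy, b$strategy),
                 events_per = a$events_per,
                 discounted = a$discounted - b$discounted,
                 undiscounted = a$undiscounted - b$undiscounted),
            class = "cca_comparison")
}

#' @export
print.cca_summary <- function(x, ...) {
  cat("Cost-consequence summary -", x$strategy,
      sprintf("(%d cycles; events per %d patients, costs per patient, KRW)\n",
              x$n_cycles, x$events_per))
  print(round(cbind(discounted = x$discounted,
                    undiscounted = x$undiscounted), 2))
  invisible(x)
}

#' @export
print.cca_comparison <- function(x, ...) {
  cat("Difference:", x$strategies[1], "-", x$strategies[2],
      sprintf("(events per %d patients, costs per patient, KRW)\n",
              x$events_per))
  print(round(cbind(discounted = x$discounted,
                    undiscounted = x$undiscounted), 2))
  invisible(x)
}

#' Flatten a summary or comparison into a data.frame
#'
#' One row per outcome with `discounted` and `undiscounted` columns,
#' ready for `write.csv()`.
#'
#' @param x a `cca_summary` or `cca_comparison`.
#' @param ... unused.
#' @return data.frame.
#' @export
as.data.frame.cca_summary <- function(x, ...) {
  data.frame(outcome = names(x$discounted),
             discounted = unname(x$discounted),
             undiscounted = unname(x$undiscounted))
}

#' @rdname as.data.frame.cca_summary
#' @export
as.data.frame.cca_comparison <- as.data.frame.cca_summary
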