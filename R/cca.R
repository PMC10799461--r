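#' Cost-consequence analysis of osteoporosis treatment strategies
#'
#' Main entry point. Runs the Markov cohort model for each strategy on a
#' common life table, fracture model and cost book, and tabulates the
#' cost-consequence summary (events per 100 patients, costs per patient,
#' discounted and undiscounted) plus the pairwise difference of the first
#' strategy against the second, in the standard layout of a
#' cost-consequence base-case table.
#'
#' The packaged base case compares continuous denosumab therapy
#' ([dmab_c()]) against discontinuation ([dmab_d()]) in a cohort of
#' 55-year-old women over a lifetime horizon with 6-month cycles and a 4.5%
#' annual discount rate applied to both costs and consequences.
#'
#' @param strategies list of [strategy_spec()] objects (first is the
#'   intervention, second the comparator for the headline difference).
#' @param life_table a [life_table()]; defaults to the packaged synthetic
#'   Korean-style table from [make_life_table()].
#' @param fracture a [fracture_model()].
#' @param costs a [cost_book()].
#' @param start_age cohort starting age in years (default 55).
#' @param cycle_length_years cycle length (default 0.5 = 6 months).
#' @param horizon `"lifetime"` (default) or a horizon in years.
#' @param sex_mix named shares over `female`/`male` (default 100% female).
#' @param perspective `"healthcare"` (direct medical costs only) or
#'   `"societal"` (adds productivity losses from fracture-related deaths).
#' @param productivity a [productivity_profile()]; required for the
#'   societal perspective.
#' @param fracture_deaths reporting convention for fracture-related deaths,
#'   `"all"` (default) or `"excess"`; see [summarize_trace()].
#' @return object of class `cca`: list with the resolved `config`, per-
#'   strategy `traces` and `summaries`, and the headline `comparison`.
#' @examples
#' fit <- cca(horizon = 10)
#' fit
#' summary(fit)
#' @export
cca <- function(strategies = list(dmab_c(), dmab_d()),
                life_table = make_life_table(),
                fracture = fracture_model(),
                costs = cost_book(),
                start_age = 55,
                cycle_length_years = 0.5,
                horizon = "lifetime",
                sex_mix = c(female = 1),
                perspective = c("healthcare", "societal"),
                productivity = NULL,
                fracture_deaths = c("all", "excess")) {
  perspective <- match.arg(perspective)
  fracture_deaths <- match.arg(fracture_deaths)
  stopifnot(length(strategies) >= 1,
            all(vapply(strategies, inherits, logical(1), "strategy_spec")))
  if (perspective == "societal" && is.null(productivity))
    stop("the societal perspective needs a productivity_profile")
  prof <- if (perspective == "societal") productivity else NULL

  names(strategies) <- vapply(strategies, `[[`, character(1), "name")
  traces <- lapply(strategies, run_cohort, fm = fracture, lt = life_table,
                   book = costs, start_age = start_age,
                   cycle_length_years = cycle_length_years,
                   horizon = horizon, sex_mix = sex_mix)
  summaries <- lapply(traces, summarize_trace, productivity = prof,
                      fracture_deaths = fracture_deaths)
  comparison <- if (length(summaries) >= 2)
    compare_summaries(summaries[[1]], summaries[[2]]) else NULL

  structure(list(
    config = list(strategies = strategies, life_table = life_table,
                  fracture = fracture, costs = costs, start_age = start_age,
                  cycle_length_years = cycle_length_years, horizon = horizon,
                  sex_mix = sex_mix, perspective = perspective,
                  productivity = productivity,
                  fracture_deaths = fracture_deaths),
    traces = traces, summaries = summaries, comparison = comparison),
    class = "cca")
}

#' @export
print.cca <- function(x, ...) {
  cfg <- x$config
  cat("Markov cohort cost-consequence analysis\n")
  cat("  strategies :", paste(names(x$summaries), collapse = " vs "), "\n")
  cat("  start age  :", cfg$start_age, " cycle:", cfg$cycle_length_years,
      "y  horizon:", as.character(cfg$horizon),
      " discount:", cfg$costs$discount_rate_annual, "\n")
  cat("  perspective:", cfg$perspective, "\n\n")
  if (!is.null(x$comparison)) print(x$comparison) else
    print(x$summaries[[1]])
  invisible(x)
}

#' Summary method: the full cost-consequence table
#'
#' @param object a `cca` fit.
#' @param ... unused.
#' @return data.frame in the base-case layout: one row per outcome, one
#'   discounted and one undiscounted column per strategy plus the pairwise
#'   difference.
#' @export
summary.cca <- function(object, ...) {
  out <- data.frame(outcome = names(object$summaries[[1]]$discounted))
  for (nm in names(object$summaries)) {
    out[[paste0(nm, "_disc")]] <- unname(object$summaries[[nm]]$discounted)
    out[[paste0(nm, "_undisc")]] <- unname(object$summaries[[nm]]$undiscounted)
  }
  if (!is.null(object$comparison)) {
    out$difference_disc <- unname(object$comparison$discounted)
    out$difference_undisc <- unname(object$comparison$undiscounted)
  }
  out
}

#' Plot cumulative outcomes of a cost-consequence run
#'
#' Base-graphics panel: cumulative fractures per 100 patients over model
#' time for each strategy, and the discounted cost components.
#'
#' @param x a `cca` fit.
#' @param which `"fractures"` or `"costs"`.
#' @param ... passed to [graphics::matplot()] / [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.cca <- function(x, which = c("fractures", "costs"), ...) {
  which <- match.arg(which)
  if (which == "fractures") {
    cum <- sapply(x$traces, function(tr) cumsum(tr$inc_vf + tr$inc_nvf) * 100)
    graphics::matplot(x$traces[[1]]$time_years, cum, type = "l", lty = 1,
                      xlab = "years", ylab = "cumulative fractures / 100 patients",
                      ...)
    graphics::legend("bottomright", legend = colnames(cum),
                     col = seq_len(ncol(cum)), lty = 1, bty = "n")
  } else {
    comp <- sapply(x$summaries, function(s)
      s$discounted[c("cost_continuous", "cost_subsequent", "cost_fracture")])
    graphics::barplot(comp, beside = TRUE,
                      legend.text = c("continuous drug", "subsequent drug",
                                      "fracture treatment"),
                      ylab = "discounted KRW per patient", ...)
  }
  invisible(x)
}

#' Microsimulation replicates of a cost-consequence run
#'
#' Draws `nsim` independent individual-level Monte Carlo replicates of the
#' first strategy's run (see [microsim()]), e.g. to gauge first-order
#' (patient-level) variability around the cohort expectation.
#'
#' @param object a `cca` fit.
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param n individuals per replicate.
#' @param strategy strategy name to simulate (default: the first).
#' @param ... unused.
#' @return list of `microsim_result` objects, length `nsim`.
#' @export
simulate.cca <- function(object, nsim = 1, seed = 1L, n = 10000,
                         strategy = names(object$summaries)[1], ...) {
  cfg <- object$config
  lapply(seq_len(nsim), function(i)
    microsim(cfg$strategies[[strategy]], cfg$fracture, cfg$life_table,
             cfg$costs, n = n, seed = seed + i - 1L,
             start_age = cfg$start_age,
             cycle_length_years = cfg$cycle_length_years,
             horizon = cfg$horizon, sex_mix = cfg$sex_mix,
             productivity = if (cfg$perspective == "societal")
               cfg$productivity else NULL,
             fracture_deaths = cfg$fracture_deaths))
}
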