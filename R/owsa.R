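#' Define a one-way sensitivity scenario
#'
#' A scenario overrides exactly one resolved configuration value of the
#' base-case analysis. Valid override paths:
#' * `discount_rate` — annual discount rate (e.g. 0 or 0.03);
#' * `horizon_years` — finite horizon in years (e.g. 3, 5, 10), or
#'   `"lifetime"`;
#' * `start_age` — cohort starting age (may be fractional, e.g. 72.3;
#'   life-table lookups floor the mid-cycle age);
#' * `offset_years` — offset window of every strategy (e.g. 1 or 3);
#' * `treatment_duration_years` — on-treatment duration of the actively
#'   treated strategies (numeric years, or `"lifetime"`); strategies with
#'   no active treatment (duration 0) are untouched;
#' * `perspective` — `"societal"` adds productivity losses to both arms.
#'
#' @param name scenario label.
#' @param path one of the paths above.
#' @param value the override value.
#' @return object of class `owsa_scenario`.
#' @export
owsa_scenario <- function(name, path, value) {
  valid <- c("discount_rate", "horizon_years", "start_age", "offset_years",
             "treatment_duration_years", "perspective")
  if (!path %in% valid)
    stop("unknown override path '", path, "'; valid paths: ",
         paste(valid, collapse = ", "))
  structure(list(name = name, path = path, value = value),
            class = "owsa_scenario")
}

# apply one scenario override to a cca() argument list
apply_override <- function(args, sc) {
  switch(sc$path,
    discount_rate = {
      args$costs$discount_rate_annual <- sc$value
      args
    },
    horizon_years = {
      args$horizon <- if (identical(sc$value, "lifetime")) "lifetime" else sc$value
      args
    },
    start_age = {
      args$start_age <- sc$value
      args
    },
    offset_years = {
      args$strategies <- lapply(args$strategies, function(s) {
        s$offset_years <- sc$value
        s
      })
      args
    },
    treatment_duration_years = {
      args$strategies <- lapply(args$strategies, function(s) {
        if (s$treatment_duration_cycles > 0) {
          s$treatment_duration_cycles <-
            if (identical(sc$value, "lifetime")) Inf
            else as.integer(round(sc$value / s$cycle_length_years))
        }
        s
      })
      args
    },
    perspective = {
      args$perspective <- sc$value
      args
    })
}

#' Run a one-way sensitivity analysis
#'
#' Re-runs the base-case comparison under each scenario, varying exactly one
#' configuration value at a time, and tabulates the first-vs-second strategy
#' differences (discounted) per scenario. The first row is always the
#' unmodified base case.
#'
#' @param scenarios list of [owsa_scenario()] objects (may be empty: the
#'   result is then the base-case row only).
#' @param ... base-case arguments passed to [cca()] (strategies,
#'   life_table, fracture, costs, start_age, horizon, perspective,
#'   productivity, ...).
#' @return data.frame of class `owsa_table`: one row per scenario with the
#'   override, the discounted difference of every outcome, and the
#'   undiscounted total-cost difference.
#' @export
run_owsa <- function(scenarios = list(), ...) {
  # resolve the full base configuration up front so overrides always address
  # materialized values, never missing defaults
  defaults <- list(strategies = list(dmab_c(), dmab_d()),
                   life_table = make_life_table(),
                   fracture = fracture_model(), costs = cost_book(),
                   start_age = 55, cycle_length_years = 0.5,
                   horizon = "lifetime", sex_mix = c(female = 1),
                   perspective = "healthcare", productivity = NULL,
                   fracture_deaths = "all")
  supplied <- list(...)
  unknown <- setdiff(names(supplied), names(defaults))
  if (length(unknown))
    stop("unknown base-case argument(s): ", paste(unknown, collapse = ", "))
  base_args <- utils::modifyList(defaults, supplied)
  rows <- list()
  fits <- list()
  add_row <- function(name, path, value, fit) {
    d <- fit$comparison$discounted
    data.frame(scenario = name, override = path,
               value = as.character(value),
               t(as.matrix(d)),
               cost_total_undisc = unname(fit$comparison$undiscounted[["cost_total"]]),
               row.names = NULL, check.names = FALSE)
  }
  base_fit <- do.call(cca, base_args)
  if (is.null(base_fit$comparison))
    stop("OWSA needs at least two strategies to difference")
  rows[["base"]] <- add_row("base_case", "", "", base_fit)
  fits[["base_case"]] <- base_fit
  for (sc in scenarios) {
    stopifnot(inherits(sc, "owsa_scenario"))
    fit <- do.call(cca, apply_override(base_args, sc))
    rows[[sc$name]] <- add_row(sc$name, sc$path, sc$value, fit)
    fits[[sc$name]] <- fit
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("owsa_table", "data.frame"), fits = fits)
}

#' Published set of one-way sensitivity scenarios
#'
#' The standard scenario list varied in the base-case analysis: discount
#' rate 0% and 3%, horizons of 3/5/10 years, starting age 72.3 (the mean
#' trial enrollment age), offset time 1 and 3 years, treatment duration
#' 1/2/5 years and lifetime, and the societal perspective.
#'
#' @return list of [owsa_scenario()] objects.
#' @export
default_owsa_scenarios <- function() {
  list(
    owsa_scenario("discount_0pct", "discount_rate", 0),
    owsa_scenario("discount_3pct", "discount_rate", 0.03),
    owsa_scenario("horizon_3y", "horizon_years", 3),
    owsa_scenario("horizon_5y", "horizon_years", 5),
    owsa_scenario("horizon_10y", "horizon_years", 10),
    owsa_scenario("start_age_72.3", "start_age", 72.3),
    owsa_scenario("offset_1y", "offset_years", 1),
    owsa_scenario("offset_3y", "offset_years", 3),
    owsa_scenario("duration_1y", "treatment_duration_years", 1),
    owsa_scenario("duration_2y", "treatment_duration_years", 2),
    owsa_scenario("duration_5y", "treatment_duration_years", 5),
    owsa_scenario("duration_lifetime", "treatment_duration_years", "lifetime"),
    owsa_scenario("societal", "perspective", "societal")
  )
}

#' Tornado-style bar chart of OWSA total-cost differences
#'
#' @param tab an `owsa_table`.
#' @param outcome column to plot (default the discounted total-cost
#'   difference).
#' @param ... passed to [graphics::barplot()].
#' @return the bar midpoints, invisibly.
#' @export
plot_owsa <- function(tab, outcome = "cost_total", ...) {
  stopifnot(inherits(tab, "owsa_table"))
  v <- tab[[outcome]]
  invisible(graphics::barplot(v, names.arg = tab$scenario, horiz = TRUE,
                              las = 1, xlab = paste("difference in", outcome),
                              ...))
}
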