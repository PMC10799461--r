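#' Individual-level microsimulation of one strategy
#'
#' Monte Carlo re-implementation of the cohort model at the level of
#' individual patients, used as an independent validation oracle for
#' [run_cohort()]. Each patient takes one random draw per decision point in
#' the exact event order of [step_cycle()]: background death, incident
#' fracture type (mutually exclusive VF / non-VF / well), fracture-related
#' excess death, then the main-state transition. Costs accrue to each
#' patient's end-of-cycle state exactly as in the cohort engine.
#'
#' Deterministic given `(seed, n)`. Reported outcomes are means over
#' patients on the cohort scale (events per 100, costs per patient) with
#' Monte Carlo standard errors.
#'
#' @param spec a [strategy_spec()].
#' @param fm a [fracture_model()].
#' @param lt a [life_table()].
#' @param book a [cost_book()].
#' @param n number of simulated patients.
#' @param seed integer seed.
#' @param start_age,cycle_length_years,horizon,sex_mix as in [run_cohort()].
#' @param productivity optional [productivity_profile()] for the societal
#'   perspective.
#' @param events_per event scale (default 100).
#' @param fracture_deaths reporting convention, `"all"` (default) or
#'   `"excess"`, matching [summarize_trace()]. Under `"all"` each incident
#'   fracture is additionally credited with its background death share
#'   `q_cycle` (an unbiased individual-level estimator of the cohort
#'   attribution `incidence * min(1, q*SMR)`).
#' @return object of class `microsim_result`: `discounted` / `undiscounted`
#'   outcome blocks (same fields as [summarize_trace()]), matching
#'   `se_discounted` / `se_undiscounted` blocks, plus `n` and `seed`.
#' @export
microsim <- function(spec, fm, lt, book = cost_book(), n = 10000, seed = 1L,
                     start_age = 55, cycle_length_years = 0.5,
                     horizon = "lifetime", sex_mix = c(female = 1),
                     productivity = NULL, events_per = 100,
                     fracture_deaths = c("all", "excess")) {
  stopifnot(n >= 1)
  fracture_deaths <- match.arg(fracture_deaths)
  max_age <- attr(lt, "max_age")
  n_cycles <- horizon_cycles(horizon, start_age, max_age, cycle_length_years)
  schedule <- if (n_cycles > 0) build_transition_schedule(spec, n_cycles)
  arm <- spec$fracture_arm
  p_vf <- fm$p_vf[, arm]
  p_nvf <- fm$p_nvf[, arm]
  subs_cost <- subsequent_cycle_cost(book, spec$subsequent_mix)
  cont_cost <- if (!is.na(spec$on_treatment_drug))
    drug_cycle_cost(book, spec$on_treatment_drug) else 0
  c_vf <- book$fracture_event_cost[["vf"]]
  c_nvf <- book$fracture_event_cost[["nvf"]]

  # deterministic sex assignment matching the mix as closely as possible
  sexes <- rep(names(sex_mix), times = round(unname(sex_mix) * n))
  sexes <- c(sexes, rep(names(sex_mix)[1], n - length(sexes)))[seq_len(n)]
  is_f <- sexes == "female"

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  state <- rep.int(1L, n)            # 1=S 2=D 3=I_mid 4=I_high 0=dead
  acc <- matrix(0, n, 12,
                dimnames = list(NULL, c(
                  "vf_u", "vf_d", "nvf_u", "nvf_d", "frd_u", "frd_d",
                  "cont_u", "cont_d", "subs_u", "subs_d", "frac_u", "frac_d")))
  prod_u <- prod_d <- numeric(n)

  for (t in seq_len(n_cycles)) {
    alive <- which(state > 0L)
    if (!length(alive)) break
    age_t <- start_age + (t - 1) * cycle_length_years
    q_f <- annual_to_cycle(lookup_q(lt, age_t, "female"), cycle_length_years)
    q_m <- annual_to_cycle(lookup_q(lt, age_t, "male"), cycle_length_years)
    qv <- ifelse(is_f[alive], q_f, q_m)
    df <- discount_factor(t, book$discount_rate_annual, cycle_length_years)

    die_bg <- stats::runif(length(alive)) < qv
    state[alive[die_bg]] <- 0L
    surv <- alive[!die_bg]

    if (length(surv)) {
      u <- stats::runif(length(surv))
      pv <- p_vf[state[surv]]
      pn <- p_nvf[state[surv]]
      got_vf <- u < pv
      got_nvf <- !got_vf & u < pv + pn
      acc[surv[got_vf], "vf_u"] <- acc[surv[got_vf], "vf_u"] + 1
      acc[surv[got_vf], "vf_d"] <- acc[surv[got_vf], "vf_d"] + df
      acc[surv[got_nvf], "nvf_u"] <- acc[surv[got_nvf], "nvf_u"] + 1
      acc[surv[got_nvf], "nvf_d"] <- acc[surv[got_nvf], "nvf_d"] + df
      acc[surv[got_vf], "frac_u"] <- acc[surv[got_vf], "frac_u"] + c_vf
      acc[surv[got_vf], "frac_d"] <- acc[surv[got_vf], "frac_d"] + c_vf * df
      acc[surv[got_nvf], "frac_u"] <- acc[surv[got_nvf], "frac_u"] + c_nvf
      acc[surv[got_nvf], "frac_d"] <- acc[surv[got_nvf], "frac_d"] + c_nvf * df

      fractured <- surv[got_vf | got_nvf]
      if (length(fractured)) {
        fvf <- got_vf[got_vf | got_nvf]
        qfr <- ifelse(is_f[fractured], q_f, q_m)
        smr <- ifelse(fvf,
                      ifelse(is_f[fractured], fm$smr_vf[["female"]],
                             fm$smr_vf[["male"]]),
                      ifelse(is_f[fractured], fm$smr_nvf[["female"]],
                             fm$smr_nvf[["male"]]))
        ex <- pmin(1, qfr * smr) - qfr
        die_fr <- stats::runif(length(fractured)) < ex
        dying <- fractured[die_fr]
        loss_u <- loss_dsc <- 0
        if (!is.null(productivity)) {
          dd <- data.frame(age = age_t, mass = 1,
                           time_years = t * cycle_length_years)
          loss_u <- productivity_loss(dd, productivity, rate_annual = 0)
          loss_dsc <- productivity_loss(dd, productivity,
                                        rate_annual = book$discount_rate_annual)
        }
        if (fracture_deaths == "all") {
          # credit each fracture with its background death share q
          acc[fractured, "frd_u"] <- acc[fractured, "frd_u"] + qfr
          acc[fractured, "frd_d"] <- acc[fractured, "frd_d"] + qfr * df
          prod_u[fractured] <- prod_u[fractured] + qfr * loss_u
          prod_d[fractured] <- prod_d[fractured] + qfr * loss_dsc
        }
        if (length(dying)) {
          acc[dying, "frd_u"] <- acc[dying, "frd_u"] + 1
          acc[dying, "frd_d"] <- acc[dying, "frd_d"] + df
          prod_u[dying] <- prod_u[dying] + loss_u
          prod_d[dying] <- prod_d[dying] + loss_dsc
          state[dying] <- 0L
        }
      }

      rem <- surv[state[surv] > 0L]
      if (length(rem)) {
        u2 <- stats::runif(length(rem))
        inS <- state[rem] == 1L
        inD <- state[rem] == 2L
        row <- schedule[t, ]
        toD <- inS & u2 < row$p_S_to_D
        toIh <- inS & !toD & u2 < row$p_S_to_D + row$p_S_to_I
        toIm <- inD & u2 < row$p_D_to_I
        state[rem[toD]] <- 2L
        state[rem[toIh]] <- 4L
        state[rem[toIm]] <- 3L
      }
    }

    end_alive <- which(state > 0L)
    if (length(end_alive)) {
      inS <- end_alive[state[end_alive] == 1L]
      inD <- end_alive[state[end_alive] == 2L]
      if (schedule$on_treatment[t] && cont_cost > 0 && length(inS)) {
        acc[inS, "cont_u"] <- acc[inS, "cont_u"] + cont_cost
        acc[inS, "cont_d"] <- acc[inS, "cont_d"] + cont_cost * df
      }
      if (length(inD)) {
        acc[inD, "subs_u"] <- acc[inD, "subs_u"] + subs_cost
        acc[inD, "subs_d"] <- acc[inD, "subs_d"] + subs_cost * df
      }
    }
  }

# per-individual outcome matrix on the reporting scale, so means give the
  # block and column sds give proper Monte Carlo SEs (including for totals)
  indiv <- function(sfx, prod) {
    m <- cbind(
      vf = events_per * acc[, paste0("vf_", sfx)],
      nvf = events_per * acc[, paste0("nvf_", sfx)],
      fracture_deaths = events_per * acc[, paste0("frd_", sfx)],
      cost_continuous = acc[, paste0("cont_", sfx)],
      cost_subsequent = acc[, paste0("subs_", sfx)],
      cost_fracture = acc[, paste0("frac_", sfx)],
      cost_productivity = prod)
    cbind(m[, 1:2, drop = FALSE],
          total_fractures = m[, "vf"] + m[, "nvf"],
          m[, 3:7, drop = FALSE],
          cost_total = m[, "cost_continuous"] + m[, "cost_subsequent"] +
            m[, "cost_fracture"] + m[, "cost_productivity"])
  }
  ord <- names(outcome_block(0, 0, 0, 0, 0, 0))
  blk <- function(sfx, prod) colMeans(indiv(sfx, prod))[ord]
  seblk <- function(sfx, prod) {
    m <- indiv(sfx, prod)
    (apply(m, 2, stats::sd) / sqrt(n))[ord]
  }

  structure(list(strategy = spec$name, n = n, seed = seed,
                 events_per = events_per,
                 discounted = blk("d", prod_d),
                 undiscounted = blk("u", prod_u),
                 se_discounted = seblk("d", prod_d),
                 se_undiscounted = seblk("u", prod_u)),
            class = c("microsim_result"))
}

#' @export
print.microsim_result <- function(x, ...) {
  cat("Microsimulation -", x$strategy,
      sprintf("(n = %d, seed = %d)\n", x$n, x$seed))
  print(round(cbind(discounted = x$discounted, se = x$se_discounted,
                    undiscounted = x$undiscounted,
                    se_u = x$se_undiscounted), 3))
  invisible(x)
}
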