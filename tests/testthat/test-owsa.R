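test_that("empty scenario list yields the base-case row only", {
  lt <- make_life_table()
  tab <- run_owsa(list(), life_table = lt, horizon = 5)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$scenario, "base_case")
})

test_that("unknown override paths are rejected with the valid set", {
  expect_error(owsa_scenario("x", "fracture_cost", 1), "valid paths")
  expect_error(owsa_scenario("x", "fracture_cost", 1), "discount_rate")
})

test_that("the 0% discount scenario equals the undiscounted base case exactly", {
  lt <- make_life_table()
  tab <- run_owsa(list(owsa_scenario("discount_0pct", "discount_rate", 0)),
                  life_table = lt, horizon = 15)
  base_fit <- attr(tab, "fits")$base_case
  zero_row <- tab[tab$scenario == "discount_0pct", ]
  undisc <- base_fit$comparison$undiscounted
  for (f in names(undisc))
    expect_identical(zero_row[[f]], unname(undisc[[f]]))
})

test_that("lifetime treatment scenario removes rebound and raises drug cost", {
  lt <- make_life_table()
  tab <- run_owsa(list(owsa_scenario("duration_lifetime",
                                     "treatment_duration_years", "lifetime")),
                  life_table = lt, horizon = "lifetime")
  fit_l <- attr(tab, "fits")$duration_lifetime
  spec_l <- fit_l$config$strategies[[1]]
  sc <- build_transition_schedule(spec_l, 50)
  expect_equal(sc$p_S_to_D, rep(0, 50))
  # the comparator's duration (0 cycles) is untouched
  expect_equal(fit_l$config$strategies[[2]]$treatment_duration_cycles, 0L)
  base <- tab[tab$scenario == "base_case", ]
  expect_gt(tab[tab$scenario == "duration_lifetime", "cost_continuous"],
            base$cost_continuous)
})

test_that("total-cost savings grow with the horizon", {
  lt <- make_life_table()
  tab <- run_owsa(list(owsa_scenario("h3", "horizon_years", 3),
                       owsa_scenario("h5", "horizon_years", 5),
                       owsa_scenario("h10", "horizon_years", 10)),
                  life_table = lt, horizon = "lifetime")
  saving <- -tab$cost_total[match(c("h3", "h5", "h10", "base_case"),
                                  tab$scenario)]
  expect_true(all(diff(saving) > 0))
})

test_that("fractional starting ages floor for mortality lookup while aging continuously", {
  lt <- make_life_table()
  tr <- run_cohort(dmab_d(), fracture_model(), lt, start_age = 72.3,
                   horizon = 2)
  expect_equal(tr$age_start, c(72.3, 72.8, 73.3, 73.8))
  q_expect <- annual_to_cycle(lookup_q(lt, c(72, 72, 73, 73), "female"), 0.5)
  expect_equal(tr$q_cycle, q_expect, tolerance = 1e-12)
})

test_that("the societal perspective adds productivity loss and nothing else", {
  lt <- make_life_table()
  prof <- make_productivity_profile()
  tab <- run_owsa(list(owsa_scenario("societal", "perspective", "societal")),
                  life_table = lt, horizon = "lifetime",
                  productivity = prof)
  base <- tab[tab$scenario == "base_case", ]
  soc <- tab[tab$scenario == "societal", ]
  same <- c("vf", "nvf", "total_fractures", "fracture_deaths",
            "cost_continuous", "cost_subsequent", "cost_fracture")
  for (f in same) expect_identical(soc[[f]], base[[f]])
  expect_lt(soc$cost_productivity, 0)   # continuation averts deaths -> saving
  expect_equal(soc$cost_total, base$cost_total + soc$cost_productivity,
               tolerance = 1e-12)
})

test_that("each scenario changes exactly one resolved configuration value", {
  lt <- make_life_table()
  tab <- run_owsa(list(owsa_scenario("age", "start_age", 72.3),
                       owsa_scenario("offset", "offset_years", 1)),
                  life_table = lt, horizon = 5)
  fits <- attr(tab, "fits")
  base_cfg <- fits$base_case$config
  expect_equal(fits$age$config$start_age, 72.3)
  expect_equal(fits$age$config$horizon, base_cfg$horizon)
  expect_equal(fits$offset$config$strategies[[1]]$offset_years, 1)
  expect_equal(fits$offset$config$start_age, base_cfg$start_age)
})
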