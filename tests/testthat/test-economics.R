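test_that("discount factors follow the annual-rate closed form", {
  expect_equal(discount_factor(1:10, 0, 0.5), rep(1, 10))
  expect_equal(discount_factor(2, 0.045, 0.5), 1 / 1.045, tolerance = 1e-12)
  expect_equal(discount_factor(1, 0.045, 0.5), 1.045^-0.5, tolerance = 1e-12)
  expect_equal(round(discount_factor(1, 0.045, 0.5), 6), 0.978232)
  expect_error(discount_factor(1, -0.01), "rate")
})

test_that("cycle cost accrual matches the unit-cost book", {
  book <- cost_book()
  empty <- c(S = 0, D = 0, I_mid = 0.6, I_high = 0.4, dead = 0)
  expect_equal(unname(accrue_cycle_costs(empty, 0, 0, TRUE, dmab_c(), book)),
               c(0, 0, 0))
  # full S occupancy on treatment: denosumab drug + administration
  full_s <- c(S = 1, D = 0, I_mid = 0, I_high = 0, dead = 0)
  got <- accrue_cycle_costs(full_s, 0, 0, TRUE, dmab_c(), book)
  expect_equal(got[["cost_continuous"]], 177650 + 4843)
  # off-treatment cycles accrue no continuous drug cost
  expect_equal(accrue_cycle_costs(full_s, 0, 0, FALSE, dmab_c(),
                                  book)[["cost_continuous"]], 0)
  # fracture treatment cost accrues per event
  expect_equal(accrue_cycle_costs(empty, 0.01, 0, FALSE, dmab_c(),
                                  book)[["cost_fracture"]], 27170.95)
  # subsequent therapy priced at the market-share-weighted per-cycle cost
  in_d <- c(S = 0, D = 1, I_mid = 0, I_high = 0, dead = 0)
  expect_equal(accrue_cycle_costs(in_d, 0, 0, FALSE, dmab_d(),
                                  book)[["cost_subsequent"]],
               subsequent_cycle_cost(book), tolerance = 1e-12)
  expect_error(drug_cycle_cost(book, "aspirin"), "unknown drug")
})

test_that("productivity loss follows the human capital approach", {
  prof <- flat_profile(income = 30e6, employment = 0.5, retirement_age = 65)
  # one death per patient at age 60, rate 0: 5 years x 15,000,000
  d60 <- data.frame(age = 60, mass = 1, time_years = 5)
  expect_equal(productivity_loss(d60, prof, rate_annual = 0), 5 * 15e6)
  # deaths at or after retirement cost nothing
  d70 <- data.frame(age = 70, mass = 1, time_years = 15)
  expect_equal(productivity_loss(d70, prof, rate_annual = 0), 0)
  # zero employment everywhere -> zero loss
  prof0 <- flat_profile(employment = 0)
  expect_equal(productivity_loss(d60, prof0, rate_annual = 0), 0)
  # discounting shrinks the loss
  expect_lt(productivity_loss(d60, prof, rate_annual = 0.045), 5 * 15e6)
  # profile gaps are reported
  short <- productivity_profile(c(`64` = 30e6), c(`64` = 0.5),
                                retirement_age = 65)
  expect_error(productivity_loss(d60, short, 0), "gap")
})

test_that("outcome blocks enforce the additive layout identities", {
  b <- outcome_block(vf = 3.5, nvf = 1.25, fracture_deaths = 0.2,
                     cost_continuous = 100, cost_subsequent = 200,
                     cost_fracture = 300, cost_productivity = 50)
  expect_identical(b[["total_fractures"]], 3.5 + 1.25)
  expect_identical(b[["cost_total"]], 100 + 200 + 300 + 50)
})

test_that("summaries add over cycles and compare componentwise", {
  fit <- cca(horizon = 5)
  s <- fit$summaries$dmab_c
  tr <- fit$traces$dmab_c
  expect_equal(s$undiscounted[["vf"]], 100 * sum(tr$inc_vf))
  expect_equal(s$discounted[["cost_fracture"]], sum(tr$cost_fracture_disc))
  # self-comparison is identically zero
  self <- compare_summaries(s, s)
  expect_equal(unname(self$discounted), rep(0, 9))
  expect_equal(unname(self$undiscounted), rep(0, 9))
  # difference totals equal sums of component differences exactly
  d <- fit$comparison$discounted
  expect_identical(d[["cost_total"]],
                   d[["cost_continuous"]] + d[["cost_subsequent"]] +
                     d[["cost_fracture"]] + d[["cost_productivity"]])
})

test_that("discounting never increases an outcome and vanishes at rate 0", {
  fit <- cca(horizon = 20)
  for (s in fit$summaries)
    expect_true(all(s$discounted <= s$undiscounted + 1e-9))
  fit0 <- cca(costs = cost_book(discount_rate_annual = 0), horizon = 20)
  for (s in fit0$summaries)
    expect_identical(s$discounted, s$undiscounted)
})

test_that("cost outputs are linear in unit costs, events unchanged", {
  lt <- make_life_table()
  book1 <- cost_book()
  book2 <- cost_book(
    drug_cost_per_cycle = 2 * book1$drug_cost_per_cycle,
    admin_cost_per_cycle = 2 * book1$admin_cost_per_cycle,
    fracture_event_cost = 2 * book1$fracture_event_cost)
  f1 <- cca(costs = book1, life_table = lt, horizon = 15)
  f2 <- cca(costs = book2, life_table = lt, horizon = 15)
  for (nm in names(f1$summaries)) {
    a <- f1$summaries[[nm]]; b <- f2$summaries[[nm]]
    cost_fields <- c("cost_continuous", "cost_subsequent", "cost_fracture",
                     "cost_total")
    expect_equal(b$discounted[cost_fields], 2 * a$discounted[cost_fields],
                 tolerance = 1e-12)
    ev <- c("vf", "nvf", "total_fractures", "fracture_deaths")
    expect_identical(b$undiscounted[ev], a$undiscounted[ev])
  }
})

test_that("budget helpers compute plain ratios and products", {
  expect_equal(saving_burden_ratio(50, 1000), 5)
  expect_equal(national_budget_impact(100, 3), 300)
})
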