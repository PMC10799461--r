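test_that("dead is absorbing and the null cycle is the identity", {
  lt <- flat_life_table(0.001)
  sched <- build_transition_schedule(dmab_d(), 5)

  dead <- cohort_state(c(S = 0, D = 0, I_mid = 0, I_high = 0, dead = 1),
                       age = 60)
  out <- step_cycle(dead, sched, fracture_model(), lt, arm = "discontinued")
  expect_equal(out$state$occupancy, dead$occupancy)
  expect_equal(unname(out$ledger[c("inc_vf", "inc_nvf", "deaths_background",
                                   "deaths_fracture_excess")]),
               rep(0, 4))

  # zero mortality, zero fracture, zero transitions: occupancy unchanged
  idle <- build_transition_schedule(inert_strategy(), 5)
  mix <- cohort_state(c(S = 0.4, D = 0.3, I_mid = 0.2, I_high = 0.1, dead = 0),
                      age = 60)
  out2 <- step_cycle(mix, idle, zero_fracture_model(), zero_life_table())
  expect_equal(out2$state$occupancy, mix$occupancy)
  expect_equal(out2$state$age, 60.5)
})

test_that("one cycle from S reproduces the hand-computed ledger", {
  # 100% in S, discontinued arm, q_cycle = 0.001, female SMRs
  lt <- life_table(data.frame(age = c(60, 61), sex = "female",
                              q_annual = c(1 - (1 - 0.001)^2, 1)),
                   max_age = 61)
  st <- cohort_state(age = 60)
  sched <- build_transition_schedule(dmab_d(), 1)
  out <- step_cycle(st, sched, fracture_model(), lt, arm = "discontinued")

  expect_equal(out$ledger[["q_cycle"]], 0.001, tolerance = 1e-12)
  # incident VF per 100 patients = 1.3 * (1 - 0.001)
  expect_equal(100 * out$ledger[["inc_vf"]], 1.2987, tolerance = 1e-9)
  expect_equal(100 * out$ledger[["inc_nvf"]], 1.6 * 0.999, tolerance = 1e-9)
  # excess fracture deaths: inc * q * (SMR - 1), summed over VF and non-VF
  expect_equal(out$ledger[["deaths_fracture_excess"]],
               0.012987 * 0.001 * (2.99 - 1) +
                 0.015984 * 0.001 * (3.29 - 1), tolerance = 1e-12)
  # all-deaths attribution adds the background share of fractured patients
  expect_equal(out$ledger[["deaths_fracture_all"]],
               out$ledger[["deaths_fracture_excess"]] +
                 (0.012987 + 0.015984) * 0.001, tolerance = 1e-12)
})

test_that("fracture_related_death closed form and cap", {
  expect_equal(fracture_related_death(0.5, 0.01, 1), 0)
  expect_equal(fracture_related_death(0.01, 0.002, 4.56), 0.01 * 0.002 * 3.56,
               tolerance = 1e-15)
  expect_equal(fracture_related_death(0.01, 0.5, 10), 0.01 * (1 - 0.5))
  expect_error(fracture_related_death(0.01, 0.5, -1), "smr")
})

test_that("run_cohort trivial horizons and the null model", {
  tr0 <- run_cohort(dmab_c(), fracture_model(), make_life_table(),
                    horizon = 0)
  expect_equal(nrow(tr0), 0)

  null <- run_cohort(dmab_d(), zero_fracture_model(), zero_life_table(),
                     horizon = 30)
  expect_equal(sum(null$inc_vf) + sum(null$inc_nvf), 0)
  expect_equal(max(null$occ_dead), 0)
})

test_that("mass is conserved and dead mass is monotone for random draws", {
  for (seed in 1:25) {
    p <- sample_params(seed)
    lt <- make_life_table(seed = seed)
    for (s in p$strategies) {
      tr <- run_cohort(s, p$fracture, lt, p$costs,
                       start_age = p$start_age, horizon = "lifetime",
                       sex_mix = p$sex_mix)
      mass <- tr$occ_S + tr$occ_D + tr$occ_I_mid + tr$occ_I_high + tr$occ_dead
      expect_true(all(abs(mass - 1) < 1e-12))
      expect_true(all(diff(tr$occ_dead) >= -1e-15))
      # terminal age absorbs the whole cohort under a lifetime horizon
      expect_equal(tr$occ_dead[nrow(tr)], 1, tolerance = 1e-9)
    }
  }
})

test_that("raising a fracture probability raises fractures, deaths and cost", {
  lt <- make_life_table()
  base_fm <- fracture_model()
  hi_vf <- default_p_vf(); hi_vf["D", "discontinued"] <- 0.05
  hi_fm <- fracture_model(p_vf = hi_vf)
  lo <- run_cohort(dmab_d(), base_fm, lt)
  hi <- run_cohort(dmab_d(), hi_fm, lt)
  expect_gt(sum(hi$inc_vf), sum(lo$inc_vf))
  expect_gt(sum(hi$deaths_fracture_excess), sum(lo$deaths_fracture_excess))
  expect_gt(sum(hi$cost_fracture), sum(lo$cost_fracture))
})

test_that("continuation dominates discontinuation in cumulative fractures", {
  fit <- cca()
  cum_c <- cumsum(fit$traces$dmab_c$inc_vf + fit$traces$dmab_c$inc_nvf)
  cum_d <- cumsum(fit$traces$dmab_d$inc_vf + fit$traces$dmab_d$inc_nvf)
  expect_true(all(cum_c <= cum_d + 1e-12))
})

test_that("mixed-sex cohorts are the weighted blend of single-sex runs", {
  lt <- make_life_table()
  mix <- run_cohort(dmab_d(), fracture_model(), lt,
                    sex_mix = c(female = 0.7, male = 0.3), horizon = 10)
  f <- run_cohort(dmab_d(), fracture_model(), lt,
                  sex_mix = c(female = 1), horizon = 10)
  m <- run_cohort(dmab_d(), fracture_model(), lt,
                  sex_mix = c(male = 1), horizon = 10)
  expect_equal(mix$inc_vf, 0.7 * f$inc_vf + 0.3 * m$inc_vf, tolerance = 1e-12)
  expect_equal(mix$occ_dead, 0.7 * f$occ_dead + 0.3 * m$occ_dead,
               tolerance = 1e-12)
})
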