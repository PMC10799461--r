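test_that("rebound probability matches its calibration anchors", {
  # 2-year offset, 6-month cycles: the published per-cycle value
  expect_equal(round(rebound_cycle_prob(2, 0.999, 0.5), 3), 0.822)
  # closed forms at other offsets: 1 - 0.001^(1/2), 1 - 0.001^(1/6)
  expect_equal(rebound_cycle_prob(1, 0.999, 0.5), 1 - 0.001^(1 / 2),
               tolerance = 1e-12)
  expect_equal(rebound_cycle_prob(3, 0.999, 0.5), 1 - 0.001^(1 / 6),
               tolerance = 1e-12)
  expect_equal(round(rebound_cycle_prob(1, 0.999, 0.5), 4), 0.9684)
  expect_equal(round(rebound_cycle_prob(3, 0.999, 0.5), 4), 0.6838)
})

test_that("rebound probability is monotone and rejects ragged offsets", {
  expect_gt(rebound_cycle_prob(1, 0.999), rebound_cycle_prob(2, 0.999))
  expect_gt(rebound_cycle_prob(2, 0.999), rebound_cycle_prob(3, 0.999))
  expect_gt(rebound_cycle_prob(2, 0.999), rebound_cycle_prob(2, 0.99))
  expect_error(rebound_cycle_prob(0.75, 0.999, 0.5), "whole number")
})

test_that("weighted subsequent transition probability", {
  expect_equal(weighted_subsequent_tp(c(dmab = 1), c(dmab = 0.033)), 0.033)
  expect_equal(weighted_subsequent_tp(c(a = 0.5, b = 0.5),
                                      c(a = 0.02, b = 0.04)), 0.03)
  expect_equal(weighted_subsequent_tp(c(a = 1), c(a = 0)), 0)
  expect_error(weighted_subsequent_tp(c(a = 0.5, b = 0.5), c(a = 0.02)), "b")
  expect_error(weighted_subsequent_tp(c(a = 0.6, b = 0.6),
                                      c(a = 0.1, b = 0.1)), "sum to 1")
})

test_that("compiled schedules encode the published strategy behaviour", {
  sc <- build_transition_schedule(dmab_c(), 20)
  # on treatment (cycles 1-6): no rebound, improvement 0.108
  expect_equal(sc$p_S_to_D[1:6], rep(0, 6))
  expect_equal(sc$p_S_to_I[1:6], rep(0.108, 6))
  expect_equal(unlist(sc[3, c("p_S_to_D", "p_S_to_I", "p_D_to_I")]),
               c(p_S_to_D = 0, p_S_to_I = 0.108, p_D_to_I = 0.033))
  # after stop: rebound at the calibrated per-cycle value, no improvement
  expect_equal(round(sc$p_S_to_D[7:20], 3), rep(0.822, 14))
  expect_equal(sc$p_S_to_I[7:20], rep(0, 14))
  expect_equal(sc$p_D_to_I, rep(0.033, 20))
  expect_equal(sc$on_treatment, c(rep(TRUE, 6), rep(FALSE, 14)))

  sd <- build_transition_schedule(dmab_d(), 20)
  expect_equal(round(sd$p_S_to_D[1], 3), 0.822)   # rebound from cycle 1
  expect_equal(sd$p_S_to_I, rep(0, 20))           # no improvement ever
  expect_equal(sd$p_D_to_I, rep(0.033, 20))
  expect_false(any(sd$on_treatment))
})

test_that("lifetime treatment never rebounds", {
  sc <- build_transition_schedule(dmab_c(treatment_duration_cycles = "lifetime"),
                                  200)
  expect_equal(sc$p_S_to_D, rep(0, 200))
  expect_true(all(sc$on_treatment))
})

test_that("outgoing probabilities from S never exceed 1", {
  for (seed in 1:25) {
    p <- sample_params(seed)
    for (s in p$strategies) {
      sc <- build_transition_schedule(s, 120)
      expect_true(all(sc$p_S_to_D + sc$p_S_to_I <= 1 + 1e-12))
    }
  }
})

test_that("strategy validation catches bad inputs", {
  expect_error(strategy_spec("x", treatment_duration_cycles = 6,
                             offset_years = 0), "offset_years")
  expect_error(strategy_spec("x", treatment_duration_cycles = 0,
                             tp_D_to_I = 1.5), "\\[0, 1\\]")
  expect_error(strategy_spec("x", treatment_duration_cycles = 0,
                             subsequent_mix = c(a = 0.6, b = 0.6)),
               "sum to 1")
  expect_error(build_transition_schedule(dmab_c(), 0), "at least 1")
})
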