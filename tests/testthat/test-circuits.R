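test_that("default_config carries the documented constants and overrides", {
  cfg <- default_config()
  expect_equal(cfg$weights$mutual, 2)
  expect_equal(cfg$weights$apl_kc, 1.5)
  expect_equal(cfg$weights$da_apl, 3)
  expect_equal(cfg$weights$apl_da, 1.5)
  expect_equal(cfg$gating$th, 3)
  expect_equal(cfg$gating$da_duration, 100)
  expect_equal(cfg$da$peak, 10)
  expect_equal(cfg$da$tau_t, 2)
  expect_equal(cfg$protocol$episode_ms, 1000)
  expect_equal(cfg$protocol$choice_ms, 2000)
  expect_equal(cfg$protocol$subtrial_ms, 100)
  # dotted-path overrides
  cfg2 <- default_config(protocol.dt = 1, weights.mutual = 3)
  expect_equal(cfg2$protocol$dt, 1)
  expect_equal(cfg2$weights$mutual, 3)
  expect_error(default_config(nosuch = 1), "unknown config key")
  expect_error(default_config(weights.nosuch = 1), "unknown config key")
})

test_that("decision_circuit starts symmetric with constant memory weights", {
  m <- decision_circuit()
  expect_s3_class(m, "decision_circuit")
  expect_equal(m$n, 5)
  expect_false(m$trained)
  expect_true(all(coef(m) == 0.5))
  expect_identical(coef(m, "cc"), coef(m, "mb"))
  expect_equal(dim(coef(m)), c(5L, 2L))
  m2 <- decision_circuit(4)
  expect_equal(dim(coef(m2)), c(4L, 2L))
  expect_error(decision_circuit(0))
})

test_that("print, summary and gating switches work", {
  m <- decision_circuit()
  expect_output(print(m), "decision circuit")
  s <- summary(m)
  expect_s3_class(s, "summary.decision_circuit")
  expect_true(s$agree)
  expect_output(print(s), "decision_circuit summary")
  m <- set_nonlinear_gating(m, da_on = FALSE, apl_on = TRUE)
  expect_false(m$da_on)
  expect_true(m$apl_on)
})

test_that("only-APL inhibition can only remove Kenyon-cell spikes", {
  m <- decision_circuit(2)
  cues <- normalize_cues(c(10, 9))
  set.seed(11)
  with_apl <- gain_gate(m, cues, variant = "only-APL")
  set.seed(11)
  without <- gain_gate(m, cues, variant = "linear")
  expect_true(sum(with_apl) <= sum(without))
  expect_true(all(with_apl <= without))
})

test_that("the no-DA-no-APL variant reproduces the linear pathway", {
  # away from the CI = 1 crossover the outcome is deterministic, so the two
  # reduced networks must agree exactly; at the crossover both are fair
  # coin-flip sequences and only agree in distribution
  m <- trained_model(0.8)
  for (ci in c(0.4, 1.6)) {
    set.seed(5)
    pi_lin <- choose(m, encode_pattern("blue", "upright", ci = ci),
                     encode_pattern("green", "inverted", ci = ci),
                     pathway = "linear")$pi
    set.seed(5)
    none <- set_nonlinear_gating(m, FALSE, FALSE)
    pi_none <- choose(none, encode_pattern("blue", "upright", ci = ci),
                      encode_pattern("green", "inverted", ci = ci),
                      pathway = "nonlinear")$pi
    expect_equal(pi_none, pi_lin)
  }
})
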