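test_that("window task: start on the goal column degenerates to one cue", {
  # only the vertical cue is live, so every policy needs exactly the
  # vertical distance in steps
  set.seed(2)
  s <- simulate_window("uniform", start = c(5, 1), trials = 4, grid = 9)
  expect_equal(as.numeric(s), 4)
  expect_equal(unname(attr(s, "steps")), rep(4, 4))
  set.seed(2)
  s2 <- simulate_window("linear", start = c(5, 1), trials = 2, grid = 9,
                        model = decision_circuit(2))
  expect_equal(as.numeric(s2), 4)
})

test_that("window task returns finite means for all policies", {
  m <- decision_circuit(2)
  for (pol in c("uniform", "linear", "nonlinear")) {
    set.seed(7)
    s <- simulate_window(pol, trials = 2, model = m)
    expect_true(is.finite(as.numeric(s)))
    expect_true(all(attr(s, "steps") >= 8))  # manhattan distance lower bound
  }
})

test_that("obstacle probabilities are valid and saliency-ordered", {
  scene <- c(3, 5, 9, 7)
  m <- decision_circuit(4)
  for (v in c("linear", "only-APL", "nonlinear")) {
    set.seed(9)
    p <- simulate_obstacle(scene, variant = v, model = m)
    expect_length(p, 4)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
    # no inversions of the saliency order
    expect_true(all(diff(p[order(scene)]) >= -1e-12))
    expect_equal(which.max(p), which.max(scene))
  }
  expect_error(simulate_obstacle(c(1, 2, 3), model = m))
})

test_that("run_reversal validates the protocol and counts incorrect choices", {
  expect_error(run_reversal(decision_circuit(),
                            protocol = list(list(punished = 2),
                                            list(punished = 2))),
               "must differ")
  # a single block is plain reinforcement learning
  set.seed(1)
  r <- run_reversal(decision_circuit(), protocol = list(list(punished = 2)))
  expect_equal(unique(r$counts$block), 1L)
  expect_true(all(r$counts$incorrect <= 1))
  expect_true(r$model$trained)
  expect_equal(choose(r$model, encode_pattern("green"),
                      encode_pattern("blue"))$pi, 1)
})

test_that("memory survives reversals: single-cue tests follow the last rule", {
  set.seed(6)
  r <- run_reversal(decision_circuit())   # final block: pattern 2 punished
  expect_equal(choose(r$model, encode_pattern("green"),
                      encode_pattern("blue"))$pi, 1)
  expect_equal(choose(r$model, encode_pattern(shape = "upright"),
                      encode_pattern(shape = "inverted"))$pi, 1)
})
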