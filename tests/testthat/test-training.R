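test_that("punish_update depresses only the chosen column of active inputs", {
  m <- decision_circuit()
  m$W_cc[] <- 5
  m$W_mb[] <- 5
  trace <- list(t_pun = 0, da_peak = 10, tau_t = 2)
  m2 <- punish_update(m, trace, active_inputs = c(2, 4),
                      chosen_behavior = 1, t = 0)
  # cumulative decrement ~ DA_peak = 10, clipped at w_min = 0
  expect_equal(unname(m2$W_cc[c(2, 4), 1]), c(0, 0))
  # inactive rows and the non-chosen column untouched
  expect_equal(unname(m2$W_cc[c(1, 3, 5), 1]), rep(5, 3))
  expect_equal(unname(m2$W_cc[, 2]), rep(5, 5))
  expect_identical(m2$W_cc, m2$W_mb)
  # no live trace: no change
  expect_identical(punish_update(m, NULL, c(1), 1, 0)$W_cc, m$W_cc)
})

test_that("train_pattern logs a well-formed episode and learns from it", {
  set.seed(1)
  m <- decision_circuit()
  fit <- train_pattern(m, encode_pattern("blue", "inverted"),
                       encode_pattern("green", "upright"), punished = TRUE)
  ep <- fit$episode
  expect_true(all(c("pattern", "chosen", "punished_pattern",
                    "punishment_applied", "t_pun", "decided", "s1", "s2")
                  %in% names(ep)))
  expect_true(ep$chosen %in% 1:2)
  # the punishment invariant: applied only on the wrong choice
  expect_equal(ep$punishment_applied, ep$chosen == 1)
  expect_identical(fit$model$W_cc, fit$model$W_mb)
  # weights stay inside the bounds
  expect_true(all(fit$model$W_cc >= 0 & fit$model$W_cc <= 10))
})

test_that("train_task learns each pattern within one punished episode", {
  for (s in 1:5) {
    set.seed(s)
    m <- train_task(decision_circuit(),
                    safe = encode_pattern("green", "upright"),
                    punished = encode_pattern("blue", "inverted"))
    expect_true(m$trained)
    log <- m$log
    pun_per_pattern <- tapply(log$punishment_applied, log$pattern, sum)
    expect_true(all(pun_per_pattern <= 1))
    # learning fixed point: a further epoch produces no punishment
    m2 <- train_task(m, safe = encode_pattern("green", "upright"),
                     punished = encode_pattern("blue", "inverted"))
    extra <- utils::tail(m2$log, 2)
    expect_false(any(extra$punishment_applied))
  }
})

test_that("epochs = 0 leaves the model unchanged", {
  m <- decision_circuit()
  m0 <- train_task(m, safe = encode_pattern("green", "upright"),
                   punished = encode_pattern("blue", "inverted"), epochs = 0)
  expect_identical(m0$W_cc, m$W_cc)
})

test_that("swapping safe and punished mirrors the learned column sums", {
  set.seed(3)
  a <- train_task(decision_circuit(),
                  safe = encode_pattern("green", "upright"),
                  punished = encode_pattern("blue", "inverted"))
  set.seed(3)
  b <- train_task(decision_circuit(),
                  safe = encode_pattern("blue", "inverted"),
                  punished = encode_pattern("green", "upright"))
  # exchanged up to the never-reinforced residual (initial weight 0.5/row)
  ga <- colSums(a$W_cc[c(2, 4), ])   # green/upright rows
  gb <- colSums(b$W_cc[c(2, 4), ])
  expect_lt(max(abs(ga - rev(gb))), 1.1)
  ba <- colSums(a$W_cc[c(3, 5), ])   # blue/inverted rows
  bb <- colSums(b$W_cc[c(3, 5), ])
  expect_lt(max(abs(ba - rev(bb))), 1.1)
})

test_that("training drives the correct memory columns to saturation", {
  m <- trained_model()
  W <- coef(m)
  # safe pattern rows favour behaviour 1, punished rows favour behaviour 2
  expect_true(all(W[c(2, 4), 1] > 5))
  expect_true(all(W[c(3, 5), 2] > 5))
  expect_true(all(W[c(2, 4), 2] < 1))
  expect_true(all(W[c(3, 5), 1] < 1))
})
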