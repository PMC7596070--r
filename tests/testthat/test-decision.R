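test_that("preference_index is the normalised count difference", {
  expect_equal(preference_index(15, 5), 0.5)
  expect_equal(preference_index(20, 0), 1)
  expect_equal(preference_index(0, 20), -1)
  expect_equal(preference_index(7, 7), 0)
  expect_error(preference_index(0, 0))
  expect_error(preference_index(-1, 2))
})

test_that("the conflict monitor applies the three routing rules", {
  m <- trained_model()
  # (1) single cue: clear memory difference -> linear
  f1 <- competitive_filter(encode_pattern("green"), encode_pattern("blue"))
  expect_equal(as.character(conflict_monitor(m, f1)), "linear")
  # (2) two non-conflicting cues -> linear
  f2 <- competitive_filter(encode_pattern("green", "upright"),
                           encode_pattern("blue", "inverted"))
  expect_equal(as.character(conflict_monitor(m, f2)), "linear")
  # (3) reversed cues (dilemma): |s1 - s2| <= th -> nonlinear
  f3 <- competitive_filter(encode_pattern("blue", "upright"),
                           encode_pattern("green", "inverted"))
  cm <- conflict_monitor(m, f3)
  expect_equal(as.character(cm), "nonlinear")
  expect_true(abs(attr(cm, "s1") - attr(cm, "s2")) <= m$config$gating$th)
})

test_that("cue_probabilities normalises counts scale-invariantly", {
  expect_equal(cue_probabilities(c(30, 10)), c(0.75, 0.25))
  expect_equal(cue_probabilities(c(0, 0, 7)), c(0, 0, 1))
  expect_equal(sum(cue_probabilities(c(3, 9, 1, 8))), 1)
  expect_equal(cue_probabilities(c(4, 12)), cue_probabilities(c(1, 3)))
  expect_error(cue_probabilities(c(0, 0)))
})

test_that("choose reads out the trained preference and flags degeneracy", {
  m <- trained_model()
  set.seed(1)
  o <- choose(m, encode_pattern("green"), encode_pattern("blue"))
  expect_s3_class(o, "decision_outcome")
  expect_equal(o$pathway, "linear")
  expect_equal(o$t1 + o$t2, 20L)         # 2000 ms / 100 ms sub-trials
  expect_equal(o$pi, 1)
  expect_output(print(o), "PI = 1")
  # identical patterns filter to nothing: undecided, not guessed
  u <- choose(m, encode_pattern("green", "upright"),
              encode_pattern("green", "upright"))
  expect_true(u$undecided)
  expect_true(is.na(u$pi))
  # predict() is the choice phase
  set.seed(1)
  p <- predict(m, encode_pattern("green"), encode_pattern("blue"))
  expect_equal(p$pi, o$pi)
})

test_that("outcome_json serialises bare numbers", {
  m <- trained_model()
  set.seed(1)
  o <- choose(m, encode_pattern("green"), encode_pattern("blue"))
  j <- jsonlite::fromJSON(outcome_json(o))
  expect_equal(j$pi, 1)
  expect_equal(j$t1 + j$t2, 20)
})

test_that("gain_gate counts are per-cue and symmetric for equal cues", {
  m <- decision_circuit(2)
  set.seed(4)
  ct <- gain_gate(m, normalize_cues(c(10, 10)), variant = "nonlinear")
  expect_length(ct, 2)
  expect_true(all(ct > 0))
  # equal saliencies: no systematic asymmetry (tolerance for jitter noise)
  expect_lt(abs(ct[1] - ct[2]) / sum(ct), 0.2)
  # linear counts are deterministic in the stimulus, monotone in saliency
  lc <- gain_gate(decision_circuit(4), normalize_cues(c(3, 5, 9, 7)),
                  variant = "linear")
  expect_equal(order(lc), order(c(3, 5, 9, 7)))
})

test_that("spike_record returns an ordered spike table", {
  m <- trained_model()
  sr <- spike_record(m, encode_pattern("green", "upright"), duration = 100,
                     seed = 1)
  expect_s3_class(sr, "spike_record")
  expect_true(all(c("time_ms", "population", "neuron_id") %in% names(sr)))
  expect_true(!is.unsorted(sr$time_ms))
  expect_true(all(sr$population %in% c("visual", "cc_in", "cc_out", "kc",
                                       "mbon", "apl", "da")))
  f <- tempfile(fileext = ".csv")
  write_spike_record(sr, f)
  expect_equal(nrow(utils::read.csv(f)), nrow(sr))
})
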