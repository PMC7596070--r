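test_that("encode_pattern produces the published channel vectors", {
  expect_equal(unname(encode_pattern("green", "upright")$channels),
               c(0, 10, 0, 10, 0))
  expect_equal(unname(encode_pattern("blue", "inverted")$channels),
               c(0, 0, 10, 0, 10))
  # colour intensity scales only the colour channels
  expect_equal(unname(encode_pattern("green", "upright", ci = 0.8)$channels),
               c(0, 8, 0, 10, 0))
  # white lights all three colour channels
  expect_equal(unname(encode_pattern("white", "upright")$channels),
               c(10, 10, 10, 10, 0))
  expect_equal(unname(encode_pattern("none", "inverted")$channels),
               c(0, 0, 0, 0, 10))
  expect_error(encode_pattern("red", "upright"))
  expect_error(encode_pattern("green", "upright", ci = -1))
})

test_that("competitive_filter is the rectified channel difference", {
  a <- encode_pattern("green", "upright")
  b <- encode_pattern("blue", "inverted")
  expect_equal(unname(competitive_filter(a, b)), c(0, 10, 0, 10, 0))
  # shared channels cancel: white vs white leaves only the shape cue
  w1 <- encode_pattern("white", "upright")
  w2 <- encode_pattern("white", "inverted")
  expect_equal(unname(competitive_filter(w1, w2)), c(0, 0, 0, 10, 0))
  # idempotent once the supports are disjoint
  f <- competitive_filter(a, b)
  expect_equal(competitive_filter(f, rep(0, 5)), f)
  expect_equal(unname(competitive_filter(f, b$channels)), unname(f))
})

test_that("normalize_cues maps to [1, 20], preserving order", {
  expect_equal(normalize_cues(c(0, 5, 10)), c(1, 10.5, 20))
  expect_equal(normalize_cues(c(7, 7, 7)), c(20, 20, 20))
  x <- normalize_cues(c(2, 9, 4, 6))
  expect_true(all(x >= 1 & x <= 20))
  expect_equal(order(x), order(c(2, 9, 4, 6)))
  expect_error(normalize_cues(c(0, 0)))
  expect_error(normalize_cues(c(-1, 3)))
})

test_that("pattern_library is addressable by name", {
  lib <- pattern_library()
  expect_true(all(c("upright-green-T", "inverted-blue-T",
                    "upright-white-T") %in% names(lib)))
  expect_equal(unname(lib[["inverted-blue-T"]]$channels), c(0, 0, 10, 0, 10))
  lib8 <- pattern_library(ci = 0.8)
  expect_equal(unname(lib8[["upright-green-T"]]$channels), c(0, 8, 0, 10, 0))
})
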