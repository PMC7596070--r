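test_that("run_experiment rejects unknown names", {
  expect_error(run_experiment("nope"), "unknown experiment name")
})

test_that("run_experiment writes csv, summary json and log", {
  od <- file.path(tempdir(), "dd-exp-test")
  r <- run_experiment("single_cue", seed = 1, out_dir = od)
  expect_equal(r$summary$pi_safe, 1)
  expect_equal(r$summary$pi_punished, -1)
  expect_true(all(file.exists(r$files)))
  j <- jsonlite::read_json(file.path(od, "single_cue_summary.json"))
  expect_equal(j$schema, "drosdecide-summary-1")
  expect_equal(j$experiment, "single_cue")
  expect_equal(j$pi_safe, 1)
  d <- utils::read.csv(file.path(od, "single_cue.csv"))
  expect_equal(nrow(d), 2)
  # same seed reproduces the same table
  r2 <- run_experiment("single_cue", seed = 1)
  expect_equal(r2$data, r$data)
})

test_that("spike_train_compare summarises the three variants", {
  r <- run_experiment("spike_train_compare", seed = 2)
  expect_equal(sort(unique(r$data$variant)),
               c("linear", "nonlinear", "only-APL"))
  expect_equal(r$summary$saliencies, c(20, 1 + 19 * 9 / 10))
  expect_true(r$summary$ratio$nonlinear > r$summary$ratio$linear)
})

test_that("two_cue experiment reproduces colour and shape learning", {
  r <- run_experiment("two_cue", seed = 1)
  expect_equal(r$summary$trained_pair, 1)
  expect_equal(r$summary$color, 1)
  expect_equal(r$summary$shape, 1)
})

test_that("generate_fixtures writes small text files", {
  d <- file.path(tempdir(), "dd-fixtures")
  files <- generate_fixtures(seed = 1, dir = d)
  expect_length(files, 3)
  expect_true(all(file.exists(files)))
  sizes <- file.size(files)
  expect_true(all(sizes <= 64 * 1024))
  expect_true(sum(sizes) <= 256 * 1024)
  pats <- utils::read.csv(files[1])
  expect_true(nrow(pats) > 0)
  # deterministic under the seed
  d2 <- file.path(tempdir(), "dd-fixtures2")
  files2 <- generate_fixtures(seed = 1, dir = d2)
  expect_identical(readLines(files[3]), readLines(files2[3]))
})

test_that("the CLI script is installed and well-formed", {
  cli <- system.file("exec", "drosdecide", package = "drosdecide")
  expect_true(nzchar(cli) && file.exists(cli))
  first <- readLines(cli, n = 1)
  expect_match(first, "^#!.*Rscript")
})
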