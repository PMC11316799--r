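test_that("the registry computes the reference transformations", {
  fns <- builtin_functions()
  expect_identical(fns$duplicate$fn(c(1L, 3L, 9L, 7L)),
                   c(1L, 1L, 3L, 3L, 9L, 9L, 7L, 7L))
  expect_identical(fns$swap_replace_cut_take$fn(c(6L, 7L, 1L, 3L, 2L, 0L, 8L, 9L, 4L, 5L)),
                   c(1L, 7L, 6L, 4L, 2L, 8L))
  expect_identical(fns$identity$fn(integer(0)), integer(0))
  expect_identical(fns$reverse$fn(c(1L, 2L, 3L)), c(3L, 2L, 1L))
  expect_identical(fns$remove_every_other$fn(c(1L, 2L, 3L, 4L, 5L)), c(1L, 3L, 5L))
  expect_identical(fns$maximum$fn(c(4L, 9L, 2L)), 9L)
  expect_identical(fns$sum$fn(c(4L, 9L, 2L)), 15L)
  expect_identical(fns$head$fn(c(7L, 1L)), 7L)
  expect_identical(fns$tail$fn(c(7L, 1L)), 1L)
  expect_identical(fns$take_3$fn(c(5L, 6L, 7L, 8L)), c(5L, 6L, 7L))
  expect_identical(fns$cut_2$fn(c(5L, 6L, 7L)), c(5L, 7L))
  expect_identical(fns$replace_2_9$fn(c(5L, 6L, 7L)), c(5L, 9L, 7L))
  expect_identical(fns$swap_1_3$fn(c(5L, 6L, 7L)), c(7L, 6L, 5L))
  expect_error(get_function("no_such"), "unknown")
})

test_that("set scoring favors varied sets and penalizes identity pairs", {
  fn <- get_function("identity")
  flat <- rep(list(list(input = c(1L, 2L), output = c(1L, 2L))), 11L)
  varied <- lapply(1:11, function(i)
    list(input = seq_len(i %% 6L + 1L) * 3L, output = seq_len(i %% 6L + 1L) * 3L))
  expect_lt(score_example_set(fn, flat), score_example_set(fn, varied))
  # the unique-output term counts distinct outputs
  fn2 <- get_function("duplicate")
  two_out <- c(rep(list(list(input = c(1L), output = c(1L, 1L))), 6L),
               rep(list(list(input = c(2L), output = c(2L, 2L))), 5L))
  eleven_out <- lapply(0:10, function(v) list(input = c(v), output = c(v, v)))
  expect_lt(score_example_set(fn2, two_out), score_example_set(fn2, eleven_out))
  # permutation invariance
  set.seed(81)
  s <- generate_example_set(fn2, n_candidates = 5L)
  expect_equal(score_example_set(fn2, s), score_example_set(fn2, s[sample.int(11L)]))
})

test_that("generated example sets respect the domain bounds", {
  set.seed(82)
  bad <- 0L
  for (fid in c("duplicate", "swap_replace_cut_take", "sum", "take_3")) {
    fn <- get_function(fid)
    for (rep in 1:25) {
      s <- generate_example_set(fn, n_candidates = 1L)
      if (length(s) != 11L) bad <- bad + 1L
      for (pr in s) {
        ok <- length(pr$input) <= 15L && length(pr$output) <= 15L &&
          all(pr$input >= 0L & pr$input <= 99L) &&
          all(is.na(pr$output) | (pr$output >= 0L & pr$output <= 99L)) &&
          identical(pr$output, as.integer(fn$fn(pr$input))) &&
          (is.null(fn$valid) || isTRUE(fn$valid(pr$input)))
        if (!ok) bad <- bad + 1L
      }
    }
  }
  expect_identical(bad, 0L)
})

test_that("generation and ordering are reproducible under a fixed seed", {
  fn <- get_function("duplicate")
  set.seed(83); a <- generate_example_set(fn, n_candidates = 20L)
  set.seed(83); b <- generate_example_set(fn, n_candidates = 20L)
  expect_identical(a, b)
  set.seed(84); oa <- order_examples(fn, a, n_orderings = 50L)
  set.seed(84); ob <- order_examples(fn, a, n_orderings = 50L)
  expect_identical(oa, ob)
})

test_that("ordering puts a non-identity example first whenever one exists", {
  fn <- get_function("identity")
  set.seed(85)
  # ten identity pairs and one differing pair: the differing pair must lead
  s <- c(rep(list(list(input = c(1L, 2L), output = c(1L, 2L))), 10L),
         list(list(input = c(9L), output = c(8L))))
  for (i in 1:5) {
    o <- order_examples(get_function("duplicate"), s, n_orderings = 300L)
    expect_false(identical(o[[1L]]$input, o[[1L]]$output))
  }
  # n_orderings = 1 keeps the input order
  expect_identical(order_examples(fn, s, n_orderings = 1L), s)
})

test_that("the protocol descriptor enumerates rounds by trials", {
  p <- make_protocol()
  expect_identical(p$n_trials, 110L)
  expect_identical(nrow(p$schedule), 110L)
  expect_identical(make_protocol(1L, 11L)$n_trials, 11L)
  expect_identical(make_protocol(0L, 11L)$n_trials, 0L)
})

test_that("dataset JSON round-trips with deterministic structure", {
  fn <- get_function("duplicate")
  set.seed(86)
  s <- generate_example_set(fn, n_candidates = 3L)
  path <- tempfile(fileext = ".json")
  write_dataset_json(fn, s, path)
  back <- read_dataset_json(path)
  expect_identical(back$function_id, "duplicate")
  expect_identical(length(back$examples), 11L)
  for (i in seq_along(s)) {
    expect_identical(back$examples[[i]]$input, s[[i]]$input)
    expect_identical(back$examples[[i]]$output, s[[i]]$output)
  }
  unlink(path)
})
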