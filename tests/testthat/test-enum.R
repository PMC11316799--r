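test_that("enumeration emits bands in order, without duplicates", {
  g <- grammar()
  nxt <- enumerate_programs(g, enumeration_budget(max_programs = 3000L))
  dls <- c()
  keys <- c()
  repeat {
    item <- nxt()
    if (is.null(item)) break
    dls <- c(dls, item$dl)
    keys <- c(keys, mplearn:::program_key(item$program))
  }
  expect_gte(length(keys), 1000L)
  expect_identical(anyDuplicated(keys), 0L)
  # band ordering: if A's description length is shorter than B's by more
  # than delta, A is emitted before B
  delta <- 1.5
  n <- length(dls)
  later_min <- rev(cummin(rev(dls)))
  expect_true(all(dls[-n] <= later_min[-1] + delta + 1e-9))
})

test_that("description lengths agree with the program prior", {
  g <- grammar()
  nxt <- enumerate_programs(g, enumeration_budget(max_programs = 500L))
  for (i in 1:100) {
    item <- nxt()
    if (is.null(item)) break
    expect_equal(item$dl, -program_log_prior(item$program, g), tolerance = 1e-9)
  }
})

test_that("first_consistent returns a program consistent with all pairs", {
  g <- grammar()
  prs <- list(list(input = c(3L, 1L), output = c(3L, 1L)),
              list(input = c(5L), output = c(5L)))
  hit <- first_consistent(enumerate_programs(g, enumeration_budget(max_programs = 2000L)), prs)
  expect_false(is.null(hit))
  for (pr in prs) {
    expect_identical(evaluate_program(hit$program, pr$input)$value, pr$output)
  }
  # the minimal identity program arrives before any longer consistent one
  expect_identical(mplearn:::program_key(hit$program), "F xs = xs")
  # with no pairs, the very first program is returned
  first <- first_consistent(enumerate_programs(g, enumeration_budget(max_programs = 10L)), list())
  expect_identical(first$steps, 1L)
  # contradictory pairs admit no program
  clash <- list(list(input = c(1L), output = c(1L)),
                list(input = c(1L), output = c(2L)))
  expect_null(first_consistent(enumerate_programs(g, enumeration_budget(max_programs = 300L)), clash))
})

test_that("the selected head program generalizes to held-out inputs", {
  g <- grammar()
  prs <- list(list(input = c(3L, 1L), output = 3L),
              list(input = c(7L, 2L, 5L), output = 7L),
              list(input = c(9L), output = 9L))
  hit <- first_consistent(enumerate_programs(g, enumeration_budget(max_programs = 20000L)), prs)
  expect_false(is.null(hit))
  set.seed(71)
  for (i in 1:50) {
    x <- sample(0:99, sample.int(15L, 1L), replace = TRUE)
    expect_identical(evaluate_program_fast(hit$program, x)$value, x[1L])
  }
})

test_that("win-stay/lose-shift keeps a correct program and re-selects after errors", {
  g <- grammar()
  # identity holds for the first trials, then the data contradict it
  pairs <- list(list(input = c(2L, 4L), output = c(2L, 4L)),
                list(input = c(5L), output = c(5L)),
                list(input = c(1L, 2L), output = c(1L)))
  mk <- function() enumerate_programs(g, enumeration_budget(max_programs = 2000L))
  state <- list(program = NULL, pairs = list())
  out1 <- win_stay_predict(state, pairs[[1L]]$input, mk)
  expect_identical(out1$prediction, c(2L, 4L))       # first consistent: identity
  state <- out1$state
  state$pairs <- pairs[1]
  committed <- mplearn:::program_key(state$program)
  out2 <- win_stay_predict(state, pairs[[2L]]$input, mk)   # stayed: was correct
  expect_identical(mplearn:::program_key(out2$state$program), committed)
  state <- out2$state
  state$pairs <- pairs[1:2]
  out3 <- win_stay_predict(state, pairs[[3L]]$input, mk)
  # prediction [1, 2] is wrong; the runner clears the commitment and the
  # next selection must fit all three pairs
  state <- out3$state
  state$pairs <- pairs
  state$program <- NULL
  out4 <- win_stay_predict(state, c(9L, 9L), mk)
  if (!is.null(out4$state$program)) {
    for (pr in pairs) {
      expect_identical(evaluate_program_fast(out4$state$program, pr$input)$value,
                       as.integer(pr$output))
    }
  }
})

test_that("the enumeration baseline acquires the identity function online", {
  set.seed(72)
  s <- generate_example_set(get_function("identity"), n_candidates = 30L)
  rr <- enum_online_run(s, enumeration_budget(max_programs = 2000L))
  expect_length(rr$trials, 11L)
  expect_gte(mean_accuracy(list(rr)), 10 / 11)
})
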