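test_that("MemorizeAll adds the data as ground rules, idempotently", {
  d <- dataset(f_printed_pairs()[1])
  p <- mp_memorize_all(program(), d)
  expect_identical(print_program(p), "F [1, 3, 9, 7] = [1, 1, 3, 3, 9, 9, 7, 7]\n")
  expect_identical(print_program(mp_memorize_all(program(), dataset(list()))),
                   print_program(program()))
  # applying twice equals applying once: the pairs are already entailed
  expect_identical(print_program(mp_memorize_all(p, d)), print_program(p))
})

test_that("Memorize adds a single indexed pair and composes to MemorizeAll", {
  d <- dataset(f_printed_pairs())
  p1 <- mp_memorize(program(), d, 1L)
  expect_identical(length(p1$rules), 1L)
  expect_null(mp_memorize(program(), d, 9L))
  step <- program()
  for (i in seq_along(d)) step <- mp_memorize(step, d, i)
  expect_identical(print_program(step), print_program(mp_memorize_all(program(), d)))
})

test_that("Recurse unrolls ground rules at the consistent arity", {
  d <- dataset(f_printed_pairs()[1])
  p <- mp_memorize_all(program(), d)
  expect_identical(mplearn:::recurse_legal_ks(p), 2L)
  p2 <- mp_recurse(p, 1L)
  txt <- print_program(p2)
  expect_match(txt, "F \\[1, 3, 9, 7\\] = \\[1, 1 \\| \\(F \\[3, 9, 7\\]\\)\\]", all = FALSE)
  expect_match(txt, "F \\[7\\] = \\[7, 7 \\| \\(F \\[\\]\\)\\]", all = FALSE)
  expect_match(txt, "F \\[\\] = \\[\\]", all = FALSE)
  # unrolled rules still compute the memorized pair
  expect_identical(evaluate_program(p2, c(1L, 3L, 9L, 7L))$value,
                   c(1L, 1L, 3L, 3L, 9L, 9L, 7L, 7L))
  # the empty pair unrolls to the base rule alone
  p0 <- mp_recurse(mp_memorize_all(program(), dataset(list(list(input = integer(0), output = integer(0))))), 1L)
  expect_identical(print_program(p0), "F [] = []\n")
  # no k satisfies 1 = 2k: inapplicable
  bad <- mp_memorize_all(program(), dataset(list(list(input = c(1L, 2L), output = 5L))))
  expect_identical(length(mplearn:::recurse_legal_ks(bad)), 0L)
  expect_null(mp_recurse(bad, 1L))
})

test_that("Delete removes the indexed rule", {
  d <- dataset(f_printed_pairs())
  p <- mp_memorize_all(program(), d)
  expect_identical(length(mp_delete(p, 2L)$rules), 2L)
  expect_identical(length(mp_delete(mp_memorize(program(), d, 1L), 1L)$rules), 0L)
  expect_null(mp_delete(p, 7L))
})

test_that("Variable generalizes all occurrences of a chosen lhs subterm", {
  p <- parse_program("F [4, 1] = [4, 4]")
  opts <- mplearn:::variable_options(p)
  # pick the option replacing the numeral 4
  sel <- which(vapply(opts, function(o) identical(o$sub, 4L), TRUE))
  expect_length(sel, 1L)
  p2 <- mp_variable(p, sel)
  expect_identical(print_program(p2), "F [x1, 1] = [x1, x1]\n")
  # selections that strand rhs variables are inapplicable
  p3 <- parse_program("F [5 | y] = [5 | y]")
  opts3 <- mplearn:::variable_options(p3)
  sel3 <- which(vapply(opts3, function(o) identical(o$sub, parse_term("[5 | y]")), TRUE))
  # replacing the whole argument would strand nothing here (it appears on
  # both sides), so instead check an out-of-range choice fails
  expect_null(mp_variable(p3, length(opts3) + 1L))
})

test_that("Compose factors an rhs subterm into a fresh symbol, preserving behavior", {
  d <- dataset(f_printed_pairs())
  p <- f_reference_program()
  opts <- mplearn:::compose_options(p)
  expect_gt(length(opts), 0L)
  for (psi in seq_along(opts)) {
    p2 <- mp_compose(p, psi)
    expect_false(is.null(p2))
    for (pr in d) {
      expect_identical(evaluate_program(p2, pr$input)$value, pr$output)
    }
  }
  # root position gives a trivial wrapper rule
  p2 <- mp_compose(p, 1L)
  expect_identical(length(p2$rules), 3L)
})

test_that("Subproblem extracts an aligned suffix pair into a fresh symbol", {
  d <- dataset(f_printed_pairs()[3])   # ([9, 2], [9, 9, 2, 2])
  p <- mp_memorize_all(program(), d)
  opts <- mplearn:::subproblem_options(p)
  expect_identical(length(opts), 2L * 4L)
  for (psi in seq_along(opts)) {
    p2 <- mp_subproblem(p, psi)
    expect_false(is.null(p2))
    expect_identical(evaluate_program(p2, c(9L, 2L))$value, c(9L, 9L, 2L, 2L))
  }
})

test_that("AntiUnify folds similar rules and keeps the base rule", {
  d <- dataset(f_printed_pairs()[1])
  p2 <- mp_recurse(mp_memorize_all(program(), d), 1L)
  p3 <- mp_anti_unify(p2)
  expect_identical(print_program(p3), "F [x1 | x2] = [x1, x1 | (F x2)]\nF [] = []\n")
  # two identical rules fold to that rule
  twin <- parse_program("F [1] = [2]\nF [1] = [2]")
  expect_identical(print_program(mp_anti_unify(twin)), "F [1] = [2]\n")
  # fewer than two same-head rules: inapplicable
  expect_null(mp_anti_unify(program()))
  expect_null(mp_anti_unify(parse_program("F [1] = [2]")))
})

test_that("AntiUnify on the memorized composition data recovers the positional rule", {
  d <- dataset(g_printed_pairs())
  p <- mp_anti_unify(mp_memorize_all(program(), d))
  expect_identical(print_program(p),
                   "F [x1, x2, x3, x4, x5, x6, x7 | x8] = [x3, x2, x1, 4, x5, x7]\n")
  ref <- g_reference_program()
  set.seed(41)
  for (i in 1:20) {
    x <- sample(0:99, sample(7:15, 1L), replace = TRUE)
    expect_identical(evaluate_program(p, x)$value, evaluate_program(ref, x)$value)
  }
})

test_that("metaprogram reduction threads steps and enforces determinism", {
  d <- dataset(f_online_pairs()[1:3])
  mp <- metaprogram(list(list(name = "MemorizeAll"),
                         list(name = "Recurse", psi = 1L),
                         list(name = "AntiUnify")))
  p <- reduce_metaprogram(mp, d)
  expect_false(is.null(p))
  expect_true(is_deterministic(p))
  ref <- f_reference_program()
  set.seed(42)
  for (i in 1:20) {
    x <- sample(0:99, sample.int(8L, 1L) - 1L, replace = TRUE)
    expect_identical(evaluate_program(p, x)$value, evaluate_program(ref, x)$value)
  }
  # the empty metaprogram reduces to its base
  expect_identical(print_program(reduce_metaprogram(metaprogram(), d)),
                   print_program(program()))
  # out-of-range psi fails
  bad <- metaprogram(list(list(name = "Memorize", psi = 99L)))
  expect_null(reduce_metaprogram(bad, d))
  # inconsistent unrolled rules are rejected as nondeterministic
  clash <- dataset(list(list(input = c(1L), output = c(5L)),
                        list(input = c(1L, 1L), output = c(5L, 6L))))
  mpc <- metaprogram(list(list(name = "MemorizeAll"), list(name = "Recurse", psi = 1L)))
  expect_null(reduce_metaprogram(mpc, clash))
})

test_that("reduction is deterministic, bit-for-bit under canonical printing", {
  d <- dataset(f_online_pairs()[1:4])
  mp <- metaprogram(list(list(name = "MemorizeAll"),
                         list(name = "Recurse", psi = 1L),
                         list(name = "AntiUnify")))
  a <- reduce_metaprogram(mp, d)
  b <- reduce_metaprogram(mp, d)
  expect_identical(print_program(a), print_program(b))
})

test_that("metaprogram text round-trips", {
  mp <- metaprogram(list(list(name = "AntiUnify"),
                         list(name = "Recurse", psi = 2L),
                         list(name = "MemorizeAll")))
  txt <- print_metaprogram(mp)
  expect_identical(print_metaprogram(parse_metaprogram(txt)), txt)
  expect_identical(print_metaprogram(parse_metaprogram("(MemorizeAll ε)")),
                   "(MemorizeAll ε)")
})

test_that("every metaprimitive output satisfies the rule invariants", {
  set.seed(43)
  d <- dataset(f_online_pairs()[1:4])
  g <- grammar()
  bad <- 0L
  for (i in 1:120) {
    mp <- sample_metaprogram(g, d)
    if (is.null(mp)) next
    p <- reduce_metaprogram(mp, d)
    if (is.null(p)) next
    for (r in p$rules) {
      if (length(setdiff(mplearn:::term_vars(r$rhs), mplearn:::term_vars(r$lhs))) ||
          !is.list(r$lhs)) bad <- bad + 1L
    }
    if (!is_deterministic(p)) bad <- bad + 1L
  }
  expect_identical(bad, 0L)
})
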