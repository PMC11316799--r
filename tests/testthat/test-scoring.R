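test_that("pair likelihood matches literal summation on the worked cases", {
  prm <- likelihood_params()
  # exact match: the dominant term is (1-eta)^2
  ll <- pair_log_likelihood(c(1L, 2L, 3L), c(1L, 2L, 3L), prm)
  expect_lt(abs(ll - brute_pair_likelihood(c(1L, 2L, 3L), c(1L, 2L, 3L))), 1e-12)
  expect_equal(ll, 2 * log1p(-1e-6), tolerance = 1e-6)
  # empty prediction vs empty observation: the single i = 0 term
  expect_lt(abs(pair_log_likelihood(integer(0), integer(0), prm) - log1p(-1e-6)), 1e-12)
  # first elements differ: only i = 0 survives
  expect_equal(pair_log_likelihood(c(5L, 2L), c(1L, 2L), prm),
               2 * log(1e-6) + 2 * (log(1e-6) - log(100)) + log1p(-1e-6),
               tolerance = 1e-9)
  # failed evaluations contribute the i = 0 term with |pred| = 0
  expect_equal(pair_log_likelihood(list(ok = FALSE, value = NULL), c(1L, 2L), prm),
               2 * (log(1e-6) - log(100)) + log1p(-1e-6), tolerance = 1e-9)
})

test_that("pair likelihood agrees with the brute-force oracle on random pairs", {
  set.seed(51)
  prm <- likelihood_params()
  worst <- 0
  for (i in 1:300) {
    np <- sample.int(8L, 1L) - 1L
    no <- sample.int(8L, 1L) - 1L
    shared <- sample.int(min(np, no) + 1L, 1L) - 1L
    obs <- sample(0:9, no, replace = TRUE)
    pred <- c(utils::head(obs, shared), sample(10:19, max(0L, np - shared), replace = TRUE))
    a <- pair_log_likelihood(pred, obs, prm)
    b <- brute_pair_likelihood(pred, obs)
    if (is.finite(a) || is.finite(b)) worst <- max(worst, abs(a - b))
  }
  # the stated agreement is absolute on the log scale
  expect_lt(worst, 1e-12)
})

test_that("likelihood is monotone in the shared prefix", {
  set.seed(52)
  prm <- likelihood_params()
  mono <- vapply(1:100, function(i) {
    obs <- sample(0:99, sample(2:8, 1L), replace = TRUE)
    lls <- vapply(0:length(obs), function(k) {
      pred <- c(utils::head(obs, k), sample(0:99, length(obs) - k, replace = TRUE) + 100L)
      pred <- pred[seq_len(length(obs))]
      pred[pred > 99L] <- NA_integer_   # guaranteed mismatch after the prefix
      pair_log_likelihood(pred, obs, prm)
    }, 0)
    all(diff(lls) >= -1e-12)
  }, TRUE)
  expect_true(all(mono))
})

test_that("dataset likelihood multiplies pairs (and can sum them instead)", {
  p <- f_reference_program()
  d <- dataset(f_printed_pairs())
  prm <- likelihood_params()
  per_pair <- vapply(d, function(pr)
    pair_log_likelihood(evaluate_program(p, pr$input), pr$output, prm), 0)
  expect_equal(data_log_likelihood(p, d, prm), sum(per_pair), tolerance = 1e-9)
  prs <- likelihood_params(per_pair = "sum")
  m <- max(per_pair)
  expect_equal(data_log_likelihood(p, d, prs), m + log(sum(exp(per_pair - m))),
               tolerance = 1e-9)
  expect_identical(data_log_likelihood(p, dataset(list()), prm), 0)
  # a perfectly predicted extra pair contributes about ln((1-eta)^2)
  d4 <- dataset(c(f_printed_pairs(), list(list(input = c(5L), output = c(5L, 5L)))))
  expect_equal(data_log_likelihood(p, d4, prm) - data_log_likelihood(p, d, prm),
               2 * log1p(-1e-6), tolerance = 1e-5)
})

test_that("metaprogram prior follows the derivation and decreases per step", {
  g <- grammar()
  d <- dataset(f_printed_pairs())
  lv <- g$n_level_options
  expect_equal(mp_log_prior(metaprogram("MemorizeAll"), g, d), -2 * log(lv))
  expect_equal(mp_log_prior(metaprogram(), g, d), -log(lv))
  mp3 <- metaprogram(list(list(name = "MemorizeAll"), list(name = "Recurse", psi = 1L),
                          list(name = "AntiUnify")))
  # four levels plus one psi over a single legal option
  expect_equal(mp_log_prior(mp3, g, d), -4 * log(lv) - log(1))
  # each extra step strictly decreases the prior
  expect_lt(mp_log_prior(mp3, g, d), mp_log_prior(metaprogram("MemorizeAll"), g, d))
  # irreducible metaprograms have zero mass
  expect_identical(mp_log_prior(metaprogram(list(list(name = "Delete", psi = 1L))), g, d), -Inf)
})

test_that("program prior favors the empty and simple programs", {
  g <- grammar()
  expect_equal(program_log_prior(program(), g), -log(2))
  pf <- f_reference_program()
  pg <- g_reference_program()
  expect_lt(program_log_prior(pf, g), program_log_prior(program(), g))
  # the positional six-element rule is more complex than the duplication rule
  expect_lt(program_log_prior(pg, g), program_log_prior(pf, g))
  # memorizing more data lowers the prior monotonically
  d <- dataset(f_printed_pairs())
  lp <- vapply(1:3, function(k)
    program_log_prior(mp_memorize_all(program(), dataset(d[seq_len(k)])), g), 0)
  expect_true(all(diff(lp) < 0))
})

test_that("the combined prior is the average of the two log priors", {
  expect_identical(combined_log_prior(-10, -20), -15)
  expect_identical(combined_log_prior(-10, -20, mode = "pm"), -10)
  expect_identical(combined_log_prior(-10, -20, mode = "pp"), -20)
  # geometric mean on the natural scale
  expect_equal(exp(combined_log_prior(log(0.1), log(0.4))), sqrt(0.1 * 0.4))
})

test_that("posterior assembly: reduction failure propagates, data order is irrelevant", {
  g <- grammar()
  d <- dataset(f_printed_pairs())
  mp3 <- metaprogram(list(list(name = "MemorizeAll"), list(name = "Recurse", psi = 1L),
                          list(name = "AntiUnify")))
  sc <- score_hypothesis(mp3, d, g)
  expect_true(sc$ok)
  expect_equal(sc$lpost, sc$llik + (sc$lpm + sc$lpp) / 2, tolerance = 1e-12)
  # empty data: prior only
  sc0 <- score_hypothesis(mp3, dataset(list()), g)
  expect_identical(sc0$ok, FALSE)   # Recurse has no ground rules without data
  scm0 <- score_hypothesis(metaprogram("MemorizeAll"), dataset(list()), g)
  expect_equal(scm0$lpost, scm0$lprior)
  # irreducible hypothesis scores -Inf
  bad <- score_hypothesis(metaprogram(list(list(name = "Delete", psi = 1L))), d, g)
  expect_identical(bad$lpost, -Inf)
  # dataset order does not change the score
  sc_perm <- score_hypothesis(mp3, dataset(d[c(3, 1, 2)]), g)
  expect_equal(sc$llik, sc_perm$llik, tolerance = 1e-9)
})

test_that("with three pairs the structured metaprogram beats pure memorization", {
  g <- grammar()
  d <- dataset(f_printed_pairs())
  mp3 <- metaprogram(list(list(name = "MemorizeAll"), list(name = "Recurse", psi = 1L),
                          list(name = "AntiUnify")))
  mem <- metaprogram("MemorizeAll")
  expect_gt(score_hypothesis(mp3, d, g)$lpost, score_hypothesis(mem, d, g)$lpost)
})

test_that("prior mass within the truncation bounds stays below one", {
  # exhaustively enumerable truncated space: metaprograms of at most two
  # steps over the {MemorizeAll, Delete} grammar with an ε base
  g <- grammar(mp_names = c("MemorizeAll", "Delete"), program_base = FALSE)
  d <- dataset(list(list(input = c(1L), output = c(2L)),
                    list(input = c(3L), output = c(4L))))
  mps <- enumerate_toy_metaprograms(g, d, max_steps = 2L)
  mass <- sum(vapply(mps, function(mp) exp(mp_log_prior(mp, g, d)), 0))
  expect_lte(mass, 1 + 1e-12)
  expect_gt(mass, 0.3)
})
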