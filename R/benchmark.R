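# Benchmark list functions, scored example-set generation, example
# ordering, and the trial protocol.
#
# Inputs and outputs are lists of 0-15 natural numbers in 0..99. Example
# sets are chosen by sampling many candidate sets of 11 input/output pairs
# and keeping the best under a score that favors variance in list lengths,
# variance in elements, many distinct outputs, and few identity pairs --
# optionally sharpened by a per-function hook. A second scored pass picks
# the presentation order.

#' Define a list function
#'
#' @param id identifier string
#' @param description human-readable description
#' @param fn reference transformation: integer vector -> integer vector
#' @param valid optional input validity predicate (integer vector -> logical)
#' @param score_hook optional function(example set) -> numeric bonus added
#'   to [score_example_set()]
#' @return an object of class `mpl_list_function`
#' @export
list_function <- function(id, description, fn, valid = NULL, score_hook = NULL) {
  structure(list(id = id, description = description, fn = fn,
                 valid = valid, score_hook = score_hook),
            class = "mpl_list_function")
}

#' Families of indexed list functions
#'
#' Constructors for the parametric families: `lf_take(k)` keeps the first k
#' elements, `lf_cut(k)` removes the k-th, `lf_replace(k, v)` overwrites the
#' k-th with v, and `lf_swap(i, j)` exchanges positions i and j. Validity
#' requires inputs long enough for the index.
#'
#' @param k,i,j 1-based positions
#' @param v replacement value (0..99)
#' @return an `mpl_list_function`
#' @name lf_families
#' @export
lf_take <- function(k) list_function(
  paste0("take_", k), paste("keep the first", k, "elements"),
  function(x) utils::head(x, k), valid = function(x) length(x) >= k,
  score_hook = function(s) sum(vapply(s, function(pr) length(pr$input) >= k + 1L, TRUE)))

#' @rdname lf_families
#' @export
lf_cut <- function(k) list_function(
  paste0("cut_", k), paste("remove element", k),
  function(x) x[-k], valid = function(x) length(x) >= k)

#' @rdname lf_families
#' @export
lf_replace <- function(k, v) list_function(
  paste0("replace_", k, "_", v), paste("replace element", k, "with", v),
  function(x) { x[k] <- v; x }, valid = function(x) length(x) >= k)

#' @rdname lf_families
#' @export
lf_swap <- function(i, j) list_function(
  paste0("swap_", i, "_", j), paste("swap elements", i, "and", j),
  function(x) { tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp; x },
  valid = function(x) length(x) >= max(i, j))

#' Built-in benchmark functions
#'
#' The registry of reference list functions: the elementwise duplication
#' function (each input element appears twice in order), the
#' take/cut/replace/swap composition whose output is always six elements
#' with a constant 4 in fourth position, and a set of standard structural
#' and arithmetic tasks (maximum, sum, reverse, remove-every-other,
#' identity, head, tail, and take/cut/replace/swap family instances).
#'
#' @return a named list of `mpl_list_function` objects
#' @examples
#' builtin_functions()$duplicate$fn(c(1, 3, 9, 7))
#' @export
builtin_functions <- function() {
  fns <- list(
    list_function("duplicate", "repeat every element two times in order",
                  function(x) rep(x, each = 2L),
                  valid = function(x) 2L * length(x) <= 15L),
    list_function("swap_replace_cut_take",
                  "take 7, remove the 6th, set the 4th to 4, swap 1st and 3rd",
                  function(x) { y <- x[1:7]; y <- y[-6]; y[4] <- 4L
                                tmp <- y[1]; y[1] <- y[3]; y[3] <- tmp; y },
                  valid = function(x) length(x) >= 7L,
                  score_hook = function(s)
                    sum(vapply(s, function(pr) length(pr$input) >= 8L, TRUE))),
    list_function("maximum", "the largest element",
                  function(x) max(x), valid = function(x) length(x) >= 1L),
    list_function("sum", "the sum of the elements",
                  function(x) sum(x),
                  valid = function(x) length(x) >= 1L && sum(x) <= 99L),
    list_function("reverse", "the elements in reverse order", rev),
    list_function("remove_every_other", "keep the 1st, 3rd, 5th, ... elements",
                  function(x) x[seq_along(x) %% 2L == 1L]),
    list_function("identity", "the input unchanged", identity),
    list_function("head", "the first element",
                  function(x) x[1L], valid = function(x) length(x) >= 1L),
    list_function("tail", "drop the first element",
                  function(x) x[-1L], valid = function(x) length(x) >= 1L),
    lf_take(3L), lf_cut(2L), lf_replace(2L, 9L), lf_swap(1L, 3L)
  )
  stats::setNames(fns, vapply(fns, function(f) f$id, ""))
}

#' Look up a built-in function by id
#' @param id function identifier
#' @return an `mpl_list_function`
#' @export
get_function <- function(id) {
  fns <- builtin_functions()
  f <- fns[[id]]
  if (is.null(f)) stop("unknown list function: ", id)
  f
}

sample_valid_input <- function(fn, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    x <- sample(0:99, sample.int(16L, 1L) - 1L, replace = TRUE)
    if (!is.null(fn$valid) && !isTRUE(fn$valid(x))) next
    y <- as.integer(fn$fn(x))
    if (length(y) > 15L) next
    if (any(!is.na(y) & (y < 0L | y > 99L))) next
    return(list(input = as.integer(x), output = y))
  }
  stop("could not sample a valid input for ", fn$id)
}

#' Score an example set
#'
#' The four global criteria: variance in input and output lengths, variance
#' in list elements, number of distinct outputs, and (negatively) the
#' number of pairs whose input equals their output; plus the function's
#' optional custom hook. Higher is better. The score depends only on the
#' set, not its order.
#'
#' @param fn an `mpl_list_function`
#' @param s a list of `list(input =, output =)` pairs
#' @param weights numeric length 4: weights of the four criteria
#' @return a single number
#' @export
score_example_set <- function(fn, s, weights = c(1, 1, 1, 1)) {
  ilen <- vapply(s, function(pr) length(pr$input), 0L)
  olen <- vapply(s, function(pr) length(pr$output), 0L)
  elems <- unlist(lapply(s, function(pr) c(pr$input, pr$output)))
  sd0 <- function(v) if (length(v) >= 2L) stats::sd(v) else 0
  len_var <- sd0(ilen) + sd0(olen)
  elem_var <- sd0(elems[!is.na(elems)])
  outs <- vapply(s, function(pr) paste(pr$output, collapse = ","), "")
  n_unique <- length(unique(outs))
  n_ident <- sum(vapply(s, function(pr) identical(pr$input, pr$output), TRUE))
  sc <- weights[1] * len_var + weights[2] * elem_var +
    weights[3] * n_unique - weights[4] * n_ident
  if (!is.null(fn$score_hook)) sc <- sc + fn$score_hook(s)
  sc
}

#' Generate a scored example set
#'
#' Samples `n_candidates` candidate sets of 11 valid input/output pairs
#' (inputs uniform over lengths 0-15 and elements 0-99, filtered by the
#' function's validity predicate) and returns the set with the highest
#' [score_example_set()]. Deterministic under a fixed RNG seed.
#'
#' @param fn an `mpl_list_function`
#' @param n_candidates candidate sets to draw (>= 1)
#' @param n_pairs pairs per set (11 by convention)
#' @param weights criterion weights
#' @return a list of `n_pairs` pairs, with the winning score as attribute
#'   `"score"`
#' @export
generate_example_set <- function(fn, n_candidates = 10000L, n_pairs = 11L,
                                 weights = c(1, 1, 1, 1)) {
  best <- NULL
  best_score <- -Inf
  for (i in seq_len(max(1L, n_candidates))) {
    s <- lapply(seq_len(n_pairs), function(j) sample_valid_input(fn))
    sc <- score_example_set(fn, s, weights)
    if (sc > best_score) { best <- s; best_score <- sc }
  }
  attr(best, "score") <- best_score
  best
}

#' Order an example set for presentation
#'
#' Scores random orderings by: the set score of the first five pairs, the
#' set score of the last six pairs, whether the first example's input
#' differs from its output (weighted strongly, so such an example leads
#' whenever one exists), and the closeness of the first input's length
#' to 5. Returns the best ordering.
#'
#' @param fn an `mpl_list_function`
#' @param s an example set (list of pairs)
#' @param n_orderings random permutations to score (>= 1; the identity
#'   ordering is always included)
#' @param weights criterion weights for the subset scores
#' @param w_first_diff weight of the first-example input-differs-from-output
#'   indicator
#' @return the reordered example set
#' @export
order_examples <- function(fn, s, n_orderings = 5000L, weights = c(1, 1, 1, 1),
                           w_first_diff = 1000) {
  n <- length(s)
  score_order <- function(perm) {
    ss <- s[perm]
    first <- ss[[1L]]
    score_example_set(fn, ss[seq_len(min(5L, n))], weights) +
      score_example_set(fn, ss[seq.int(min(6L, n), n)], weights) +
      w_first_diff * (!identical(first$input, first$output)) -
      abs(5 - length(first$input))
  }
  best <- seq_len(n)
  best_score <- score_order(best)
  for (i in seq_len(max(0L, n_orderings - 1L))) {
    perm <- sample.int(n)
    sc <- score_order(perm)
    if (sc > best_score) { best <- perm; best_score <- sc }
  }
  s[best]
}

#' Build a trial protocol descriptor
#'
#' @param n_rounds rounds (default 10); each round presents one function
#' @param trials_per_round trials per round (default 11)
#' @return a list with `n_rounds`, `trials_per_round`, `n_trials`, and a
#'   data frame `schedule` with one row per trial
#' @examples
#' make_protocol()$n_trials   # 110
#' @export
make_protocol <- function(n_rounds = 10L, trials_per_round = 11L) {
  stopifnot(n_rounds >= 0L, trials_per_round >= 0L)
  schedule <- if (n_rounds > 0L && trials_per_round > 0L) {
    data.frame(round = rep(seq_len(n_rounds), each = trials_per_round),
               trial = rep(seq_len(trials_per_round), times = n_rounds))
  } else data.frame(round = integer(), trial = integer())
  list(n_rounds = n_rounds, trials_per_round = trials_per_round,
       n_trials = nrow(schedule), schedule = schedule)
}

#' Read and write example sets as JSON
#'
#' The on-disk format is `{"function_id", "description", "examples":
#' [{"input": [...], "output": [...]}]}` with deterministic field order.
#'
#' @param fn an `mpl_list_function` (or any list with `id`, `description`)
#' @param s an example set
#' @param path file path
#' @return `read_dataset_json`: a list with `function_id`, `description`,
#'   and `examples`
#' @export
write_dataset_json <- function(fn, s, path) {
  obj <- list(function_id = fn$id, description = fn$description,
              examples = lapply(s, function(pr)
                list(input = as.integer(pr$input), output = as.integer(pr$output))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dataset_json
#' @export
read_dataset_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  obj$examples <- lapply(obj$examples, function(pr)
    list(input = as.integer(unlist(pr$input)),
         output = as.integer(unlist(pr$output))))
  obj
}
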