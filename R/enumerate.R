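# The enumeration baseline: type-directed, grammar-based program
# enumeration in bands of increasing description length, with a
# win-stay/lose-shift online policy.
#
# Description length of a program is its negative log prior under the
# program grammar (nats), so the stream visits hypotheses in approximately
# decreasing order of prior probability. Enumeration proceeds depth-first
# within a band [i*delta, (i+1)*delta) and iteratively deepens across
# bands. One enumerated candidate counts as one step, making budgets
# comparable to search-step counts.

#' Enumeration budget
#'
#' @param delta band width in nats (default 1.5)
#' @param max_programs cap on the total number of emitted programs
#' @param max_dl cap on description length in nats
#' @return a list of class `mpl_enum_budget`
#' @export
enumeration_budget <- function(delta = 1.5, max_programs = 20000L, max_dl = 25) {
  stopifnot(delta > 0)
  structure(list(delta = delta, max_programs = as.integer(max_programs),
                 max_dl = max_dl), class = "mpl_enum_budget")
}

# depth-first enumeration of rhs terms with derivation cost in [lo, hi);
# emit(term, cost) is called for each complete term
enumerate_terms <- function(g, ty, scope, lo, hi, depth, acc_cost, prefix_emit) {
  opts <- term_options(g, ty, scope, depth)
  n <- length(opts)
  if (!n) return(invisible(NULL))
  step <- log(n)
  for (o in opts) {
    c0 <- acc_cost + step
    if (c0 >= hi) next
    switch(o$kind,
      var = prefix_emit(o$name, c0),
      bool = prefix_emit(o$value, c0),
      atom = prefix_emit(list(o$name), c0),
      num = {
        cn <- c0 + log(g$n_numerals)
        if (cn < hi) for (v in 0:(g$n_numerals - 1L)) prefix_emit(as.integer(v), cn)
      },
      op = {
        if (!length(o$args)) { prefix_emit(list(o$name), c0); next }
        enum_args <- function(i, built, cost) {
          if (cost >= hi) return(invisible(NULL))
          if (i > length(o$args)) {
            prefix_emit(c(list(o$name), built), cost)
            return(invisible(NULL))
          }
          enumerate_terms(g, o$args[[i]], scope, 0, hi - cost, depth + 1L, 0,
                          function(sub, sc) enum_args(i + 1L, c(built, list(sub)), cost + sc))
          invisible(NULL)
        }
        enum_args(1L, list(), c0)
      })
  }
  invisible(NULL)
}

#' Enumerate programs in description-length bands
#'
#' Returns a stream (a closure) producing single-rule programs
#' `F xs = rhs` in depth-first order within bands of `delta` nats,
#' bands in increasing order. Every well-typed program within the caps
#' appears exactly once; the stream ends with `NULL`.
#'
#' @param g a grammar
#' @param budget an [enumeration_budget()]
#' @param target target symbol (must be defined in the grammar's signature)
#' @return a function; each call returns `list(program, dl)` or `NULL`
#' @examples
#' nxt <- enumerate_programs(grammar(), enumeration_budget(max_programs = 50))
#' p1 <- nxt()
#' @export
enumerate_programs <- function(g, budget = enumeration_budget(), target = "F") {
  sch <- g$sig$defined[[target]]
  if (is.null(sch)) stop("target symbol not defined: ", target)
  # fixed overhead of the program skeleton: two rule-count decisions, the
  # head-symbol choice, and the lhs pattern (a single fresh variable)
  pvars <- list(xs = "list")
  base_cost <- 2 * log(2) + log(length(g$sig$defined)) +
    log(length(pattern_options(g, "list", list())))
  emitted <- 0L
  band <- 0L
  queue <- list()
  qi <- 1L
  fill_band <- function() {
    lo <- band * budget$delta
    hi <- min((band + 1) * budget$delta, budget$max_dl + base_cost)
    out <- list()
    if (lo < hi) {
      enumerate_terms(g, "list", pvars, 0, hi - base_cost, 0L, 0,
                      function(t, c) {
                        total <- base_cost + c
                        if (total >= lo && total < hi) {
                          out[[length(out) + 1L]] <<- list(term = t, dl = total)
                        }
                      })
    }
    out
  }
  function() {
    repeat {
      if (emitted >= budget$max_programs) return(NULL)
      if (qi <= length(queue)) {
        item <- queue[[qi]]
        qi <<- qi + 1L
        emitted <<- emitted + 1L
        p <- program(list(rule(list(target, "xs"), item$term)),
                     target = target, sig = g$sig)
        return(list(program = p, dl = item$dl))
      }
      if (band * budget$delta > budget$max_dl + base_cost) return(NULL)
      queue <<- fill_band()
      qi <<- 1L
      band <<- band + 1L
    }
  }
}

#' First program consistent with a set of pairs
#'
#' Scans the stream and returns the first program whose evaluation matches
#' every pair exactly, together with the number of candidates examined.
#'
#' @param stream a stream from [enumerate_programs()] (a fresh one; streams
#'   are single-pass)
#' @param pairs list of `list(input =, output =)` pairs
#' @param fuel evaluation budget per pair
#' @return `list(program, dl, steps)` or `NULL` if the stream is exhausted
#' @export
first_consistent <- function(stream, pairs, fuel = 3000L) {
  steps <- 0L
  repeat {
    item <- stream()
    if (is.null(item)) return(NULL)
    steps <- steps + 1L
    ok <- TRUE
    for (pr in pairs) {
      res <- evaluate_program_fast(item$program, pr$input, fuel)
      if (!isTRUE(res$ok) || !identical(res$value, as.integer(pr$output))) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(list(program = item$program, dl = item$dl, steps = steps))
  }
}

#' Win-stay/lose-shift prediction step
#'
#' If the state holds a committed program it is used unchanged; otherwise
#' (no commitment yet, or the previous prediction was wrong) the first
#' enumerated program consistent with all observed pairs is selected.
#'
#' @param state list with fields `program` (or NULL) and `pairs` observed
#'   so far
#' @param new_input input to predict on
#' @param make_stream zero-argument function returning a fresh enumeration
#'   stream (re-selection rescans from the start)
#' @param fuel evaluation budget per pair
#' @return list with `prediction` (integer vector or NULL) and the updated
#'   `state`
#' @export
win_stay_predict <- function(state, new_input, make_stream, fuel = 3000L) {
  if (is.null(state$program)) {
    hit <- first_consistent(make_stream(), state$pairs, fuel)
    state$program <- if (is.null(hit)) NULL else hit$program
  }
  prediction <- NULL
  if (!is.null(state$program)) {
    res <- evaluate_program_fast(state$program, new_input, fuel)
    if (isTRUE(res$ok)) prediction <- res$value
  }
  list(prediction = prediction, state = state)
}

#' Online 11-trial run for the enumeration baseline
#'
#' Implements the win-stay/lose-shift protocol: keep the committed program
#' after a correct prediction; after an incorrect one, re-select the first
#' enumerated program consistent with all pairs observed so far.
#'
#' @param fn_dataset a dataset of exactly 11 ordered pairs
#' @param budget an [enumeration_budget()]
#' @param seed RNG seed (recorded; enumeration itself is deterministic)
#' @param g grammar
#' @return a run record in the same shape as [online_run()]
#' @export
enum_online_run <- function(fn_dataset, budget = enumeration_budget(),
                            seed = 1L, g = grammar()) {
  stopifnot(length(fn_dataset) == 11L)
  set.seed(seed)
  state <- list(program = NULL, pairs = list())
  trials <- vector("list", 11L)
  for (i in 1:11) {
    out <- win_stay_predict(state, fn_dataset[[i]]$input,
                            function() enumerate_programs(g, budget))
    state <- out$state
    observed <- fn_dataset[[i]]$output
    correct <- !is.null(out$prediction) &&
      identical(as.integer(out$prediction), as.integer(observed))
    trials[[i]] <- list(input = fn_dataset[[i]]$input, predicted = out$prediction,
                        observed = observed, correct = correct,
                        best = if (!is.null(state$program))
                          list(key = program_key(state$program)) else NULL)
    state$pairs <- c(state$pairs, list(fn_dataset[[i]]))
    if (!correct) state$program <- NULL   # lose-shift: re-select next trial
  }
  list(trials = trials, seed = seed, params = budget)
}
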