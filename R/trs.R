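# Programs as first-order term rewriting systems, with matching, rewriting,
# normalization, and evaluation.
#
# Semantics fixed for reproducibility: leftmost-outermost reduction, with a
# program's own rules tried in order before the primitive delta-rules.
# Primitive semantics ("delta rules"):
#   (+ x y), (- x y): integer arithmetic; results outside 0..99 and any nan
#                     argument give nan
#   (> x y): strict greater-than; nan arguments give false
#   (== x y): literal identity of fully evaluated values
#   (if p a b), (is_empty xs), (head xs), (tail xs): as usual; head [] is
#                     nan and tail [] is [] so that list access is total
#   (fix x f): fixpoint iteration -- expands to
#                     (if (== (f x) x) x (fix (f x) f))

#' Construct a rewrite rule
#'
#' A rule `lhs ≈ rhs` whose left-hand side must be headed by a defined
#' function symbol and whose right-hand side may only use variables bound on
#' the left.
#'
#' @param lhs,rhs terms (or character scalars, which are parsed)
#' @param sig signature used when parsing character input
#' @return an object of class `mpl_rule`
#' @export
rule <- function(lhs, rhs, sig = sig_default()) {
  if (is.character(lhs) && length(lhs) == 1L && grepl("[([]|^[0-9]", lhs)) lhs <- parse_term(lhs, sig)
  if (is.character(rhs) && length(rhs) == 1L && grepl("[([]|^[0-9]|^nan$|^true$|^false$", rhs)) rhs <- parse_term(rhs, sig)
  if (!is.list(lhs)) stop("rule lhs must be an application headed by a defined symbol")
  extra <- setdiff(term_vars(rhs), term_vars(lhs))
  if (length(extra)) stop("rhs variables not bound on lhs: ", paste(extra, collapse = ", "))
  structure(list(lhs = lhs, rhs = rhs, print = rule_print_compute(lhs, rhs)),
            class = "mpl_rule")
}

rule_print_compute <- function(lhs, rhs) {
  lhs_txt <- if (is.list(lhs) && length(lhs) > 1L) {
    paste(lhs[[1L]], paste(vapply(lhs[-1L], print_term, ""), collapse = " "))
  } else print_term(lhs)
  paste(lhs_txt, "=", print_term(rhs))
}

#' Construct a program (an ordered list of rewrite rules)
#'
#' @param rules list of `mpl_rule` objects (possibly empty: the empty
#'   program, written ε)
#' @param target the distinguished target function symbol, default `"F"`
#' @param sig the signature the program is defined over
#' @return an object of class `mpl_program`
#' @export
program <- function(rules = list(), target = "F", sig = sig_default()) {
  # memo: per-program environment for lazily computed derived data (canonical
  # key, rule indexes, metaprimitive option lists); programs are immutable
  # after construction, and copies share the memo
  structure(list(rules = rules, target = target, sig = sig,
                 memo = new.env(parent = emptyenv())),
            class = "mpl_program")
}

program_key <- function(p) {
  k <- p$memo$key
  if (is.null(k)) {
    k <- if (!length(p$rules)) "ε" else
      paste(vapply(p$rules, print_rule, ""), collapse = "; ")
    p$memo$key <- k
  }
  k
}

# memoize a per-program computation under `name`
program_memo <- function(p, name, fn) {
  v <- p$memo[[name]]
  if (is.null(v)) {
    v <- fn(p)
    p$memo[[name]] <- v
  }
  v
}

#' @export
print.mpl_program <- function(x, ...) {
  cat(print_program(x))
  invisible(x)
}

#' Serialize / read a program in its one-rule-per-line text format
#'
#' Lines have the form `lhs = rhs` in the concrete term grammar; `#` starts
#' a comment. `parse_program(print_program(p))` round-trips.
#'
#' @param p a program
#' @return `print_program`: a character scalar.
#' @export
print_program <- function(p) {
  if (!length(p$rules)) return("# ε (empty program)\n")
  paste0(paste(vapply(p$rules, print_rule, ""), collapse = "\n"), "\n")
}

# Rule lhs prints in the juxtaposed style of rewrite rules: "F [x | y] = ...".
print_rule <- function(r) {
  if (!is.null(r$print)) r$print else rule_print_compute(r$lhs, r$rhs)
}

#' @rdname print_program
#' @param text program text
#' @param target target symbol
#' @param sig signature; defined symbols appearing as rule heads are added
#'   automatically with type `list -> list` if missing
#' @return `parse_program`: an `mpl_program`.
#' @export
parse_program <- function(text, target = "F", sig = sig_default()) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  # two passes so later rules can mention symbols defined by earlier heads
  for (ln in lines) {
    head_sym <- sub("^[\\[(]*\\(?\\s*", "", ln)
    head_sym <- regmatches(ln, regexpr("[A-Za-z_][A-Za-z0-9_']*", ln))
    if (length(head_sym) && is.na(sig_arity(sig, head_sym))) {
      sig <- sig_define(sig, head_sym)
    }
  }
  rules <- lapply(lines, function(ln) parse_rule_line(ln, sig))
  program(rules, target = target, sig = sig)
}

parse_rule_line <- function(ln, sig) {
  toks <- tokenize_term(ln)
  # split at the top-level "=" or "≈" token ("==" is its own token)
  depth <- 0L
  split_at <- NA_integer_
  for (i in seq_along(toks)) {
    tk <- toks[i]
    if (tk %in% c("(", "[")) depth <- depth + 1L
    else if (tk %in% c(")", "]")) depth <- depth - 1L
    else if (depth == 0L && tk %in% c("=", "≈")) { split_at <- i; break }
  }
  if (is.na(split_at)) stop("rule line lacks '=': ", ln)
  lhs <- parse_term_seq(toks[seq_len(split_at - 1L)], sig)
  rhs <- parse_term_seq(toks[seq(split_at + 1L, length(toks))], sig)
  rule(lhs, rhs, sig)
}

# Parse a token sequence as a term, allowing top-level application by
# juxtaposition (the usual rewrite-rule style, e.g. "F [x | y]").
parse_term_seq <- function(toks, sig) {
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  parts <- list()
  while (!is.na(peek_tok(st))) parts <- c(parts, list(parse_one(st, sig)))
  if (length(parts) == 1L) return(parts[[1L]])
  head <- parts[[1L]]
  if (!(is.list(head) && length(head) == 1L)) stop("cannot apply non-symbol term")
  op <- head[[1L]]
  ar <- sig_arity(sig, op)
  if (length(parts) - 1L != ar) stop("arity error applying ", op)
  c(list(op), parts[-1L])
}

# --- matching ---------------------------------------------------------------

# extend a substitution by construction (list subassignment copies values)
subst_bind <- function(subst, var, value) {
  nn <- names(subst)
  subst <- c(subst, list(value))
  names(subst) <- c(nn, var)
  subst
}

#' First-order matching
#'
#' Finds the unique substitution `σ` with `σ(pattern) = target`, if one
#' exists. Patterns may be nonlinear: repeated variables must bind equal
#' subterms.
#'
#' @param pattern a term possibly containing variables
#' @param target a ground term
#' @return a named list of bindings, or `NULL` if the pattern does not match
#' @examples
#' trs_match(parse_term("[x | y]"), parse_term("[1, 3, 9, 7]"))
#' @export
trs_match <- function(pattern, target) {
  match_rec(pattern, target, list())
}

match_rec <- function(pat, tgt, subst) {
  if (is.character(pat)) {
    b <- subst[[pat]]
    if (is.null(b)) return(subst_bind(subst, pat, tgt))
    if (identical(b, tgt)) return(subst)
    return(NULL)
  }
  if (is.list(pat)) {
    if (!is.list(tgt) || length(pat) != length(tgt) || pat[[1L]] != tgt[[1L]]) return(NULL)
    for (i in seq_along(pat)[-1L]) {
      subst <- match_rec(pat[[i]], tgt[[i]], subst)
      if (is.null(subst)) return(NULL)
    }
    return(subst)
  }
  if (identical(pat, tgt)) subst else NULL
}

# --- rewriting --------------------------------------------------------------

is_value_scalar <- function(t) !is.list(t) && !is.character(t)

delta_step <- function(t) {
  op <- t[[1L]]
  # unapplied symbol atoms (e.g. the f in (fix x f)) are normal forms
  if (length(t) == 1L) return(NULL)
  switch(op,
    "+" = , "-" = {
      x <- t[[2L]]; y <- t[[3L]]
      if (!is_value_scalar(x) || !is_value_scalar(y)) return(NULL)
      if (is.na(x) || is.na(y)) return(NA_integer_)
      r <- if (op == "+") as.integer(x) + as.integer(y) else as.integer(x) - as.integer(y)
      if (r < 0L || r > 99L) NA_integer_ else r
    },
    ">" = {
      x <- t[[2L]]; y <- t[[3L]]
      if (!is_value_scalar(x) || !is_value_scalar(y)) return(NULL)
      if (is.na(x) || is.na(y)) return(FALSE)
      as.integer(x) > as.integer(y)
    },
    "==" = {
      x <- t[[2L]]; y <- t[[3L]]
      if (is.character(x) || is.character(y)) return(NULL)
      if (!term_is_normal_value(x) || !term_is_normal_value(y)) return(NULL)
      identical(x, y)
    },
    "if" = {
      p <- t[[2L]]
      if (!is.logical(p)) return(NULL)
      if (p) t[[3L]] else t[[4L]]
    },
    "is_empty" = {
      xs <- t[[2L]]
      if (!is.list(xs)) return(NULL)
      h <- xs[[1L]]
      if (h == "nil") TRUE else if (h == "cons") FALSE else NULL
    },
    "head" = {
      xs <- t[[2L]]
      if (!is.list(xs)) return(NULL)
      h <- xs[[1L]]
      if (h == "cons") xs[[2L]] else if (h == "nil") NA_integer_ else NULL
    },
    "tail" = {
      xs <- t[[2L]]
      if (!is.list(xs)) return(NULL)
      h <- xs[[1L]]
      if (h == "cons") xs[[3L]] else if (h == "nil") list("nil") else NULL
    },
    "fix" = {
      x <- t[[2L]]; f <- t[[3L]]
      if (!is.list(f) || length(f) != 1L) return(NULL)
      fx <- list(f[[1L]], x)
      list("if", list("==", fx, x), x, list("fix", fx, f))
    },
    NULL
  )
}

# TRUE for fully evaluated first-order values (numerals, booleans, ground
# cons chains of values). Used by == so it only fires on normal forms.
term_is_normal_value <- function(t) {
  if (!is.list(t)) return(!is.character(t))
  h <- t[[1L]]
  if (h == "nil") return(length(t) == 1L)
  if (h == "cons") return(term_is_normal_value(t[[2L]]) && term_is_normal_value(t[[3L]]))
  FALSE
}

# One leftmost-outermost rewrite step; NULL if t is in normal form.
rewrite_rec <- function(rules_by_head, t) {
  if (!is.list(t)) return(NULL)
  op <- t[[1L]]
  rs <- rules_by_head[[op]]
  if (!is.null(rs)) {
    for (r in rs) {
      s <- match_rec(r$lhs, t, list())
      if (!is.null(s)) return(term_subst(r$rhs, s))
    }
  }
  r <- delta_step(t)
  if (!is.null(r)) return(r)
  for (i in seq_along(t)[-1L]) {
    r <- rewrite_rec(rules_by_head, t[[i]])
    if (!is.null(r)) return(list_replace(t, i, r))
  }
  NULL
}

rules_by_head <- function(p) {
  program_memo(p, "rules_by_head", function(p) {
    out <- list()
    for (r in p$rules) {
      h <- r$lhs[[1L]]
      out[[h]] <- c(out[[h]], list(r))
    }
    out
  })
}

#' Single rewrite step
#'
#' Applies the first applicable rule (program rules in order, then primitive
#' delta-rules) at the leftmost-outermost redex.
#'
#' @param p a program
#' @param t a term
#' @return the rewritten term, or `NULL` if `t` is in normal form
#' @export
rewrite_step <- function(p, t) {
  rewrite_rec(rules_by_head(p), t)
}

#' Normalize a term under a program
#'
#' Iterates [rewrite_step()] until a normal form is reached or a resource
#' bound is hit. The result is an evaluation record, never an error:
#' exceeding `step_limit` or the term-size cap, or ending on a normal form
#' that is not a fully concrete value, yields `ok = FALSE`.
#'
#' @param p a program
#' @param t a term
#' @param step_limit maximum number of rewrite steps (default 10000)
#' @param size_limit maximum term size in nodes (default 10000)
#' @return a list with fields `ok`, `term` (final term), `value` (integer
#'   vector with NA for nan when the normal form is a concrete list, else
#'   NULL), and `steps`
#' @export
normalize <- function(p, t, step_limit = 10000L, size_limit = 10000L) {
  rbh <- rules_by_head(p)
  steps <- 0L
  while (steps < step_limit) {
    nxt <- rewrite_rec(rbh, t)
    if (is.null(nxt)) {
      ok <- term_is_normal_value(t)
      return(list(ok = ok, term = t,
                  value = if (ok && is.list(t)) term_to_vector(t) else NULL,
                  steps = steps))
    }
    t <- nxt
    steps <- steps + 1L
    if (steps %% 4L == 0L && term_size(t) > size_limit) {
      return(list(ok = FALSE, term = t, value = NULL, steps = steps))
    }
  }
  list(ok = FALSE, term = t, value = NULL, steps = steps)
}

#' Evaluate a program on an input list
#'
#' Encodes `input` as a term, normalizes `F(input)` (for the program's
#' target symbol), and decodes the normal form back into an integer vector.
#' `nan` elements decode to `NA`.
#'
#' @param p a program
#' @param input integer vector with elements in 0..99
#' @param step_limit,size_limit resource bounds passed to [normalize()]
#' @return a list with fields `ok`, `value` (integer vector or NULL), and
#'   `steps`
#' @examples
#' p <- parse_program("F [] = []\nF [x | y] = [x, x | (F y)]")
#' evaluate_program(p, c(9, 2))$value
#' @export
evaluate_program <- function(p, input, step_limit = 10000L, size_limit = 10000L) {
  t <- list(p$target, t_list(input))
  res <- normalize(p, t, step_limit, size_limit)
  v <- res$value
  ok <- res$ok && !is.null(v)
  list(ok = ok, value = if (ok) v else NULL, steps = res$steps)
}

# --- determinism ------------------------------------------------------------

rename_vars <- function(t, suffix) {
  if (is.character(t)) return(paste0(t, suffix))
  if (is.list(t)) for (i in seq_along(t)[-1L]) t[[i]] <- rename_vars(t[[i]], suffix)
  t
}

# First-order unification of two terms (both may contain variables).
term_unify <- function(a, b, subst = list()) {
  a <- unify_walk(a, subst)
  b <- unify_walk(b, subst)
  if (is.character(a)) {
    if (identical(a, b)) return(subst)
    if (occurs_in(a, b, subst)) return(NULL)
    subst[[a]] <- b
    return(subst)
  }
  if (is.character(b)) return(term_unify(b, a, subst))
  if (is.list(a)) {
    if (!is.list(b) || length(a) != length(b) || a[[1L]] != b[[1L]]) return(NULL)
    for (i in seq_along(a)[-1L]) {
      subst <- term_unify(a[[i]], b[[i]], subst)
      if (is.null(subst)) return(NULL)
    }
    return(subst)
  }
  if (identical(a, b)) subst else NULL
}

unify_walk <- function(t, subst) {
  while (is.character(t) && !is.null(subst[[t]])) t <- subst[[t]]
  t
}

occurs_in <- function(v, t, subst) {
  t <- unify_walk(t, subst)
  if (is.character(t)) return(identical(v, t))
  if (is.list(t)) {
    for (i in seq_along(t)[-1L]) if (occurs_in(v, t[[i]], subst)) return(TRUE)
  }
  FALSE
}

subst_resolve <- function(t, subst) {
  t <- unify_walk(t, subst)
  if (is.list(t)) for (i in seq_along(t)[-1L]) t[[i]] <- subst_resolve(t[[i]], subst)
  t
}

#' Check that a program is deterministic
#'
#' A program is rejected when two rules overlap at the root under an
#' order-insensitive reading: their left-hand sides unify (after renaming
#' apart) but the unified right-hand sides differ, so some ground instance
#' could rewrite to two different results. Memorized rules with distinct
#' ground patterns always pass.
#'
#' @param p a program
#' @return logical
#' @export
is_deterministic <- function(p) {
  rs <- p$rules
  n <- length(rs)
  if (n < 2L) return(TRUE)
  heads <- vapply(rs, function(r) r$lhs[[1L]], "")
  ground <- vapply(rs, function(r) length(term_vars(r$lhs)) == 0L, TRUE)
  lhs_key <- vapply(rs, function(r) print_term(r$lhs), "")
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (heads[i] != heads[j]) next
      # two ground lhs overlap only when identical
      if (ground[i] && ground[j]) {
        if (lhs_key[i] == lhs_key[j] &&
            !identical(rs[[i]]$rhs, rs[[j]]$rhs)) return(FALSE)
        next
      }
      li <- rename_vars(rs[[i]]$lhs, "#1")
      ri <- rename_vars(rs[[i]]$rhs, "#1")
      lj <- rename_vars(rs[[j]]$lhs, "#2")
      rj <- rename_vars(rs[[j]]$rhs, "#2")
      s <- term_unify(li, lj)
      if (!is.null(s)) {
        if (!identical(subst_resolve(ri, s), subst_resolve(rj, s))) return(FALSE)
      }
    }
  }
  TRUE
}
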