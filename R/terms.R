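# Terms over the object-level list-function language.
#
# Representation (chosen for speed in the rewriting inner loop):
#   * numeral           -- an integer scalar in 0..99; NA_integer_ encodes nan
#   * boolean           -- TRUE / FALSE
#   * variable          -- a character scalar, e.g. "x", "x1"
#   * application       -- a list whose first element is the operator name
#                          (character) and whose remaining elements are the
#                          argument terms; list("nil") is the empty list [],
#                          list("F") is the unapplied symbol atom F.
# Applications are kept n-ary at the operator's declared arity; currying only
# exists at the type level (see infer_type).

#' Default signature of the object-level language
#'
#' Returns the signature holding the built-in primitive operators (`+`, `-`,
#' `>`, `if`, `==`, `is_empty`, `head`, `tail`, `cons`, `nil`, `fix`) with
#' their arities and type schemes, plus any defined function symbols.
#' Numerals `0..99`, `nan`, and the booleans are literals, not operators.
#'
#' @param defined named list of defined function symbols; each entry is a
#'   list with fields `args` (list of argument types) and `ret` (result
#'   type). Defaults to a single symbol `F : list -> list`, the conventional
#'   name of the target function.
#' @return an object of class `mpl_signature` with fields `ops` and
#'   `defined`.
#' @examples
#' sig <- sig_default()
#' names(sig$ops)
#' @export
sig_default <- function(defined = list(F = list(args = list("list"), ret = "list"))) {
  ops <- list(
    "+"        = list(args = list("num", "num"), ret = "num"),
    "-"        = list(args = list("num", "num"), ret = "num"),
    ">"        = list(args = list("num", "num"), ret = "bool"),
    "if"       = list(args = list("bool", "a", "a"), ret = "a"),
    "=="       = list(args = list("a", "a"), ret = "bool"),
    "is_empty" = list(args = list("list"), ret = "bool"),
    "head"     = list(args = list("list"), ret = "num"),
    "tail"     = list(args = list("list"), ret = "list"),
    "cons"     = list(args = list("num", "list"), ret = "list"),
    "nil"      = list(args = list(), ret = "list"),
    "fix"      = list(args = list("a", list("->", "a", "a")), ret = "a")
  )
  bad <- intersect(names(defined), names(ops))
  if (length(bad)) stop("defined symbols clash with primitives: ", paste(bad, collapse = ", "))
  structure(list(ops = ops, defined = defined), class = "mpl_signature")
}

#' Extend a signature with a defined function symbol
#'
#' @param sig an `mpl_signature`
#' @param name symbol name (must not clash with a primitive)
#' @param args list of argument types
#' @param ret result type
#' @return the extended signature
#' @export
sig_define <- function(sig, name, args = list("list"), ret = "list") {
  if (name %in% names(sig$ops)) stop("symbol clashes with a primitive: ", name)
  sig$defined[[name]] <- list(args = args, ret = ret)
  sig
}

sig_arity <- function(sig, name) {
  s <- sig$ops[[name]]
  if (is.null(s)) s <- sig$defined[[name]]
  if (is.null(s)) return(NA_integer_)
  length(s$args)
}

is_defined_symbol <- function(sig, name) !is.null(sig$defined[[name]])

# --- constructors -----------------------------------------------------------

#' @rdname term_helpers
#' @export
t_num <- function(n) {
  n <- as.integer(n)
  if (!is.na(n) && (n < 0L || n > 99L)) NA_integer_ else n
}

#' Term construction helpers
#'
#' Small constructors for the internal term representation: `t_num(n)` for a
#' numeral (values outside 0..99 become `nan`), `t_nan()`, `t_var(name)`,
#' `t_app(op, ...)` for an operator application, and `t_list(v)` to encode an
#' integer vector as a cons chain (NA elements become `nan`).
#'
#' @param n integer value
#' @param name variable name
#' @param op operator name
#' @param ... argument terms
#' @param v integer vector (possibly with NAs)
#' @return a term
#' @name term_helpers
#' @export
t_app <- function(op, ...) c(list(op), list(...))

#' @rdname term_helpers
#' @export
t_nan <- function() NA_integer_

#' @rdname term_helpers
#' @export
t_var <- function(name) name

#' @rdname term_helpers
#' @export
t_list <- function(v) {
  t <- list("nil")
  for (x in rev(as.integer(v))) t <- list("cons", x, t)
  t
}

is_term_var <- function(t) is.character(t)
is_term_app <- function(t) is.list(t)

term_equal <- function(a, b) identical(a, b)

term_size <- function(t) {
  if (!is.list(t)) return(1L)
  n <- 1L
  for (i in seq_along(t)[-1L]) n <- n + term_size(t[[i]])
  n
}

term_vars <- function(t) .mpl_term_vars_cpp(t, TRUE)

# Replace element i of a list by construction. R's `[[<-` duplicates the
# assigned value, which turns structure-sharing algorithms quadratic; all
# hot paths build nodes with c()/list() instead.
list_replace <- function(t, i, v) {
  n <- length(t)
  c(t[seq_len(i - 1L)], list(v), if (i < n) t[seq.int(i + 1L, n)])
}

# Apply a substitution (named list var -> term).
term_subst <- function(t, subst) {
  if (is.character(t)) {
    b <- subst[[t]]
    if (is.null(b)) t else b
  } else if (is.list(t) && length(t) > 1L) {
    c(t[1L], lapply(t[-1L], term_subst, subst))
  } else t
}

# All subterms in preorder (including t itself). Returns a flat list.
term_subterms <- function(t) {
  acc <- list(t)
  if (is.list(t)) {
    for (i in seq_along(t)[-1L]) acc <- c(acc, term_subterms(t[[i]]))
  }
  acc
}

# Replace every occurrence of subterm `old` in `t` by `new`.
term_replace_all <- function(t, old, new) {
  if (identical(t, old)) return(new)
  if (is.list(t) && length(t) > 1L) {
    return(c(t[1L], lapply(t[-1L], term_replace_all, old, new)))
  }
  t
}

# Decode a ground cons chain into an integer vector; NULL if not a chain.
term_to_vector <- function(t) {
  out <- integer()
  while (is.list(t) && t[[1L]] == "cons") {
    h <- t[[2L]]
    if (is.list(h) || is.character(h) || is.logical(h)) return(NULL)
    out <- c(out, as.integer(h))
    t <- t[[3L]]
  }
  if (is.list(t) && t[[1L]] == "nil" && length(t) == 1L) out else NULL
}

# --- printing ---------------------------------------------------------------

#' Print a term in concrete s-expression syntax
#'
#' Produces the canonical textual form: numerals print as themselves,
#' `nan`/`true`/`false` as keywords, cons chains in bracket notation
#' (`[1, 3, 9]`, `[x, x | (F y)]`), and operator applications as
#' parenthesized s-expressions. `parse_term(print_term(t))` is the identity
#' on well-formed terms.
#'
#' @param t a term
#' @return a character scalar
#' @examples
#' print_term(t_list(c(9, 2)))
#' @export
print_term <- function(t) .mpl_print_term_cpp(t)

# reference R implementation, retained for documentation of the canonical
# format and for cross-checking the compiled printer in tests
print_term_r <- function(t) {
  if (is.character(t)) return(t)
  if (is.logical(t)) return(if (t) "true" else "false")
  if (!is.list(t)) return(if (is.na(t)) "nan" else as.character(t))
  op <- t[[1L]]
  if (op == "nil") return("[]")
  if (op == "cons") {
    items <- character()
    while (is.list(t) && t[[1L]] == "cons") {
      items <- c(items, print_term_r(t[[2L]]))
      t <- t[[3L]]
    }
    if (is.list(t) && t[[1L]] == "nil") {
      return(paste0("[", paste(items, collapse = ", "), "]"))
    }
    return(paste0("[", paste(items, collapse = ", "), " | ", print_term_r(t), "]"))
  }
  if (op == "lambda") {
    return(paste0("(lambda ", t[[2L]], " ", print_term_r(t[[3L]]), ")"))
  }
  if (length(t) == 1L) return(op)
  paste0("(", op, " ", paste(vapply(t[-1L], print_term_r, ""), collapse = " "), ")")
}

# --- parsing ----------------------------------------------------------------

tokenize_term <- function(text) {
  pat <- "\\s*(==|\\[\\]|[()\\[\\],|]|=|≈|[0-9]+|[A-Za-z_+><!?*-][A-Za-z0-9_'!?*-]*|λ|\\S)"
  toks <- character()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    m <- regexpr(pat, substr(text, pos, n), perl = TRUE)
    if (m == -1L) break
    len <- attr(m, "match.length")
    tok <- sub("^\\s+", "", substr(text, pos, pos + len - 1L))
    pos <- pos + len
    if (nzchar(tok)) toks <- c(toks, tok)
  }
  toks
}

#' Parse a term from concrete syntax
#'
#' Accepts the s-expression grammar: numerals `0..99`, `nan`, `true`,
#' `false`, `[]`; bracket lists `[a, b]` and bracket-prepend `[a, b | rest]`;
#' applications `(op a b ...)`; and `(lambda x body)` surface lambdas
#' (alias `λ`). Unknown operator symbols and arity violations are
#' errors.
#'
#' @param text a character scalar of concrete syntax
#' @param sig a signature, by default `sig_default()`
#' @return a term
#' @examples
#' parse_term("[1, 3, 9, 7]")
#' parse_term("(head xs)")
#' @export
parse_term <- function(text, sig = sig_default()) {
  toks <- tokenize_term(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  t <- parse_one(st, sig)
  if (st$i <= length(st$toks)) {
    stop("syntax error at token ", st$i, ": trailing input '", st$toks[st$i], "'")
  }
  t
}

peek_tok <- function(st) if (st$i <= length(st$toks)) st$toks[st$i] else NA_character_
next_tok <- function(st) {
  tok <- peek_tok(st)
  if (is.na(tok)) stop("syntax error: unexpected end of input")
  st$i <- st$i + 1L
  tok
}
expect_tok <- function(st, what) {
  tok <- next_tok(st)
  if (tok != what) stop("syntax error at token ", st$i - 1L, ": expected '", what, "', got '", tok, "'")
  tok
}

parse_one <- function(st, sig) {
  tok <- next_tok(st)
  if (grepl("^[0-9]+$", tok)) return(t_num(as.integer(tok)))
  if (tok == "nan") return(NA_integer_)
  if (tok == "true") return(TRUE)
  if (tok == "false") return(FALSE)
  if (tok == "[]") return(list("nil"))
  if (tok == "[") return(parse_bracket(st, sig))
  if (tok == "(") {
    op <- next_tok(st)
    if (op == "λ" || op == "lambda") {
      v <- next_tok(st)
      body <- parse_one(st, sig)
      expect_tok(st, ")")
      return(list("lambda", v, body))
    }
    args <- list()
    while (!identical(peek_tok(st), ")")) {
      if (is.na(peek_tok(st))) stop("syntax error: unbalanced '('")
      args <- c(args, list(parse_one(st, sig)))
    }
    expect_tok(st, ")")
    ar <- sig_arity(sig, op)
    if (is.na(ar)) stop("unknown symbol: ", op)
    if (length(args) != ar) {
      stop("arity error: ", op, " expects ", ar, " arguments, got ", length(args))
    }
    return(c(list(op), args))
  }
  if (grepl("^[A-Za-z_]", tok)) {
    # known symbol atoms parse as zero-argument applications; otherwise a variable
    if (!is.na(sig_arity(sig, tok))) return(list(tok))
    return(tok)
  }
  stop("syntax error at token ", st$i - 1L, ": unexpected '", tok, "'")
}

parse_bracket <- function(st, sig) {
  items <- list()
  rest <- list("nil")
  if (!identical(peek_tok(st), "]")) {
    repeat {
      items <- c(items, list(parse_one(st, sig)))
      tok <- next_tok(st)
      if (tok == "]") break
      if (tok == "|") {
        rest <- parse_one(st, sig)
        expect_tok(st, "]")
        break
      }
      if (tok != ",") stop("syntax error in list at token ", st$i - 1L, ": got '", tok, "'")
    }
  } else {
    expect_tok(st, "]")
  }
  t <- rest
  for (x in rev(items)) t <- list("cons", x, t)
  t
}
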