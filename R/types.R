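# Hindley-Milner-style type checking for object-level terms.
#
# Types: "num", "bool", "list" (lists always hold num in this language),
# arrow types list("->", dom, cod), and inference-time type variables
# represented as character scalars starting with "?". Type variables never
# appear in user-facing schemes except through the polymorphic primitives
# (if, ==, fix), whose schemes mention the scheme variable "a".

ty_is_var <- function(ty) is.character(ty) && startsWith(ty, "?")

ty_fresh <- function(st) {
  st$n <- st$n + 1L
  paste0("?", st$n)
}

# Walk a type through the current substitution (path compression not needed
# at this scale).
ty_resolve <- function(ty, st) {
  while (ty_is_var(ty)) {
    nxt <- st$sub[[ty]]
    if (is.null(nxt)) return(ty)
    ty <- nxt
  }
  if (is.list(ty)) {
    ty[[2L]] <- ty_resolve(ty[[2L]], st)
    ty[[3L]] <- ty_resolve(ty[[3L]], st)
  }
  ty
}

ty_unify <- function(a, b, st, where) {
  a <- ty_resolve(a, st)
  b <- ty_resolve(b, st)
  if (identical(a, b)) return(invisible(TRUE))
  if (ty_is_var(a)) { st$sub[[a]] <- b; return(invisible(TRUE)) }
  if (ty_is_var(b)) { st$sub[[b]] <- a; return(invisible(TRUE)) }
  if (is.list(a) && is.list(b)) {
    ty_unify(a[[2L]], b[[2L]], st, where)
    ty_unify(a[[3L]], b[[3L]], st, where)
    return(invisible(TRUE))
  }
  stop("type mismatch in ", where, ": ", ty_show(a), " vs ", ty_show(b))
}

ty_show <- function(ty) {
  if (is.list(ty)) paste0("(", ty_show(ty[[2L]]), " -> ", ty_show(ty[[3L]]), ")")
  else ty
}

# Instantiate a scheme: replace scheme variable "a" by a fresh type variable.
ty_instantiate <- function(scheme, st) {
  inst <- NULL
  rec <- function(ty) {
    if (is.list(ty)) return(list("->", rec(ty[[2L]]), rec(ty[[3L]])))
    if (identical(ty, "a")) {
      if (is.null(inst)) inst <<- ty_fresh(st)
      return(inst)
    }
    ty
  }
  list(args = lapply(scheme$args, rec), ret = rec(scheme$ret))
}

sig_scheme <- function(sig, name) {
  s <- sig$ops[[name]]
  if (is.null(s)) s <- sig$defined[[name]]
  s
}

# Curried arrow type for a symbol atom.
ty_curry <- function(args, ret) {
  ty <- ret
  for (a in rev(args)) ty <- list("->", a, ty)
  ty
}

#' Infer the principal type of a term
#'
#' Runs unification-based type inference over the term. Free variables are
#' assigned fresh type variables (or the types given in `env`); the returned
#' type has any residual type variables resolved as far as possible. A term
#' that violates an operator's argument types raises a type-mismatch error
#' naming the offending subterm.
#'
#' @param t a term
#' @param sig a signature
#' @param env optional named list assigning types to free variables
#' @return the type: `"num"`, `"bool"`, `"list"`, an arrow `list("->", a, b)`,
#'   or a type variable (character starting with `"?"`) when unconstrained
#' @examples
#' infer_type(parse_term("(head xs)"), sig_default())
#' @export
infer_type <- function(t, sig = sig_default(), env = list()) {
  st <- new.env(parent = emptyenv())
  st$n <- 0L
  st$sub <- list()
  venv <- new.env(parent = emptyenv())
  for (v in names(env)) assign(v, env[[v]], envir = venv)
  ty <- infer_rec(t, sig, st, venv)
  ty_resolve(ty, st)
}

infer_rec <- function(t, sig, st, venv) {
  if (is.character(t)) {
    if (!exists(t, envir = venv, inherits = FALSE)) assign(t, ty_fresh(st), envir = venv)
    return(get(t, envir = venv, inherits = FALSE))
  }
  if (is.logical(t)) return("bool")
  if (!is.list(t)) return("num")
  op <- t[[1L]]
  if (op == "lambda") {
    v <- t[[2L]]
    old <- if (exists(v, envir = venv, inherits = FALSE)) get(v, envir = venv) else NULL
    a <- ty_fresh(st)
    assign(v, a, envir = venv)
    b <- infer_rec(t[[3L]], sig, st, venv)
    if (is.null(old)) rm(list = v, envir = venv) else assign(v, old, envir = venv)
    return(list("->", a, b))
  }
  scheme <- sig_scheme(sig, op)
  if (is.null(scheme)) stop("unknown symbol: ", op)
  inst <- ty_instantiate(scheme, st)
  nargs <- length(t) - 1L
  if (nargs == 0L && length(inst$args) > 0L) {
    # unapplied symbol atom: curried arrow type
    return(ty_curry(inst$args, inst$ret))
  }
  if (nargs != length(inst$args)) {
    stop("arity error in ", print_term(t), ": ", op, " expects ", length(inst$args), " arguments")
  }
  for (i in seq_len(nargs)) {
    got <- infer_rec(t[[i + 1L]], sig, st, venv)
    ty_unify(inst$args[[i]], got, st, print_term(t))
  }
  inst$ret
}
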