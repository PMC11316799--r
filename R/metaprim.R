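# Metaprimitives: program transformations that, composed into metaprograms,
# reduce (given data) to ordinary rewrite programs.
#
# Every metaprimitive that takes a random choice ψ enumerates its legal
# options in a canonical deterministic order (rule order, then preorder
# subterm position), so a ψ is always a stable, serializable integer index
# into that list. A metaprimitive with no legal option, or whose result
# would violate the rule invariants, is *inapplicable*: the reduction of the
# enclosing metaprogram fails (it never silently acts as the identity).

MP_NAMES <- c("MemorizeAll", "Memorize", "Recurse", "Delete",
              "Variable", "Compose", "Subproblem", "AntiUnify")
MP_TAKES_PSI <- c(MemorizeAll = FALSE, Memorize = TRUE, Recurse = TRUE,
                  Delete = TRUE, Variable = TRUE, Compose = TRUE,
                  Subproblem = TRUE, AntiUnify = FALSE)

MAX_MP_STEPS <- 7L
MAX_MP_CHOICES <- 50L
RECURSE_KS <- 0:4

# Evaluation budget used inside metaprimitives (entailment checks) and
# search; deliberately smaller than the user-facing normalize() default.
MP_EVAL_STEPS <- 600L
MP_EVAL_SIZE <- 2000L
MP_EVAL_FUEL <- 3000L

#' Construct a dataset of input/output pairs
#'
#' @param pairs a list of `list(input =, output =)` integer vectors, or
#'   `NULL` to build from `inputs`/`outputs`
#' @param inputs,outputs parallel lists of integer vectors
#' @return a list of pairs with class `mpl_dataset`
#' @export
dataset <- function(pairs = NULL, inputs = NULL, outputs = NULL) {
  if (is.null(pairs)) {
    stopifnot(length(inputs) == length(outputs))
    pairs <- Map(function(i, o) list(input = as.integer(i), output = as.integer(o)),
                 inputs, outputs)
  }
  for (pr in pairs) {
    iv <- pr$input; ov <- pr$output
    if (length(iv) > 15L || length(ov) > 15L) stop("list lengths must be 0..15")
    if (any(stats::na.omit(c(iv, ov)) < 0L) || any(stats::na.omit(c(iv, ov)) > 99L))
      stop("elements must be 0..99")
  }
  structure(unname(pairs), class = c("mpl_dataset", "list"))
}

#' Construct a metaprogram
#'
#' A metaprogram is a base program (usually the empty program ε) plus an
#' ordered sequence of at most 7 metaprimitive steps, applied innermost
#' first. Steps are `list(name =, psi =)` where `psi` is an integer index
#' into the canonical option list of the metaprimitive at its application
#' point (NULL for MemorizeAll / AntiUnify, which take no choice).
#'
#' @param steps list of steps; may also be given as a character vector of
#'   names for ψ-free steps
#' @param base base program (default ε over `sig`)
#' @param sig signature for the default base
#' @return an object of class `mpl_metaprogram`
#' @examples
#' mp <- metaprogram(list(list(name = "MemorizeAll"), list(name = "AntiUnify")))
#' print_metaprogram(mp)
#' @export
metaprogram <- function(steps = list(), base = NULL, sig = sig_default()) {
  if (is.character(steps)) steps <- lapply(steps, function(nm) list(name = nm))
  if (is.null(base)) base <- program(sig = sig)
  steps <- lapply(steps, function(s) {
    if (!s$name %in% MP_NAMES) stop("unknown metaprimitive: ", s$name)
    if (is.null(s$psi)) s["psi"] <- list(NULL) else s$psi <- as.integer(s$psi)
    s[c("name", "psi")]
  })
  if (length(steps) > MAX_MP_STEPS) stop("metaprograms may have at most ", MAX_MP_STEPS, " steps")
  structure(list(base = base, steps = steps), class = "mpl_metaprogram")
}

#' Print / parse metaprograms in nested application syntax
#'
#' The textual form mirrors the usage column of the metaprimitive table:
#' `(AntiUnify (Recurse (MemorizeAll ε) ψ:1))`. An explicit base program is
#' written between braces with rules separated by `;`.
#'
#' @param mp a metaprogram
#' @return `print_metaprogram`: a character scalar
#' @export
print_metaprogram <- function(mp) {
  txt <- if (!length(mp$base$rules)) "ε" else
    paste0("{", gsub("\n", "; ", sub("\n$", "", print_program(mp$base))), "}")
  for (s in mp$steps) {
    txt <- if (is.null(s$psi)) paste0("(", s$name, " ", txt, ")")
           else paste0("(", s$name, " ", txt, " ψ:", s$psi, ")")
  }
  txt
}

#' @rdname print_metaprogram
#' @param text metaprogram text
#' @param sig signature for the base program
#' @return `parse_metaprogram`: an `mpl_metaprogram`
#' @export
parse_metaprogram <- function(text, sig = sig_default()) {
  text <- trimws(text)
  steps <- list()
  # peel outer applications
  while (startsWith(text, "(")) {
    inner <- substr(text, 2L, nchar(text) - 1L)
    nm <- sub("\\s.*$", "", inner)
    if (!nm %in% MP_NAMES) stop("unknown metaprimitive: ", nm)
    rest <- trimws(substr(inner, nchar(nm) + 1L, nchar(inner)))
    psi <- NULL
    m <- regexpr("\\s*ψ:[0-9]+$", rest)
    if (m != -1L) {
      psi <- as.integer(sub("^.*ψ:", "", rest))
      rest <- trimws(substr(rest, 1L, m - 1L))
    }
    steps <- c(list(list(name = nm, psi = psi)), steps)
    text <- rest
  }
  base <- if (text == "ε" || text == "") program(sig = sig) else {
    if (!startsWith(text, "{")) stop("bad metaprogram base: ", text)
    parse_program(gsub(";", "\n", substr(text, 2L, nchar(text) - 1L)), sig = sig)
  }
  metaprogram(steps, base = base)
}

# --- shared helpers ---------------------------------------------------------

# canonical variable renaming: x1, x2, ... in order of first occurrence on
# the lhs then the rhs (simultaneous rename; compiled). Rules that came out
# of a previous canonicalization are flagged and skipped.
canon_rule <- function(r) {
  if (isTRUE(r$canon)) return(r)
  cc <- .mpl_canon_rule_cpp(r$lhs, r$rhs)
  if (identical(cc$lhs, r$lhs) && identical(cc$rhs, r$rhs)) {
    if (is.null(r$print)) r$print <- rule_print_compute(r$lhs, r$rhs)
    r$canon <- TRUE
    return(r)
  }
  structure(list(lhs = cc$lhs, rhs = cc$rhs,
                 print = rule_print_compute(cc$lhs, cc$rhs), canon = TRUE),
            class = "mpl_rule")
}

mk_program <- function(rules, p) {
  rules <- lapply(rules, canon_rule)
  program(rules, target = p$target, sig = p$sig)
}

rule_is_ground <- function(r) {
  length(term_vars(r$lhs)) == 0L && length(term_vars(r$rhs)) == 0L
}

# ground target rules whose lhs is target applied to a concrete list and
# whose rhs is a concrete list; returns indices
ground_list_rules <- function(p) program_memo(p, "ground_rules", ground_list_rules_compute)

ground_list_rules_compute <- function(p) {
  idx <- integer()
  for (i in seq_along(p$rules)) {
    r <- p$rules[[i]]
    if (r$lhs[[1L]] != p$target || length(r$lhs) != 2L) next
    if (is.null(term_to_vector(r$lhs[[2L]]))) next
    if (is.null(term_to_vector(r$rhs))) next
    idx <- c(idx, i)
  }
  idx
}

entails_pair <- function(p, x, y) {
  if (!length(p$rules)) return(FALSE)
  res <- evaluate_program_fast(p, x, MP_EVAL_FUEL)
  isTRUE(res$ok) && identical(res$value, as.integer(y))
}

fresh_symbol <- function(p) {
  n <- 1L
  repeat {
    nm <- paste0("G", n)
    if (is.na(sig_arity(p$sig, nm))) return(nm)
    n <- n + 1L
  }
}

# --- the eight metaprimitives ----------------------------------------------

#' Metaprimitive: memorize the whole dataset
#'
#' Appends, for each pair `(x, y)` in order, the ground rule `F x ≈ y`,
#' skipping pairs the program already entails (entailment is checked by
#' evaluation). Applying it twice is a no-op the second time.
#'
#' @param p a program
#' @param d a dataset
#' @return the extended program
#' @export
mp_memorize_all <- function(p, d) {
  rules <- p$rules
  q <- p
  for (pr in d) {
    if (entails_pair(q, pr$input, pr$output)) next
    rules <- c(rules, list(rule(list(p$target, t_list(pr$input)), t_list(pr$output))))
    q <- mk_program(rules, p)
  }
  q
}

#' Metaprimitive: memorize a single pair
#'
#' @param p a program
#' @param d a dataset
#' @param psi index of the pair to memorize
#' @return the extended program, or `NULL` if `psi` is out of range
#' @export
mp_memorize <- function(p, d, psi) {
  if (is.null(psi) || psi < 1L || psi > length(d)) return(NULL)
  pr <- d[[psi]]
  mk_program(c(p$rules, list(rule(list(p$target, t_list(pr$input)), t_list(pr$output)))), p)
}

#' Metaprimitive: delete a rule
#'
#' @param p a program
#' @param psi rule index
#' @return the program without that rule, or `NULL` if out of range
#' @export
mp_delete <- function(p, psi) {
  if (is.null(psi) || psi < 1L || psi > length(p$rules)) return(NULL)
  mk_program(p$rules[-psi], p)
}

# legal unroll arities: k such that every ground list rule satisfies
# |output| = k * |input|
recurse_legal_ks <- function(p) program_memo(p, "recurse_ks", recurse_legal_ks_compute)

recurse_legal_ks_compute <- function(p) {
  idx <- ground_list_rules(p)
  if (!length(idx)) return(integer())
  ins <- lapply(idx, function(i) term_to_vector(p$rules[[i]]$lhs[[2L]]))
  outs <- lapply(idx, function(i) term_to_vector(p$rules[[i]]$rhs))
  Filter(function(k) all(mapply(function(x, y) length(y) == k * length(x), ins, outs)),
         RECURSE_KS)
}

#' Metaprimitive: introduce elementwise recursion
#'
#' Selects an unroll arity `k` (ψ indexes the legal arities among 0..4, in
#' increasing order): each input element must explain exactly `k`
#' consecutive output elements in every memorized ground rule. Each such
#' rule `F [x0,...,xm] ≈ [y0,...,yn]` is replaced by its one-step unrolled
#' family `F [xj,...,xm] ≈ [y(kj),...,y(kj+k-1) | F [x(j+1),...,xm]]`
#' chained down to the base rule `F [] ≈ []`.
#'
#' @param p a program
#' @param psi index into the legal arities
#' @return the unrolled program, or `NULL` if inapplicable
#' @export
mp_recurse <- function(p, psi) {
  ks <- recurse_legal_ks(p)
  if (is.null(psi) || psi < 1L || psi > length(ks)) return(NULL)
  k <- ks[[psi]]
  idx <- ground_list_rules(p)
  seen <- character()
  out <- list()
  for (i in seq_along(p$rules)) {
    if (!i %in% idx) { out <- c(out, list(p$rules[[i]])); next }
    x <- term_to_vector(p$rules[[i]]$lhs[[2L]])
    y <- term_to_vector(p$rules[[i]]$rhs)
    m <- length(x)
    for (j in seq_len(m)) {
      lhs <- list(p$target, t_list(x[j:m]))
      ys <- if (k > 0L) y[(k * (j - 1L) + 1L):(k * j)] else integer()
      rest <- if (j < m) x[(j + 1L):m] else integer()
      # the k explained outputs, then the recursive call on the remainder
      rhs <- cons_append_call(ys, list(p$target, t_list(rest)))
      r <- rule(lhs, rhs)
      key <- print_rule(r)
      if (!key %in% seen) { seen <- c(seen, key); out <- c(out, list(r)) }
    }
  }
  base <- rule(list(p$target, list("nil")), list("nil"))
  if (!print_rule(base) %in% seen) out <- c(out, list(base))
  mk_program(out, p)
}

# build [y1, ..., yn | call]
cons_append_call <- function(ys, call) {
  t <- call
  for (v in rev(as.integer(ys))) t <- list("cons", v, t)
  t
}

#' Metaprimitive: generalize a slot into a variable
#'
#' ψ selects, in canonical order (rule order, then preorder of the
#' left-hand side), a distinct non-variable proper subterm of a rule's lhs;
#' every occurrence of that subterm in the rule (lhs and rhs) is replaced by
#' one fresh variable.
#'
#' @param p a program
#' @param psi option index
#' @return the generalized program, or `NULL` if inapplicable
#' @export
mp_variable <- function(p, psi) {
  opts <- variable_options(p)
  if (is.null(psi) || psi < 1L || psi > length(opts)) return(NULL)
  o <- opts[[psi]]
  r <- p$rules[[o$rule]]
  fresh <- "#v"
  r$lhs <- term_replace_all(r$lhs, o$sub, fresh)
  r$rhs <- term_replace_all(r$rhs, o$sub, fresh)
  # a selection that swallows variables still used on the rhs is inapplicable
  if (length(setdiff(term_vars(r$rhs), term_vars(r$lhs)))) return(NULL)
  rules <- p$rules
  rules[[o$rule]] <- rule(r$lhs, r$rhs)
  mk_program(rules, p)
}

variable_options <- function(p) program_memo(p, "variable_opts", variable_options_compute)

variable_options_compute <- function(p) {
  opts <- list()
  for (i in seq_along(p$rules)) {
    lhs <- p$rules[[i]]$lhs
    subs <- term_subterms(lhs)
    subs <- subs[-1L]                      # exclude the whole lhs
    seen <- character()
    for (s in subs) {
      if (is.character(s)) next            # variables: identity, not an option
      if (is.list(s) && length(s) == 1L && s[[1L]] == p$target) next
      key <- print_term(s)
      if (key %in% seen) next
      seen <- c(seen, key)
      opts <- c(opts, list(list(rule = i, sub = s)))
    }
  }
  opts
}

#' Metaprimitive: factor a right-hand-side subterm into a new function
#'
#' ψ selects (rule, rhs non-variable subterm position in preorder); the
#' subterm is abstracted into a fresh defined symbol applied to the
#' subterm's free variables, with a new rule defining that symbol. The
#' transformation is behavior-preserving.
#'
#' @param p a program
#' @param psi option index
#' @return the refactored program, or `NULL` if inapplicable
#' @export
mp_compose <- function(p, psi) {
  opts <- compose_options(p)
  if (is.null(psi) || psi < 1L || psi > length(opts)) return(NULL)
  o <- opts[[psi]]
  r <- p$rules[[o$rule]]
  s <- term_at_path(r$rhs, o$path)
  vs <- term_vars(s)
  g <- fresh_symbol(p)
  call <- c(list(g), lapply(vs, identity))
  new_rhs <- term_set_path(r$rhs, o$path, call)
  # type the fresh symbol concretely from the host rule's typing
  tys <- compose_types(p, r, o$path, vs)
  sig2 <- sig_define(p$sig, g, args = tys$args, ret = tys$ret)
  rules <- p$rules
  rules[[o$rule]] <- rule(r$lhs, new_rhs)
  defn <- rule(c(list(g), lapply(vs, identity)), s)
  rules <- append(rules, list(defn), after = o$rule)
  p2 <- p
  p2$sig <- sig2
  mk_program(rules, p2)
}

compose_options <- function(p) program_memo(p, "compose_opts", compose_options_compute)

# argument and result types for a composed-out subterm: walk the host
# rule's rhs top-down from the head scheme's result type
compose_types <- function(p, r, path, vs) {
  sch <- sig_scheme(p$sig, r$lhs[[1L]])
  pvars <- list()
  assign_types <- function(pat, ty) {
    if (is.character(pat)) {
      if (is.null(pvars[[pat]])) pvars[[pat]] <<- ty
      return(invisible(NULL))
    }
    if (!is.list(pat)) return(invisible(NULL))
    if (pat[[1L]] == "cons") { assign_types(pat[[2L]], "num"); assign_types(pat[[3L]], "list") }
  }
  for (i in seq_along(sch$args)) {
    aty <- sch$args[[i]]
    assign_types(r$lhs[[i + 1L]], if (identical(aty, "?")) "list" else aty)
  }
  walk_ty <- function(t, ty, pa) {
    if (!length(pa)) return(ty)
    sub_sch <- sig_scheme(p$sig, t[[1L]])
    if (is.null(sub_sch)) return("list")
    args <- lapply(sub_sch$args, instantiate_a, ty)
    if (t[[1L]] == "==") args <- list("num", "num")
    aty <- args[[pa[1L] - 1L]]
    if (identical(aty, "a") || identical(aty, "?")) aty <- "num"
    walk_ty(t[[pa[1L]]], aty, pa[-1L])
  }
  ret <- walk_ty(r$rhs, if (identical(sch$ret, "?")) "list" else sch$ret, path)
  args <- lapply(vs, function(v) { tv <- pvars[[v]]; if (is.null(tv)) "num" else tv })
  list(args = args, ret = if (is.list(ret)) "list" else ret)
}

compose_options_compute <- function(p) {
  opts <- list()
  for (i in seq_along(p$rules)) {
    paths <- term_paths(p$rules[[i]]$rhs)
    for (pa in paths) {
      s <- term_at_path(p$rules[[i]]$rhs, pa)
      if (is.character(s)) next
      opts <- c(opts, list(list(rule = i, path = pa)))
    }
  }
  opts
}

# preorder paths (integer vectors of child indices; integer(0) = root)
term_paths <- function(t) {
  acc <- list(integer())
  if (is.list(t)) {
    for (i in seq_along(t)[-1L]) {
      for (sub in term_paths(t[[i]])) acc <- c(acc, list(c(i, sub)))
    }
  }
  acc
}

term_at_path <- function(t, path) {
  for (i in path) t <- t[[i]]
  t
}

term_set_path <- function(t, path, new) {
  if (!length(path)) return(new)
  t[[path[1L]]] <- term_set_path(t[[path[1L]]], path[-1L], new)
  t
}

#' Metaprimitive: extract an aligned subproblem
#'
#' ψ selects a ground rule and an aligned pair of suffixes (a suffix of the
#' input list, a suffix of the output list); a fresh symbol G is defined by
#' the ground rule `G input-suffix ≈ output-suffix`, and the host rule's
#' right-hand side is rewritten to call G at that suffix. Later
#' metaprimitives may then generalize G.
#'
#' @param p a program
#' @param psi option index
#' @return the rewritten program, or `NULL` if inapplicable
#' @export
mp_subproblem <- function(p, psi) {
  opts <- subproblem_options(p)
  if (is.null(psi) || psi < 1L || psi > length(opts)) return(NULL)
  o <- opts[[psi]]
  r <- p$rules[[o$rule]]
  x <- term_to_vector(r$lhs[[2L]])
  y <- term_to_vector(r$rhs)
  a <- x[seq(o$ia, length(x))]
  b <- y[seq(o$ib, length(y))]
  g <- fresh_symbol(p)
  # replace the rhs suffix starting at position ib with (G a)
  path <- rep(3L, o$ib - 1L)
  new_rhs <- term_set_path(r$rhs, path, list(g, t_list(a)))
  sig2 <- sig_define(p$sig, g, args = list("list"), ret = "list")
  rules <- p$rules
  rules[[o$rule]] <- rule(r$lhs, new_rhs)
  rules <- append(rules, list(rule(list(g, t_list(a)), t_list(b))), after = o$rule)
  p2 <- p
  p2$sig <- sig2
  mk_program(rules, p2)
}

subproblem_options <- function(p) program_memo(p, "subproblem_opts", subproblem_options_compute)

subproblem_options_compute <- function(p) {
  opts <- list()
  for (i in ground_list_rules(p)) {
    x <- term_to_vector(p$rules[[i]]$lhs[[2L]])
    y <- term_to_vector(p$rules[[i]]$rhs)
    if (!length(x) || !length(y)) next
    for (ia in seq_along(x)) {
      for (ib in seq_along(y)) {
        opts <- c(opts, list(list(rule = i, ia = ia, ib = ib)))
      }
    }
  }
  opts
}

#' Metaprimitive: anti-unify similar rules
#'
#' Groups rules with the same head symbol by the root constructor of the
#' rule argument, and folds each group of two or more rules into a single
#' rule by pairwise least general generalization (left-associated over rule
#' order). A fold whose result would use right-hand-side variables not bound
#' on the left leaves that group unchanged; if no group folds, the
#' metaprimitive is inapplicable.
#'
#' @param p a program
#' @param d dataset (unused; present for the uniform reduction interface)
#' @return the generalized program, or `NULL` if inapplicable
#' @examples
#' d <- dataset(inputs = list(c(1, 3), c(2, 5)), outputs = list(c(3, 1), c(5, 2)))
#' p <- mp_memorize_all(program(), d)
#' print_program(mp_anti_unify(p))
#' @export
mp_anti_unify <- function(p, d = NULL) {
  rs <- p$rules
  if (length(rs) < 2L) return(NULL)
  keys <- vapply(seq_along(rs), function(i) {
    lhs <- rs[[i]]$lhs
    arg_key <- if (length(lhs) >= 2L) {
      a <- lhs[[2L]]
      if (is.list(a)) a[[1L]] else if (is.character(a)) "<var>" else "<lit>"
    } else "<none>"
    paste0(lhs[[1L]], "/", arg_key)
  }, "")
  groups <- split(seq_along(rs), keys)
  groups <- Filter(function(g) length(g) >= 2L, groups)
  if (!length(groups)) return(NULL)
  folded <- list()   # first-index -> new rule
  drop <- integer()
  any_folded <- FALSE
  for (g in groups) {
    g <- sort(g)
    acc <- list("rule", rs[[g[1L]]]$lhs, rs[[g[1L]]]$rhs)
    for (i in g[-1L]) {
      acc <- lgg(acc, list("rule", rs[[i]]$lhs, rs[[i]]$rhs), prefix = "w")$gen
    }
    new_lhs <- acc[[2L]]
    new_rhs <- acc[[3L]]
    if (length(setdiff(term_vars(new_rhs), term_vars(new_lhs)))) next
    folded[[as.character(g[1L])]] <- rule(new_lhs, new_rhs)
    drop <- c(drop, g[-1L])
    any_folded <- TRUE
  }
  if (!any_folded) return(NULL)
  out <- list()
  for (i in seq_along(rs)) {
    if (i %in% drop) next
    nm <- as.character(i)
    out <- c(out, list(if (!is.null(folded[[nm]])) folded[[nm]] else rs[[i]]))
  }
  mk_program(out, p)
}

# --- option counting and reduction ------------------------------------------

#' Canonical option list sizes for each metaprimitive
#'
#' Returns the number of legal ψ options for metaprimitive `name` applied to
#' program `p` with dataset `d` (0 for inapplicable; 1 for the ψ-free
#' metaprimitives when applicable).
#'
#' @param name metaprimitive name
#' @param p a program
#' @param d a dataset
#' @return integer count
#' @export
mp_n_options <- function(name, p, d) {
  switch(name,
    MemorizeAll = 1L,
    AntiUnify = 1L,
    Memorize = length(d),
    Recurse = length(recurse_legal_ks(p)),
    Delete = length(p$rules),
    Variable = length(variable_options(p)),
    Compose = length(compose_options(p)),
    Subproblem = length(subproblem_options(p))
  )
}

mp_apply <- function(name, p, d, psi) {
  switch(name,
    MemorizeAll = mp_memorize_all(p, d),
    AntiUnify = mp_anti_unify(p, d),
    Memorize = mp_memorize(p, d, psi),
    Recurse = mp_recurse(p, psi),
    Delete = mp_delete(p, psi),
    Variable = mp_variable(p, psi),
    Compose = mp_compose(p, psi),
    Subproblem = mp_subproblem(p, psi)
  )
}

#' Reduce a metaprogram to a program
#'
#' Applies the metaprogram's steps left to right (innermost first),
#' threading the program through each metaprimitive. Reduction is
#' deterministic given the ψ tokens. It fails -- returning `NULL` -- if any
#' step is inapplicable, any ψ is out of range, or the final program is not
#' deterministic as a rewrite system.
#'
#' @param mp a metaprogram
#' @param d a dataset
#' @return the reduced `mpl_program`, or `NULL` on failure
#' @examples
#' d <- dataset(inputs = list(c(1, 3, 9, 7)), outputs = list(c(1, 1, 3, 3, 9, 9, 7, 7)))
#' mp <- metaprogram(c("MemorizeAll", "AntiUnify"))
#' reduce_metaprogram(mp, d)
#' @export
reduce_metaprogram <- function(mp, d) {
  tr <- reduce_metaprogram_trace(mp, d)
  if (tr$ok) tr$program else NULL
}

# Full reduction trace: per-step option counts feed the metaprogram prior
# (each ψ contributes log 1/n_options).
reduce_metaprogram_trace <- function(mp, d) {
  p <- mp$base
  n_opts <- integer()
  log_psi <- 0
  n_psi <- 0L
  for (s in mp$steps) {
    k <- mp_n_options(s$name, p, d)
    if (k < 1L) return(list(ok = FALSE, why = paste0(s$name, ": no legal options")))
    if (MP_TAKES_PSI[[s$name]]) {
      if (is.null(s$psi) || s$psi < 1L || s$psi > k) {
        return(list(ok = FALSE, why = paste0(s$name, ": ψ out of range")))
      }
      log_psi <- log_psi - log(k)
      n_psi <- n_psi + 1L
    }
    p2 <- mp_apply(s$name, p, d, s$psi)
    if (is.null(p2)) return(list(ok = FALSE, why = paste0(s$name, ": inapplicable")))
    n_opts <- c(n_opts, k)
    p <- p2
  }
  if (!is_deterministic(p)) return(list(ok = FALSE, why = "nondeterministic TRS"))
  list(ok = TRUE, program = p, n_options = n_opts, log_psi = log_psi, n_psi = n_psi)
}
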