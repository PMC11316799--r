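# Grammar-based priors over programs and metaprograms, and the matching
# samplers.
#
# Both priors are type-constrained grammars with uniform production
# probabilities over the type-legal options at each choice point. The
# program prior p_P derives an ordered rule list (geometric stop, 1/2 per
# decision), each rule as a typed lhs pattern plus a typed rhs term. The
# metaprogram prior p_M derives a chain of metaprimitive steps ending in a
# base (ε or an explicit program), with each random-choice token ψ
# contributing log(1/|options|) for the option set at its application point
# -- which depends on the data, making the grammar context-sensitive.
#
# A single option-enumeration routine backs sampling, prior scoring, and
# enumeration, so densities are exact for Metropolis-Hastings corrections.

#' Construct the default grammar
#'
#' @param sig signature (defaults to [sig_default()])
#' @param max_depth depth cap for term derivations; deeper structure has
#'   zero prior mass. The default 18 covers the deepest term a memorized
#'   15-element list can produce (a 16-deep cons chain) while keeping the
#'   truncated grammar's expected derivation size moderate.
#' @param n_numerals size of the numeral family (uniform within the family)
#' @param sample_max_nodes node budget for the samplers: a draw whose term
#'   grows past this many nodes is abandoned (the grammar is supercritical,
#'   so unbounded draws have a heavy size tail)
#' @param mp_names metaprimitive names available to the metaprogram grammar
#'   (restrict to study truncated spaces)
#' @param program_base whether the metaprogram grammar includes the
#'   explicit-program base production in addition to ε
#' @return an object of class `mpl_grammar`
#' @export
grammar <- function(sig = sig_default(), max_depth = 18L, n_numerals = 100L,
                    sample_max_nodes = 120L, mp_names = MP_NAMES,
                    program_base = TRUE) {
  structure(list(sig = sig, max_depth = max_depth, n_numerals = n_numerals,
                 sample_max_nodes = sample_max_nodes,
                 mp_names = mp_names, program_base = program_base,
                 n_level_options = length(mp_names) + 1L + as.integer(program_base),
                 cache = new.env(parent = emptyenv())),
            class = "mpl_grammar")
}

ty_key <- function(ty) if (is.list(ty)) paste0(ty_key(ty[[2L]]), "->", ty_key(ty[[3L]])) else ty

ty_matches <- function(have, want) identical(have, want) || identical(have, "?")

# Atom options at an arrow type: unary symbols whose argument/result types
# instantiate to the requested arrow.
atom_options <- function(g, dom, cod) {
  out <- character()
  all_ops <- c(g$sig$ops, g$sig$defined)
  for (nm in names(all_ops)) {
    sch <- all_ops[[nm]]
    if (length(sch$args) != 1L) next
    a <- sch$args[[1L]]; r <- sch$ret
    if (identical(a, "a") && identical(r, "a")) { out <- c(out, nm); next }
    if (is.list(a) || is.list(r)) next
    if (ty_matches(a, dom) && ty_matches(r, cod)) out <- c(out, nm)
  }
  out
}

# Canonical option list for a term derivation at type `ty` with variables
# `scope` (named list var -> type) at depth `depth`. Each option is
# list(kind, ...); kinds: var, num, bool, op (with arg types), atom.
# Memoized per (type, scope shape, depth regime, defined symbols).
term_options <- function(g, ty, scope, depth) {
  key <- paste(ty_key(ty), depth < g$max_depth,
               paste(names(scope), unlist(scope, use.names = FALSE), collapse = ","),
               paste(names(g$sig$defined), collapse = ","), sep = "|")
  hit <- g$cache[[key]]
  if (!is.null(hit)) return(hit)
  opts <- term_options_compute(g, ty, scope, depth)
  g$cache[[key]] <- opts
  opts
}

term_options_compute <- function(g, ty, scope, depth) {
  opts <- list()
  if (is.list(ty)) {  # arrow type: symbol atoms only
    for (nm in atom_options(g, ty[[2L]], ty[[3L]])) {
      opts <- c(opts, list(list(kind = "atom", name = nm)))
    }
    return(opts)
  }
  for (v in names(scope)) {
    if (ty_matches(scope[[v]], ty)) opts <- c(opts, list(list(kind = "var", name = v)))
  }
  if (ty == "num") opts <- c(opts, list(list(kind = "num")))
  if (ty == "bool") opts <- c(opts, list(list(kind = "bool", value = TRUE)),
                              list(list(kind = "bool", value = FALSE)))
  deep <- depth < g$max_depth
  all_ops <- c(g$sig$ops, g$sig$defined)
  for (nm in names(all_ops)) {
    sch <- all_ops[[nm]]
    nargs <- length(sch$args)
    ret <- sch$ret
    poly <- identical(ret, "a")
    if (!poly && !ty_matches(ret, ty)) next
    if (nargs == 0L) {  # nullary constructor (nil): a terminal
      opts <- c(opts, list(list(kind = "op", name = nm, args = list())))
      next
    }
    if (!deep) next
    args <- sch$args
    if (poly) args <- lapply(args, instantiate_a, ty)
    else args <- lapply(args, function(a) if (identical(a, "a")) "num" else instantiate_a(a, ty))
    if (nm == "==") args <- list("num", "num")   # fixed instantiation
    if (nm == "fix" && !length(atom_options(g, ty, ty))) next
    if (identical(ret, "?")) { }                  # opportunistically typed aux symbol
    opts <- c(opts, list(list(kind = "op", name = nm, args = args)))
  }
  opts
}

instantiate_a <- function(a, ty) {
  if (is.list(a)) return(list("->", instantiate_a(a[[2L]], ty), instantiate_a(a[[3L]], ty)))
  if (identical(a, "a")) ty else a
}

# --- term sampling and scoring ---------------------------------------------

#' Sample a term from the type-directed grammar
#'
#' @param g a grammar
#' @param ty requested type (`"num"`, `"bool"`, `"list"`)
#' @param scope named list of in-scope variables and their types
#' @param depth starting depth (used when regenerating a subtree in place)
#' @param budget internal node-budget counter; a draw exceeding the
#'   grammar's `sample_max_nodes` returns `NULL`
#' @return a term, or `NULL` if no option exists or the budget is exhausted
#' @export
sample_term <- function(g, ty = "list", scope = list(), depth = 0L, budget = NULL) {
  if (is.null(budget)) {
    budget <- new.env(parent = emptyenv())
    budget$n <- g$sample_max_nodes
  }
  sample_term_tab(g, options_tab(g, scope), ty, scope, depth, budget)
}

# the variable scope is fixed throughout a term derivation, so the option
# lists for the three base types (x shallow/deep) can be looked up once per
# call instead of per node
options_tab <- function(g, scope) {
  list(deep = list(num = term_options(g, "num", scope, 0L),
                   bool = term_options(g, "bool", scope, 0L),
                   list = term_options(g, "list", scope, 0L)),
       shallow = list(num = term_options(g, "num", scope, g$max_depth),
                      bool = term_options(g, "bool", scope, g$max_depth),
                      list = term_options(g, "list", scope, g$max_depth)))
}

tab_options <- function(g, tab, ty, scope, depth) {
  if (is.list(ty)) return(term_options(g, ty, scope, depth))   # arrow types
  if (depth < g$max_depth) tab$deep[[ty]] else tab$shallow[[ty]]
}

sample_term_tab <- function(g, tab, ty, scope, depth, budget) {
  budget$n <- budget$n - 1L
  if (budget$n < 0L) return(NULL)
  opts <- tab_options(g, tab, ty, scope, depth)
  if (!length(opts)) return(NULL)
  o <- opts[[.mpl_sample1(length(opts))]]
  switch(o$kind,
    var = o$name,
    num = as.integer(.mpl_sample1(g$n_numerals) - 1L),
    bool = o$value,
    atom = list(o$name),
    op = {
      t <- list(o$name)
      for (a in o$args) {
        sub <- sample_term_tab(g, tab, a, scope, depth + 1L, budget)
        if (is.null(sub)) return(NULL)
        t <- c(t, list(sub))
      }
      t
    })
}

# log-probability (and number of uniform choices) of deriving term t;
# logp = -Inf when t is not derivable at this type/depth.
term_cost <- function(g, t, ty, scope, depth) {
  term_cost_tab(g, options_tab(g, scope), t, ty, scope, depth)
}

term_cost_tab <- function(g, tab, t, ty, scope, depth) {
  opts <- tab_options(g, tab, ty, scope, depth)
  n <- length(opts)
  if (!n) return(list(logp = -Inf, n_choices = 0L))
  if (is.character(t)) {
    hit <- any(vapply(opts, function(o) o$kind == "var" && o$name == t, TRUE))
    return(list(logp = if (hit) -log(n) else -Inf, n_choices = 1L))
  }
  if (is.logical(t)) {
    hit <- any(vapply(opts, function(o) o$kind == "bool" && identical(o$value, t), TRUE))
    return(list(logp = if (hit) -log(n) else -Inf, n_choices = 1L))
  }
  if (!is.list(t)) {  # numeral or nan: the numeral family, then 1/n_numerals
    hit <- any(vapply(opts, function(o) o$kind == "num", TRUE))
    return(list(logp = if (hit) -log(n) - log(g$n_numerals) else -Inf, n_choices = 2L))
  }
  nm <- t[[1L]]
  if (length(t) == 1L && is.na(sig_arity(g$sig, nm))) return(list(logp = -Inf, n_choices = 0L))
  if (length(t) == 1L && sig_arity(g$sig, nm) > 0L) {  # atom
    hit <- any(vapply(opts, function(o) o$kind == "atom" && o$name == nm, TRUE))
    return(list(logp = if (hit) -log(n) else -Inf, n_choices = 1L))
  }
  sel <- NULL
  for (o in opts) if (o$kind == "op" && o$name == nm) { sel <- o; break }
  if (is.null(sel) || length(sel$args) != length(t) - 1L) {
    return(list(logp = -Inf, n_choices = 0L))
  }
  logp <- -log(n)
  nch <- 1L
  for (i in seq_along(sel$args)) {
    sub <- term_cost_tab(g, tab, t[[i + 1L]], sel$args[[i]], scope, depth + 1L)
    if (!is.finite(sub$logp)) return(list(logp = -Inf, n_choices = 0L))
    logp <- logp + sub$logp
    nch <- nch + sub$n_choices
  }
  list(logp = logp, n_choices = nch)
}

# --- lhs patterns -----------------------------------------------------------

# options for a pattern node at type ty given already-bound pattern vars
pattern_options <- function(g, ty, pvars) {
  opts <- list(list(kind = "fresh"))
  for (v in names(pvars)) if (identical(pvars[[v]], ty)) {
    opts <- c(opts, list(list(kind = "var", name = v)))
  }
  if (ty == "list") opts <- c(opts,
    list(list(kind = "op", name = "nil", args = list())),
    list(list(kind = "op", name = "cons", args = list("num", "list"))))
  if (ty == "num") opts <- c(opts, list(list(kind = "num")))
  if (ty == "bool") opts <- c(opts, list(list(kind = "bool", value = TRUE)),
                              list(list(kind = "bool", value = FALSE)))
  opts
}

sample_pattern <- function(g, ty, pvars, depth = 0L) {
  opts <- pattern_options(g, ty, pvars)
  deep <- depth < g$max_depth
  if (!deep) opts <- Filter(function(o) !(o$kind == "op" && length(o$args)), opts)
  o <- opts[[.mpl_sample1(length(opts))]]
  switch(o$kind,
    fresh = {
      v <- paste0("x", length(pvars) + 1L)
      pvars[[v]] <- ty
      list(pat = v, pvars = pvars)
    },
    var = list(pat = o$name, pvars = pvars),
    num = list(pat = as.integer(.mpl_sample1(g$n_numerals) - 1L), pvars = pvars),
    bool = list(pat = o$value, pvars = pvars),
    op = {
      pat <- list(o$name)
      for (a in o$args) {
        sub <- sample_pattern(g, a, pvars, depth + 1L)
        pat <- c(pat, list(sub$pat))
        pvars <- sub$pvars
      }
      list(pat = pat, pvars = pvars)
    })
}

pattern_cost <- function(g, pat, ty, pvars, depth = 0L) {
  opts <- pattern_options(g, ty, pvars)
  n <- length(opts)
  if (is.character(pat)) {
    if (!is.null(pvars[[pat]])) {  # reuse
      hit <- any(vapply(opts, function(o) o$kind == "var" && o$name == pat, TRUE))
      return(list(logp = if (hit) -log(n) else -Inf, n_choices = 1L, pvars = pvars))
    }
    pvars[[pat]] <- ty  # fresh
    return(list(logp = -log(n), n_choices = 1L, pvars = pvars))
  }
  if (is.logical(pat)) return(list(logp = -log(n), n_choices = 1L, pvars = pvars))
  if (!is.list(pat)) {
    return(list(logp = -log(n) - log(g$n_numerals), n_choices = 2L, pvars = pvars))
  }
  nm <- pat[[1L]]
  sel <- NULL
  for (o in opts) if (o$kind == "op" && o$name == nm) { sel <- o; break }
  if (is.null(sel)) return(list(logp = -Inf, n_choices = 0L, pvars = pvars))
  logp <- -log(n)
  nch <- 1L
  for (i in seq_along(sel$args)) {
    sub <- pattern_cost(g, pat[[i + 1L]], sel$args[[i]], pvars, depth + 1L)
    if (!is.finite(sub$logp)) return(list(logp = -Inf, n_choices = 0L, pvars = pvars))
    logp <- logp + sub$logp
    nch <- nch + sub$n_choices
    pvars <- sub$pvars
  }
  list(logp = logp, n_choices = nch, pvars = pvars)
}

# --- programs ---------------------------------------------------------------

#' Sample a program from the grammar
#'
#' Rules are derived with a geometric stopping decision (probability 1/2 of
#' adding another rule); each rule has a typed left-hand-side pattern for
#' the target symbol and a right-hand-side term over the pattern's
#' variables.
#'
#' @param g a grammar
#' @param max_rules hard cap on sampled rules (derivations beyond it are
#'   abandoned and resampled from the stop decision)
#' @return an `mpl_program`
#' @export
sample_program <- function(g, max_rules = 6L) {
  rules <- list()
  heads <- names(g$sig$defined)
  while (length(rules) < max_rules && .mpl_sample1(2L) == 1L) {
    head <- heads[[.mpl_sample1(length(heads))]]
    sch <- g$sig$defined[[head]]
    pvars <- list()
    lhs <- list(head)
    for (a in sch$args) {
      sub <- sample_pattern(g, resolve_unknown(a), pvars)
      lhs <- c(lhs, list(sub$pat))
      pvars <- sub$pvars
    }
    rhs <- sample_term(g, resolve_unknown(sch$ret), pvars)
    if (is.null(rhs)) next
    if (length(setdiff(term_vars(rhs), term_vars(lhs)))) next  # containment by construction of scope
    rules <- c(rules, list(rule(lhs, rhs)))
  }
  mk_program(rules, program(sig = g$sig))
}

resolve_unknown <- function(ty) if (identical(ty, "?")) "list" else ty

#' Program prior
#'
#' Log-probability of deriving `p` from the type-constrained program
#' grammar: geometric rule-count decisions, a head-symbol choice per rule,
#' the lhs pattern derivation, and the rhs term derivation. Returns `-Inf`
#' for programs outside the grammar (e.g. deeper than the grammar's depth
#' cap).
#'
#' @param p a program
#' @param g a grammar; its signature is widened automatically to cover the
#'   program's own defined symbols
#' @return log-probability (a single number)
#' @examples
#' program_log_prior(parse_program("F [] = []\nF [x | y] = [x, x | (F y)]"), grammar())
#' @export
program_log_prior <- function(p, g = grammar()) {
  program_cost(p, g)$logp
}

program_cost <- function(p, g = grammar()) {
  program_memo(p, "pcost", function(p) program_cost_compute(p, g))
}

program_cost_compute <- function(p, g) {
  g$sig <- p$sig  # symbols introduced by metaprimitives take part in the grammar
  heads <- names(g$sig$defined)
  logp <- -log(2) * (length(p$rules) + 1L)   # continue/stop decisions
  nch <- length(p$rules) + 1L
  head_choice <- -log(length(heads))
  defined_key <- paste(heads, collapse = ",")
  for (r in p$rules) {
    # rule derivations are independent given the head scheme; cache by the
    # rule's canonical print (programs share most rules with their
    # neighbours in search)
    rk <- paste0("RC|", print_rule(r), "|", defined_key)
    hit <- g$cache[[rk]]
    if (is.null(hit)) {
      hit <- rule_cost(r, g)
      g$cache[[rk]] <- hit
    }
    if (!is.finite(hit$logp)) return(list(logp = -Inf, n_choices = 0L))
    logp <- logp + head_choice + hit$logp
    nch <- nch + 1L + hit$n_choices
  }
  list(logp = logp, n_choices = nch)
}

rule_cost <- function(r, g) {
  head <- r$lhs[[1L]]
  sch <- g$sig$defined[[head]]
  if (is.null(sch) || length(sch$args) != length(r$lhs) - 1L) {
    return(list(logp = -Inf, n_choices = 0L))
  }
  logp <- 0
  nch <- 0L
  pvars <- list()
  for (i in seq_along(sch$args)) {
    sub <- pattern_cost(g, r$lhs[[i + 1L]], resolve_unknown(sch$args[[i]]), pvars)
    if (!is.finite(sub$logp)) return(list(logp = -Inf, n_choices = 0L))
    logp <- logp + sub$logp
    nch <- nch + sub$n_choices
    pvars <- sub$pvars
  }
  sub <- term_cost(g, r$rhs, resolve_unknown(sch$ret), pvars, 0L)
  if (!is.finite(sub$logp)) return(list(logp = -Inf, n_choices = 0L))
  list(logp = logp + sub$logp, n_choices = nch + sub$n_choices)
}

# --- metaprograms -----------------------------------------------------------

#' Metaprogram prior
#'
#' Log-probability of the metaprogram's derivation: one uniform choice per
#' level (a metaprimitive, or one of the two base productions at the end),
#' the base program's derivation when explicit, and `log(1/|options|)` per
#' random-choice token ψ at its application point. The option sets are
#' computed from the data via the reduction trace, so an irreducible
#' metaprogram scores `-Inf`.
#'
#' @param mp a metaprogram
#' @param g a grammar
#' @param d the dataset the metaprogram is reduced against
#' @return log-probability
#' @export
mp_log_prior <- function(mp, g, d) {
  mp_cost(mp, g, d)$logp
}

mp_cost <- function(mp, g, d, trace = NULL) {
  for (s in mp$steps) {
    if (!s$name %in% g$mp_names) return(list(logp = -Inf, n_choices = 0L))
  }
  logp <- -log(g$n_level_options) * (length(mp$steps) + 1L)
  nch <- length(mp$steps) + 1L
  if (length(mp$base$rules)) {
    if (!g$program_base) return(list(logp = -Inf, n_choices = 0L))
    sub <- program_cost(mp$base, g)
    if (!is.finite(sub$logp)) return(list(logp = -Inf, n_choices = 0L))
    logp <- logp + sub$logp
    nch <- nch + sub$n_choices
  }
  if (is.null(trace)) trace <- reduce_metaprogram_trace(mp, d)
  if (!trace$ok) return(list(logp = -Inf, n_choices = nch + 0L))
  list(logp = logp + trace$log_psi, n_choices = nch + trace$n_psi, trace = trace)
}

#' Sample a metaprogram from the grammar
#'
#' Derives the step chain top-down (uniform over the ten level options,
#' truncated at 7 steps), samples an explicit base program when that
#' production is drawn, and then assigns each ψ uniformly over its legal
#' options during reduction. Returns `NULL` when the sampled structure is
#' irreducible against `d`.
#'
#' @param g a grammar
#' @param d a dataset
#' @return an `mpl_metaprogram` (with valid ψ tokens), or `NULL`
#' @export
sample_metaprogram <- function(g, d) {
  nn <- length(g$mp_names)
  n_base <- 1L + as.integer(g$program_base)
  names <- character()
  repeat {
    if (length(names) >= MAX_MP_STEPS) { base_kind <- .mpl_sample1(n_base); break }
    k <- .mpl_sample1(g$n_level_options)
    if (k <= nn) { names <- c(g$mp_names[k], names); next }  # prepend: outer levels first
    base_kind <- k - nn
    break
  }
  base <- if (base_kind == 1L) program(sig = g$sig) else sample_program(g)
  steps <- lapply(names, function(nm) list(name = nm))
  mp_assign_psis(metaprogram(steps, base = base), d)
}

# walk the reduction, sampling each ψ uniformly from its legal options
mp_assign_psis <- function(mp, d) {
  p <- mp$base
  for (i in seq_along(mp$steps)) {
    nm <- mp$steps[[i]]$name
    k <- mp_n_options(nm, p, d)
    if (k < 1L) return(NULL)
    if (MP_TAKES_PSI[[nm]]) mp$steps[[i]]$psi <- .mpl_sample1(k)
    p <- mp_apply(nm, p, d, mp$steps[[i]]$psi)
    if (is.null(p)) return(NULL)
  }
  mp
}
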