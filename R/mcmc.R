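# Metropolis-Hastings search over metaprograms with parallel tempering,
# dual pools (full language vs object-level only), and the online
# trial-by-trial protocol.
#
# A search step is one proposal + accept decision on one chain. The full
# pool proposes: base resampling, step insertion, step removal, and ψ
# regeneration, with exact Hastings corrections computed from the option
# counts. The object pool searches base-only hypotheses (plain programs)
# with whole-program resampling and typed subtree regeneration, the
# tree-regeneration move of MCMC over programs.
#
# Wall-clock schedules in the source procedure (swap proposals, temperature
# adaptation) are replaced by deterministic step-based schedules so that
# (seed, config) reproduces a run bit-for-bit.

#' Search parameters
#'
#' @param steps_per_trial search steps per trial (one proposal on one chain)
#' @param alpha probability of advancing the full-language pool at each
#'   step (1 = metaprogram search only; 0 = object-level search only)
#' @param n_chains tempered chains per pool
#' @param swap_interval steps between replica-exchange sweeps
#' @param top_k retained top-scoring hypotheses
#' @param prior_mode `"full"`, `"pm"`, or `"pp"` (prior lesions)
#' @param eta,N likelihood noise rate and alphabet size
#' @param eval_fuel work budget per candidate evaluation during search
#'   (passed to [evaluate_program_fast()])
#' @param max_steps metaprimitive step bound per metaprogram
#' @return a list of class `mpl_search_params`
#' @export
search_params <- function(steps_per_trial = 5000L, alpha = 1.0, n_chains = 5L,
                          swap_interval = 250L, top_k = 100L,
                          prior_mode = "full", eta = 1e-6, N = 100L,
                          eval_fuel = 3000L, max_steps = MAX_MP_STEPS) {
  structure(list(steps_per_trial = as.integer(steps_per_trial), alpha = alpha,
                 n_chains = as.integer(n_chains),
                 swap_interval = as.integer(swap_interval),
                 top_k = as.integer(top_k), prior_mode = prior_mode,
                 lik = likelihood_params(eta, N), eval_fuel = as.integer(eval_fuel),
                 max_steps = as.integer(max_steps)),
            class = "mpl_search_params")
}

# --- cached scoring ---------------------------------------------------------

new_caches <- function() {
  ids <- new.env(parent = emptyenv())
  ids$n <- 0L
  list(score = new.env(parent = emptyenv()),   # (mp key, |d|) -> mpl_score
       eval = new.env(parent = emptyenv()),    # (program id, input) -> value/failure
       trace = new.env(parent = emptyenv()),   # (prefix key, |d|) -> reduction level
       det = new.env(parent = emptyenv()),     # program id -> is_deterministic
       ids = ids)                              # program key -> short id
}

# short interned id for a program (long canonical keys make cache lookups
# pay per-character; the id is memoized on the program itself)
program_sid <- function(caches, p) {
  sid <- p$memo$sid
  if (!is.null(sid)) return(sid)
  key <- program_key(p)
  sid <- caches$ids[[key]]
  if (is.null(sid)) {
    caches$ids$n <- caches$ids$n + 1L
    sid <- as.character(caches$ids$n)
    caches$ids[[key]] <- sid
  }
  p$memo$sid <- sid
  sid
}

# incremental reduction: metaprogram prefixes are cached per dataset size,
# so a proposal that shares a prefix with anything seen before only applies
# its new suffix steps
cached_trace <- function(caches, mp, d, check_det = TRUE) {
  n <- length(mp$steps)
  dl <- as.character(length(d))
  txt <- if (!length(mp$base$rules)) "ε" else program_key(mp$base)
  keys <- character(n + 1L)
  keys[1L] <- paste0(txt, "\u1f", dl)
  for (i in seq_len(n)) {
    s <- mp$steps[[i]]
    txt <- if (is.null(s$psi)) paste0("(", s$name, " ", txt, ")")
           else paste0("(", s$name, " ", txt, " \u3c8:", s$psi, ")")
    keys[i + 1L] <- paste0(txt, "\u1f", dl)
  }
  # find the deepest cached level
  lev <- NULL
  start <- 0L
  for (i in rev(seq_len(n + 1L))) {
    hit <- caches$trace[[keys[i]]]
    if (!is.null(hit)) { lev <- hit; start <- i - 1L; break }
  }
  if (is.null(lev)) {
    lev <- list(ok = TRUE, program = mp$base, log_psi = 0, n_psi = 0L,
                n_options = integer())
    caches$trace[[keys[1L]]] <- lev
    start <- 0L
  }
  if (!lev$ok) return(lev)
  i <- start + 1L
  while (i <= n && lev$ok) {
    s <- mp$steps[[i]]
    k <- mp_n_options(s$name, lev$program, d)
    lev <- if (k < 1L) {
      list(ok = FALSE, why = paste0(s$name, ": no legal options"))
    } else if (MP_TAKES_PSI[[s$name]] && (is.null(s$psi) || s$psi < 1L || s$psi > k)) {
      list(ok = FALSE, why = paste0(s$name, ": \u3c8 out of range"))
    } else {
      p2 <- mp_apply(s$name, lev$program, d, s$psi)
      if (is.null(p2)) list(ok = FALSE, why = paste0(s$name, ": inapplicable"))
      else list(ok = TRUE, program = p2,
                log_psi = lev$log_psi - (if (MP_TAKES_PSI[[s$name]]) log(k) else 0),
                n_psi = lev$n_psi + (if (MP_TAKES_PSI[[s$name]]) 1L else 0L),
                n_options = c(lev$n_options, k))
    }
    caches$trace[[keys[i + 1L]]] <- lev
    i <- i + 1L
  }
  if (!lev$ok || !check_det) return(lev)
  pk <- program_sid(caches, lev$program)
  det <- caches$det[[pk]]
  if (is.null(det)) {
    det <- is_deterministic(lev$program)
    caches$det[[pk]] <- det
  }
  if (!det) return(list(ok = FALSE, why = "nondeterministic TRS"))
  lev
}

eval_cached <- function(caches, prog, input, sp) {
  key <- paste0(program_sid(caches, prog), "\u1f", paste(input, collapse = ","))
  hit <- caches$eval[[key]]
  if (!is.null(hit)) return(hit)
  out <- evaluate_program_fast(prog, input, sp$eval_fuel)
  caches$eval[[key]] <- out
  out
}

score_cached <- function(caches, mp, d, g, sp, key = NULL) {
  if (is.null(key)) key <- print_metaprogram(mp)
  ck <- paste0(key, "\u1f", length(d))
  hit <- caches$score[[ck]]
  if (!is.null(hit)) return(hit)
  sc <- score_hypothesis_fast(caches, mp, d, g, sp)
  sc$key <- key
  caches$score[[ck]] <- sc
  sc
}

# as score_hypothesis(), but with the evaluation cache threaded through
score_hypothesis_fast <- function(caches, mp, d, g, sp) {
  bad <- list(ok = FALSE, lpm = -Inf, lpp = -Inf, llik = -Inf, lprior = -Inf,
              lpost = -Inf, n_choices = NA_integer_, program = NULL, mp = mp)
  trace <- cached_trace(caches, mp, d)
  if (!trace$ok) return(bad)
  mc <- mp_cost(mp, g, d, trace = trace)
  if (!is.finite(mc$logp) || mc$n_choices > MAX_MP_CHOICES) return(bad)
  prog <- trace$program
  pk <- program_sid(caches, prog)
  lpp <- caches$score[[paste0("\u1fPP", pk)]]
  if (is.null(lpp)) {
    lpp <- program_log_prior(prog, g)
    caches$score[[paste0("\u1fPP", pk)]] <- lpp
  }
  if (!is.finite(lpp)) return(bad)
  llik <- 0
  for (pr in d) {
    res <- eval_cached(caches, prog, pr$input, sp)
    llik <- llik + pair_log_likelihood(res, pr$output, sp$lik)
  }
  lprior <- combined_log_prior(mc$logp, lpp, sp$prior_mode)
  list(ok = TRUE, lpm = mc$logp, lpp = lpp, llik = llik, lprior = lprior,
       lpost = llik + lprior, n_choices = mc$n_choices, program = prog, mp = mp)
}

# --- archive ----------------------------------------------------------------

archive_add <- function(state, sc) {
  if (!isTRUE(sc$ok) || !is.finite(sc$lpost)) return(invisible(NULL))
  if (!is.null(state$archive[[sc$key]])) {
    state$archive[[sc$key]]$lpost <- sc$lpost  # refresh under current data
    return(invisible(NULL))
  }
  state$archive[[sc$key]] <- sc
  state$archive_n <- state$archive_n + 1L
  if (state$archive_n > 2L * state$top_k) archive_prune(state)
  invisible(NULL)
}

archive_prune <- function(state) {
  keys <- ls(state$archive)
  scores <- vapply(keys, function(k) state$archive[[k]]$lpost, 0)
  keep <- keys[order(scores, decreasing = TRUE)][seq_len(min(state$top_k, length(keys)))]
  drop <- setdiff(keys, keep)
  rm(list = drop, envir = state$archive)
  state$archive_n <- length(keep)
}

archive_best <- function(state) {
  keys <- sort(ls(state$archive))
  if (!length(keys)) return(NULL)
  best <- NULL
  for (k in keys) {
    sc <- state$archive[[k]]
    if (is.null(best) ||
        sc$lpost > best$lpost + 1e-12 ||
        (abs(sc$lpost - best$lpost) <= 1e-12 &&
         length(sc$mp$steps) < length(best$mp$steps))) {
      best <- sc
    }
  }
  best
}

# --- proposals --------------------------------------------------------------

# reduce the base plus the first u steps; NULL if that prefix fails
reduce_prefix <- function(caches, mp, u, d) {
  mp$steps <- mp$steps[seq_len(u)]
  tr <- cached_trace(caches, mp, d, check_det = FALSE)
  if (tr$ok) tr$program else NULL
}

n_moves_full <- function(mp) {
  s <- length(mp$steps)
  has_psi <- any(vapply(mp$steps, function(x) !is.null(x$psi), TRUE))
  1L + 1L + (s > 0L) + has_psi   # regen-base, insert, remove, regen-psi
}

sample_base <- function(g) {
  if (.mpl_sample1(2L) == 1L) program(sig = g$sig) else sample_program(g)
}

base_log_density <- function(base, g) {
  if (!length(base$rules)) return(-log(2))
  co <- program_cost(base, g)
  if (!is.finite(co$logp)) return(-Inf)
  -log(2) + co$logp
}

# Sample a fresh inner metaprogram (base + up to `budget` steps) against
# data, assigning ψ tokens as the partial reduction proceeds. Returns
# list(base, steps, logdens) or NULL on a dead end. The density accounts for
# every uniform choice: one 10-way choice per level (8 metaprimitives + two
# base productions; 2-way when the step budget is exhausted), the base
# program's derivation when explicit, and log(1/k) per assigned ψ.
sample_inner <- function(caches, g, d, budget) {
  nn <- length(g$mp_names)
  n_base <- 1L + as.integer(g$program_base)
  logdens <- 0
  names <- character()
  repeat {
    if (length(names) >= budget) {
      k <- .mpl_sample1(n_base)
      logdens <- logdens - log(n_base)
      base_kind <- k
      break
    }
    k <- .mpl_sample1(g$n_level_options)
    logdens <- logdens - log(g$n_level_options)
    if (k <= nn) { names <- c(g$mp_names[k], names); next }
    base_kind <- k - nn
    break
  }
  if (base_kind == 1L) {
    base <- program(sig = g$sig)
  } else {
    base <- sample_program(g)
    co <- program_cost(base, g)
    if (!is.finite(co$logp)) return(NULL)
    logdens <- logdens + co$logp
  }
  # assign ψs innermost-out, reusing cached prefix reductions
  steps <- list()
  mpw <- metaprogram(list(), base = base)
  for (i in seq_along(names)) {
    nm <- names[[i]]
    tr <- cached_trace(caches, mpw, d, check_det = FALSE)
    if (!tr$ok) return(NULL)
    k <- mp_n_options(nm, tr$program, d)
    if (k < 1L) return(NULL)
    psi <- NULL
    if (MP_TAKES_PSI[[nm]]) {
      psi <- .mpl_sample1(k)
      logdens <- logdens - log(k)
    }
    steps <- c(steps, list(list(name = nm, psi = psi)))
    mpw$steps <- steps
  }
  # validate the last step through the cache as well
  tr <- cached_trace(caches, mpw, d, check_det = FALSE)
  if (!tr$ok) return(NULL)
  list(base = base, steps = steps, logdens = logdens)
}

# density of an existing inner metaprogram (base + steps[1..c]) under
# sample_inner, using the cached reduction for ψ option counts
inner_log_density <- function(caches, mp, c, d, g, budget) {
  n_base <- 1L + as.integer(g$program_base)
  logdens <- -log(g$n_level_options) * c
  logdens <- logdens - (if (c >= budget) log(n_base) else log(g$n_level_options))
  if (length(mp$base$rules)) {
    co <- program_cost(mp$base, g)
    if (!is.finite(co$logp)) return(-Inf)
    logdens <- logdens + co$logp
  }
  if (c > 0L) {
    mpc <- mp
    mpc$steps <- mp$steps[seq_len(c)]
    tr <- cached_trace(caches, mpc, d, check_det = FALSE)
    if (!tr$ok) return(-Inf)
    logdens <- logdens + tr$log_psi
  }
  logdens
}

# One proposal for the full-language pool. Returns NULL (auto-reject) or
# list(mp, log_hastings).
propose_full <- function(mp, d, g, sp, caches) {
  s <- length(mp$steps)
  psi_steps <- which(vapply(mp$steps, function(x) !is.null(x$psi), TRUE))
  moves <- c("regen", "insert", if (s > 0L) "remove", if (length(psi_steps)) "psi")
  mv <- moves[[.mpl_sample1(length(moves))]]
  nm_cur <- length(moves)
  if (mv == "regen") {
    # regenerate a uniformly chosen subtree: the nested metaprogram's
    # subtrees are its base plus each inner step chain
    cpoint <- .mpl_sample1(s + 1L) - 1L     # replace base + steps 1..cpoint
    outer <- if (cpoint < s) mp$steps[seq.int(cpoint + 1L, s)] else list()
    budget <- sp$max_steps - length(outer)
    inner <- sample_inner(caches, g, d, budget)
    if (is.null(inner)) return(NULL)
    mp2 <- metaprogram(c(inner$steps, outer), base = inner$base, sig = g$sig)
    s2 <- length(mp2$steps)
    rev_dens <- inner_log_density(caches, mp, cpoint, d, g, budget)
    if (!is.finite(rev_dens)) return(NULL)
    lq_fwd <- -log(nm_cur) - log(s + 1L) + inner$logdens
    lq_rev <- -log(n_moves_full(mp2)) - log(s2 + 1L) + rev_dens
    return(list(mp = mp2, log_hastings = lq_rev - lq_fwd))
  }
  if (mv == "insert") {
    if (s >= sp$max_steps) return(NULL)
    u <- .mpl_sample1(s + 1L) - 1L            # insert after u existing steps
    nm <- g$mp_names[.mpl_sample1(length(g$mp_names))]
    p_u <- reduce_prefix(caches, mp, u, d)
    if (is.null(p_u)) return(NULL)
    k <- mp_n_options(nm, p_u, d)
    if (k < 1L) return(NULL)
    step <- list(name = nm, psi = if (MP_TAKES_PSI[[nm]]) .mpl_sample1(k) else NULL)
    mp2 <- mp
    mp2$steps <- append(mp$steps, list(step), after = u)
    nm_new <- n_moves_full(mp2)
    lq_fwd <- -log(nm_cur) - log(s + 1L) - log(length(g$mp_names)) -
      (if (MP_TAKES_PSI[[nm]]) log(k) else 0)
    lq_rev <- -log(nm_new) - log(s + 1L)        # remove that step from mp2
    return(list(mp = mp2, log_hastings = lq_rev - lq_fwd))
  }
  if (mv == "remove") {
    u <- .mpl_sample1(s)
    removed <- mp$steps[[u]]
    mp2 <- mp
    mp2$steps <- mp$steps[-u]
    p_u <- reduce_prefix(caches, mp, u - 1L, d)
    if (is.null(p_u)) return(NULL)
    k <- mp_n_options(removed$name, p_u, d)
    if (k < 1L) return(NULL)                    # reverse insert impossible
    nm_new <- n_moves_full(mp2)
    lq_fwd <- -log(nm_cur) - log(s)
    lq_rev <- -log(nm_new) - log(s) -
      log(length(g$mp_names)) - (if (MP_TAKES_PSI[[removed$name]]) log(k) else 0)
    return(list(mp = mp2, log_hastings = lq_rev - lq_fwd))
  }
  # regenerate one ψ in place
  u <- psi_steps[[.mpl_sample1(length(psi_steps))]]
  p_u <- reduce_prefix(caches, mp, u - 1L, d)
  if (is.null(p_u)) return(NULL)
  k <- mp_n_options(mp$steps[[u]]$name, p_u, d)
  if (k < 1L) return(NULL)
  mp2 <- mp
  mp2$steps[[u]]$psi <- .mpl_sample1(k)
  list(mp = mp2, log_hastings = 0)
}

# typed rhs slots of a base program, for subtree regeneration (memoized on
# the program)
rhs_slots <- function(p, g) {
  program_memo(p, "rhs_slots", function(p) rhs_slots_compute(p, g))
}

rhs_slots_compute <- function(p, g) {
  slots <- list()
  for (i in seq_along(p$rules)) {
    r <- p$rules[[i]]
    head <- r$lhs[[1L]]
    sch <- c(g$sig$ops, g$sig$defined)[[head]]
    if (is.null(sch)) sch <- p$sig$defined[[head]]
    if (is.null(sch)) next
    pvars <- pattern_var_types(r$lhs, sch)
    walk <- function(t, ty, path, depth) {
      slots[[length(slots) + 1L]] <<- list(rule = i, path = path, ty = ty,
                                           depth = depth, scope = pvars)
      if (!is.list(t) || length(t) == 1L) return(invisible(NULL))
      sub_sch <- c(g$sig$ops, p$sig$defined)[[t[[1L]]]]
      if (is.null(sub_sch)) return(invisible(NULL))
      args <- lapply(sub_sch$args, instantiate_a, ty)
      if (identical(sub_sch$ret, "a")) args <- lapply(sub_sch$args, instantiate_a, ty)
      if (t[[1L]] == "==") args <- list("num", "num")
      for (j in seq_along(args)) {
        aty <- if (identical(args[[j]], "a")) "num" else args[[j]]
        walk(t[[j + 1L]], resolve_unknown(aty), c(path, j + 1L), depth + 1L)
      }
    }
    walk(r$rhs, resolve_unknown(sch$ret), integer(), 0L)
  }
  slots
}

pattern_var_types <- function(lhs, sch) {
  pv <- list()
  assign_types <- function(pat, ty) {
    if (is.character(pat)) { if (is.null(pv[[pat]])) pv[[pat]] <<- ty; return(invisible(NULL)) }
    if (!is.list(pat)) return(invisible(NULL))
    if (pat[[1L]] == "cons") { assign_types(pat[[2L]], "num"); assign_types(pat[[3L]], "list") }
  }
  for (i in seq_along(sch$args)) assign_types(lhs[[i + 1L]], resolve_unknown(sch$args[[i]]))
  pv
}

# One proposal for the object-level pool (base-only hypotheses).
propose_object <- function(mp, d, g, sp) {
  slots <- rhs_slots(mp$base, g)
  moves <- c("resample", if (length(slots)) "subtree")
  mv <- moves[[.mpl_sample1(length(moves))]]
  if (mv == "resample") {
    newp <- sample_program(g)
    mp2 <- metaprogram(list(), base = newp, sig = g$sig)
    lh <- base_log_density(mp$base, g) - base_log_density(newp, g) +
      log(length(moves)) - log(length(c("resample", if (length(rhs_slots(newp, g))) "subtree")))
    return(list(mp = mp2, log_hastings = lh))
  }
  sl <- slots[[.mpl_sample1(length(slots))]]
  new_sub <- sample_term(g, sl$ty, sl$scope, sl$depth)
  if (is.null(new_sub)) return(NULL)
  r <- mp$base$rules[[sl$rule]]
  old_sub <- term_at_path(r$rhs, sl$path)
  new_rhs <- term_set_path(r$rhs, sl$path, new_sub)
  if (length(setdiff(term_vars(new_rhs), term_vars(r$lhs)))) return(NULL)
  rules <- mp$base$rules
  rules[[sl$rule]] <- rule(r$lhs, new_rhs)
  newp <- program(rules, target = mp$base$target, sig = mp$base$sig)
  mp2 <- metaprogram(list(), base = newp, sig = g$sig)
  co_new <- term_cost(g, new_sub, sl$ty, sl$scope, sl$depth)
  co_old <- term_cost(g, old_sub, sl$ty, sl$scope, sl$depth)
  if (!is.finite(co_old$logp) || !is.finite(co_new$logp)) return(NULL)
  n_new <- length(rhs_slots(newp, g))
  lh <- (-log(n_new) + co_old$logp) - (-log(length(slots)) + co_new$logp)
  list(mp = mp2, log_hastings = lh)
}

#' Metropolis-Hastings acceptance decision
#'
#' Accepts with probability `min(1, exp((proposal - current)/T))`, adjusted
#' by the log proposal-density ratio for asymmetric moves.
#'
#' @param current,proposal log posteriors
#' @param temperature chain temperature (>= 1)
#' @param log_hastings log q(current | proposal) - log q(proposal | current)
#' @return logical
#' @export
mh_accept <- function(current, proposal, temperature, log_hastings = 0) {
  if (!is.finite(proposal) && proposal < 0) return(FALSE)
  if (!is.finite(current) && current < 0) return(TRUE)
  lr <- (proposal - current) / temperature + log_hastings
  if (lr >= 0) return(TRUE)
  log(stats::runif(1)) < lr
}

# --- search state -----------------------------------------------------------

new_search_state <- function(g, sp) {
  st <- new.env(parent = emptyenv())
  st$g <- g
  st$sp <- sp
  st$archive <- new.env(parent = emptyenv())
  st$archive_n <- 0L
  st$top_k <- sp$top_k
  st$caches <- new_caches()
  eps <- metaprogram(list(), sig = g$sig)
  st$pools <- list(
    full = list(chains = rep(list(eps), sp$n_chains),
                keys = rep("ε", sp$n_chains), next_chain = 1L),
    object = list(chains = rep(list(eps), sp$n_chains),
                  keys = rep("ε", sp$n_chains), next_chain = 1L)
  )
  st$temps <- rep(1, sp$n_chains)
  st$step_count <- 0L
  st
}

set_trial_temperatures <- function(st, trial) {
  tmax <- trial + 1
  st$temps <- exp(seq(0, log(tmax), length.out = st$sp$n_chains))
}

advance_chain <- function(st, pool_name, chain_idx, d) {
  sp <- st$sp
  g <- st$g
  mp <- st$pools[[pool_name]]$chains[[chain_idx]]
  cur <- score_cached(st$caches, mp, d, g, sp,
                      key = st$pools[[pool_name]]$keys[chain_idx])
  archive_add(st, cur)
  prop <- if (pool_name == "full") propose_full(mp, d, g, sp, st$caches) else propose_object(mp, d, g, sp)
  if (is.null(prop)) return(invisible(NULL))
  if (length(prop$mp$steps) > sp$max_steps) return(invisible(NULL))
  sc <- score_cached(st$caches, prop$mp, d, g, sp)
  archive_add(st, sc)
  if (mh_accept(cur$lpost, sc$lpost, st$temps[chain_idx], prop$log_hastings)) {
    st$pools[[pool_name]]$chains[[chain_idx]] <- prop$mp
    st$pools[[pool_name]]$keys[chain_idx] <- sc$key
  }
  invisible(NULL)
}

#' Replica-exchange sweep over adjacent temperature pairs
#'
#' @param st search state environment
#' @param pool_name `"full"` or `"object"`
#' @param d current dataset
#' @export
tempering_swap <- function(st, pool_name, d) {
  sp <- st$sp
  for (j in seq_len(sp$n_chains - 1L)) {
    mp_a <- st$pools[[pool_name]]$chains[[j]]
    mp_b <- st$pools[[pool_name]]$chains[[j + 1L]]
    ka <- st$pools[[pool_name]]$keys[j]
    kb <- st$pools[[pool_name]]$keys[j + 1L]
    sa <- score_cached(st$caches, mp_a, d, st$g, sp, key = ka)
    sb <- score_cached(st$caches, mp_b, d, st$g, sp, key = kb)
    if (!is.finite(sa$lpost) && !is.finite(sb$lpost)) next
    lr <- (1 / st$temps[j] - 1 / st$temps[j + 1L]) * (sb$lpost - sa$lpost)
    if (is.nan(lr)) lr <- 0   # equal temperatures against an infinite gap
    if (lr >= 0 || log(stats::runif(1)) < lr) {
      st$pools[[pool_name]]$chains[[j]] <- mp_b
      st$pools[[pool_name]]$chains[[j + 1L]] <- mp_a
      st$pools[[pool_name]]$keys[j] <- kb
      st$pools[[pool_name]]$keys[j + 1L] <- ka
    }
  }
  invisible(NULL)
}

#' Run one trial's worth of search
#'
#' Advances chains for `steps` search steps: at each step the
#' full-language pool is chosen with probability alpha (the object-level
#' pool otherwise), and the chosen pool's next chain in round-robin order
#' makes one proposal. Replica-exchange sweeps run every `swap_interval`
#' steps. All scored hypotheses feed the shared top-K archive.
#'
#' @param st search state (from an [online_run()] or [new_search_state()])
#' @param d dataset visible this trial
#' @param steps number of search steps
#' @return the state, invisibly
#' @export
run_trial <- function(st, d, steps) {
  sp <- st$sp
  for (k in seq_len(steps)) {
    use_full <- sp$alpha >= 1 || (sp$alpha > 0 && stats::runif(1) < sp$alpha)
    pool_name <- if (use_full) "full" else "object"
    ci <- st$pools[[pool_name]]$next_chain
    st$pools[[pool_name]]$next_chain <- if (ci == sp$n_chains) 1L else ci + 1L
    advance_chain(st, pool_name, ci, d)
    st$step_count <- st$step_count + 1L
    if (st$step_count %% sp$swap_interval == 0L) {
      if (sp$alpha > 0) tempering_swap(st, "full", d)
      if (sp$alpha < 1) tempering_swap(st, "object", d)
    }
  }
  invisible(st)
}

#' Predict an output from the current archive
#'
#' Evaluates the archive's highest-posterior hypothesis on the input. Ties
#' are broken by fewer metaprimitive steps, then canonical print order.
#'
#' @param st search state
#' @param input integer vector
#' @return a list with `ok`, `value`, and the winning score `best`
#' @export
predict_best <- function(st, input) {
  best <- archive_best(st)
  if (is.null(best)) return(list(ok = FALSE, value = NULL, best = NULL))
  res <- eval_cached(st$caches, best$program, input, st$sp)
  list(ok = res$ok, value = res$value, best = best)
}

#' Run the online 11-trial protocol
#'
#' Trial i trains on the first i-1 pairs, predicts the i-th input, then
#' reveals the i-th output. Chains are hotstarted from the best known
#' hypothesis between trials, and the temperature ladder is rescaled to
#' span 1 .. trial+1. With the same seed and configuration the run record
#' is reproducible bit-for-bit.
#'
#' @param fn_dataset a dataset of exactly 11 ordered pairs
#' @param sp search parameters
#' @param seed integer RNG seed
#' @param g grammar (defaults to the standard one)
#' @return a run record: list with `trials` (11 entries of input, predicted,
#'   observed, correct, and the per-trial best score), `params`, `seed`
#' @export
online_run <- function(fn_dataset, sp = search_params(), seed = 1L, g = grammar()) {
  stopifnot(length(fn_dataset) == 11L)
  set.seed(seed)
  st <- new_search_state(g, sp)
  trials <- vector("list", 11L)
  for (i in 1:11) {
    d <- dataset(fn_dataset[seq_len(i - 1L)])
    set_trial_temperatures(st, i)
    rescore_archive(st, d)
    hotstart_chains(st, d)
    run_trial(st, d, sp$steps_per_trial)
    pred <- predict_best(st, fn_dataset[[i]]$input)
    observed <- fn_dataset[[i]]$output
    correct <- isTRUE(pred$ok) && identical(as.integer(pred$value), as.integer(observed))
    best <- pred$best
    trials[[i]] <- list(
      input = fn_dataset[[i]]$input, predicted = pred$value,
      observed = observed, correct = correct,
      best = if (!is.null(best)) list(key = best$key, lpm = best$lpm, lpp = best$lpp,
                                      llik = best$llik, lpost = best$lpost) else NULL)
  }
  list(trials = trials, seed = seed, params = sp)
}

# re-score every archived hypothesis under the current dataset
rescore_archive <- function(st, d) {
  keys <- ls(st$archive)
  for (k in keys) {
    sc <- score_cached(st$caches, st$archive[[k]]$mp, d, st$g, st$sp, key = k)
    if (isTRUE(sc$ok)) st$archive[[k]] <- sc else rm(list = k, envir = st$archive)
  }
  st$archive_n <- length(ls(st$archive))
  invisible(NULL)
}

hotstart_chains <- function(st, d) {
  best <- archive_best(st)
  if (is.null(best)) return(invisible(NULL))
  # the object pool only holds base-only hypotheses: hotstart it from the
  # reduced program of the best hypothesis
  obj <- if (length(best$mp$steps)) {
    metaprogram(list(), base = best$program, sig = st$g$sig)
  } else best$mp
  obj_key <- print_metaprogram(obj)
  for (j in seq_len(st$sp$n_chains)) {
    st$pools$full$chains[[j]] <- best$mp
    st$pools$full$keys[j] <- best$key
    st$pools$object$chains[[j]] <- obj
    st$pools$object$keys[j] <- obj_key
  }
  invisible(NULL)
}
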