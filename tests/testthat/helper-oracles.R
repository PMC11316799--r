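# Independent oracles shared across test files. These deliberately avoid
# the package's own matching and likelihood code paths.

# A tiny first-order matcher over plain list terms.
tiny_match <- function(pat, tgt, subst = list()) {
  if (is.character(pat)) {
    b <- subst[[pat]]
    if (is.null(b)) { subst[[pat]] <- tgt; return(subst) }
    if (identical(b, tgt)) subst else NULL
  } else if (is.list(pat)) {
    if (!is.list(tgt) || length(pat) != length(tgt) ||
        !identical(pat[[1L]], tgt[[1L]])) return(NULL)
    for (i in seq_along(pat)[-1L]) {
      subst <- tiny_match(pat[[i]], tgt[[i]], subst)
      if (is.null(subst)) return(NULL)
    }
    subst
  } else {
    if (identical(pat, tgt)) subst else NULL
  }
}

# All ground terms of depth <= d over the 4-symbol toy signature
# {c0, c1, f/1, g/2}.
toy_terms <- function(d) {
  if (d == 1L) return(list(list("c0"), list("c1")))
  smaller <- toy_terms(d - 1L)
  out <- smaller
  for (a in smaller) out <- c(out, list(list("f", a)))
  for (a in smaller) for (b in smaller) out <- c(out, list(list("g", a, b)))
  unique(out)
}

# All terms of depth <= d over the toy signature extended with variables.
toy_terms_with_vars <- function(d, vars) {
  if (d == 1L) return(c(list(list("c0"), list("c1")), as.list(vars)))
  smaller <- toy_terms_with_vars(d - 1L, vars)
  out <- smaller
  for (a in smaller) out <- c(out, list(list("f", a)))
  for (a in smaller) for (b in smaller) out <- c(out, list(list("g", a, b)))
  unique(out)
}

# Literal brute-force evaluation of the prefix-likelihood summation.
brute_pair_likelihood <- function(pred, obs, eta = 1e-6, N = 100) {
  np <- length(pred)
  no <- length(obs)
  total <- 0
  for (i in 0:min(np, no)) {
    shares <- if (i == 0L) TRUE else {
      all(mapply(function(a, b) identical(is.na(a), is.na(b)) &&
                   (is.na(a) || a == b),
                 pred[seq_len(i)], obs[seq_len(i)]))
    }
    if (!shares) next
    total <- total + eta^(np - i) * (eta / N)^(no - i) * (1 - eta)^(1 + min(i, 1))
  }
  log(total)
}
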