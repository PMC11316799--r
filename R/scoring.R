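# The prefix likelihood and the posterior over metaprograms.
#
# An output is scored against an observation under a noise process that
# deletes trailing symbols and appends random ones, each with probability
# eta per symbol, over an alphabet of N symbols. Every shared-prefix length
# i from 0 up to the longest common prefix contributes a term
#   eta^(|pred|-i) * (eta/N)^(|obs|-i) * (1-eta)^(1+min(i,1)),
# so the likelihood grows with the shared prefix. A hypothesis whose
# evaluation fails contributes only the i = 0 term with |pred| read as 0.

#' Likelihood parameters
#'
#' @param eta per-symbol noise probability (default 1e-6)
#' @param N append-alphabet size (default 100: the numerals 0..99)
#' @param per_pair `"product"` (default) multiplies per-pair likelihoods, as
#'   implied by independent generation of the pairs; `"sum"` adds them on
#'   the natural scale instead, for comparison
#' @return a list of class `mpl_lik_params`
#' @export
likelihood_params <- function(eta = 1e-6, N = 100L, per_pair = c("product", "sum")) {
  stopifnot(eta > 0, eta < 1, N >= 1)
  structure(list(eta = eta, N = as.integer(N), per_pair = match.arg(per_pair)),
            class = "mpl_lik_params")
}

lcp_length <- function(a, b) {
  n <- min(length(a), length(b))
  i <- 0L
  while (i < n) {
    x <- a[i + 1L]; y <- b[i + 1L]
    same <- (is.na(x) && is.na(y)) || (!is.na(x) && !is.na(y) && x == y)
    if (!same) break
    i <- i + 1L
  }
  i
}

#' Log-likelihood of one predicted/observed pair
#'
#' @param predicted either an evaluation result (a list with fields `ok`
#'   and `value`, as returned by [evaluate_program()]) or an integer vector;
#'   a failed evaluation is scored as a prediction sharing a prefix of
#'   length 0 with the observation, with predicted length 0
#' @param observed integer vector (NA encodes nan)
#' @param params likelihood parameters
#' @return log-probability
#' @examples
#' pair_log_likelihood(c(1, 2, 3), c(1, 2, 3), likelihood_params())
#' @export
pair_log_likelihood <- function(predicted, observed, params = likelihood_params()) {
  if (is.list(predicted)) {
    predicted <- if (isTRUE(predicted$ok)) predicted$value else NULL
  }
  np <- length(predicted)
  no <- length(observed)
  L <- if (np) lcp_length(predicted, observed) else 0L
  leta <- log(params$eta)
  letaN <- leta - log(params$N)
  l1me <- log1p(-params$eta)
  i <- 0:L
  terms <- (np - i) * leta + (no - i) * letaN + (1 + pmin(i, 1)) * l1me
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}

#' Log-likelihood of a dataset under a program
#'
#' Evaluates the program on each input and combines the per-pair prefix
#' likelihoods: by default as a product (sum of logs), or on the natural
#' scale as a sum when `params$per_pair == "sum"`.
#'
#' @param p a program
#' @param d a dataset
#' @param params likelihood parameters
#' @param step_limit,size_limit evaluation bounds per pair
#' @return log-probability (0 for an empty dataset)
#' @export
data_log_likelihood <- function(p, d, params = likelihood_params(),
                                step_limit = MP_EVAL_STEPS, size_limit = MP_EVAL_SIZE) {
  if (!length(d)) return(0)
  lls <- vapply(d, function(pr) {
    res <- evaluate_program(p, pr$input, step_limit, size_limit)
    pair_log_likelihood(res, pr$output, params)
  }, 0)
  if (params$per_pair == "product") return(sum(lls))
  m <- max(lls)
  m + log(sum(exp(lls - m)))
}

#' Combined prior over a hypothesis
#'
#' The geometric mean of the metaprogram prior and the program prior on the
#' natural scale: `(ln p_M(H) + ln p_P(H~)) / 2`. Lesioned modes keep only
#' one of the two components.
#'
#' @param lpm,lpp log metaprogram / program priors
#' @param mode `"full"`, `"pm"` (metaprogram prior only), or `"pp"`
#' @return log prior (unnormalized)
#' @export
combined_log_prior <- function(lpm, lpp, mode = c("full", "pm", "pp")) {
  mode <- match.arg(mode)
  switch(mode, full = (lpm + lpp) / 2, pm = lpm, pp = lpp)
}

#' Score a hypothesis: priors, likelihood, posterior
#'
#' Reduces the metaprogram against the data and assembles its full score.
#' Irreducible metaprograms get `-Inf` throughout.
#'
#' @param mp a metaprogram
#' @param d a dataset
#' @param g a grammar
#' @param params likelihood parameters
#' @param prior_mode `"full"`, `"pm"`, or `"pp"` (prior lesions)
#' @param max_choices reject hypotheses with more random choices than this
#' @return a list of class `mpl_score` with fields `ok`, `lpm`, `lpp`,
#'   `llik`, `lprior`, `lpost`, `n_choices`, `program`, and `mp`
#' @export
score_hypothesis <- function(mp, d, g = grammar(), params = likelihood_params(),
                             prior_mode = "full", max_choices = MAX_MP_CHOICES) {
  bad <- list(ok = FALSE, lpm = -Inf, lpp = -Inf, llik = -Inf,
              lprior = -Inf, lpost = -Inf, n_choices = NA_integer_,
              program = NULL, mp = mp)
  class(bad) <- "mpl_score"
  trace <- reduce_metaprogram_trace(mp, d)
  if (!trace$ok) return(bad)
  mc <- mp_cost(mp, g, d, trace = trace)
  if (!is.finite(mc$logp) || mc$n_choices > max_choices) return(bad)
  prog <- trace$program
  lpp <- program_log_prior(prog, g)
  if (!is.finite(lpp)) return(bad)
  llik <- data_log_likelihood(prog, d, params)
  lprior <- combined_log_prior(mc$logp, lpp, prior_mode)
  out <- list(ok = TRUE, lpm = mc$logp, lpp = lpp, llik = llik,
              lprior = lprior, lpost = llik + lprior,
              n_choices = mc$n_choices, program = prog, mp = mp)
  class(out) <- "mpl_score"
  out
}
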