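# Anti-unification: the least general generalization (lgg) of two terms.
#
# Classic first-order construction (Plotkin/Reynolds): walk the two terms in
# parallel; where they agree structurally, keep the shared symbol; where they
# differ, introduce a variable. Identical mismatch pairs map to the same
# variable, which is what makes the result *least* general and lets repeated
# structure (e.g. an element that appears in both the input and the output
# of a rule) generalize to a single shared variable.

#' Least general generalization of two terms
#'
#' Computes the most specific term `g` having both `a` and `b` as instances,
#' together with the two witnessing substitutions (`σa(g) = a`,
#' `σb(g) = b`). Identical sub-occurrence pairs are mapped to the same
#' variable. Fresh variables are named `v1, v2, ...`; pass `prefix` to avoid
#' capture against existing variables.
#'
#' @param a,b terms
#' @param prefix prefix for introduced variables (default `"v"`)
#' @return a list with fields `gen` (the generalization), `sa`, `sb`
#'   (named lists mapping introduced variables to subterms of `a` / `b`)
#' @examples
#' r <- lgg(parse_term("[1, 1 | (F y)]"), parse_term("[3, 3 | (F z)]"))
#' print_term(r$gen)
#' @export
lgg <- function(a, b, prefix = "v") {
  .mpl_lgg_cpp(a, b, prefix)
}
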