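# Fast evaluation of programs on inputs, backed by the compiled evaluator
# in src/eval.cpp.
#
# normalize() defines the reference semantics (stepwise leftmost-outermost
# rewriting, program rules before delta-rules, first match wins); rescanning
# the term for the leftmost redex every step costs O(steps x size), which
# would dominate search. The compiled engine computes the same normal form
# by weak-head evaluation with pattern-demanded forcing and in-place update
# of forced subterms (graph reduction): variable patterns bind arguments
# unevaluated, constructor and literal patterns force to weak-head normal
# form, nonlinear patterns compare full normal forms, and `if` forces only
# its condition and the chosen branch. The two engines agree on
# deterministic programs whenever both terminate (property-tested); fuel
# exhaustion and stuck normal forms are failures in both.

FAST_FUEL_DEFAULT <- 30000L

#' Fast evaluation of a program on an input list
#'
#' Compiled counterpart of [evaluate_program()], used by the search loop;
#' computes the same normal form as the stepwise engine on deterministic
#' programs, with a work budget in place of the step limit.
#'
#' @param p a program
#' @param input integer vector
#' @param fuel work budget (elementary evaluation events)
#' @return list with fields `ok` and `value`
#' @export
evaluate_program_fast <- function(p, input, fuel = FAST_FUEL_DEFAULT) {
  v <- .mpl_eval_cpp(program_key(p), lapply(p$rules, function(r) r[c("lhs", "rhs")]),
                     p$target, as.integer(input), as.double(fuel))
  if (is.null(v)) list(ok = FALSE, value = NULL) else list(ok = TRUE, value = v)
}
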