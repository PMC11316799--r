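---
title: "Metaprogram search for list functions: models and methods"
author: "mplearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaprogram search for list functions: models and methods}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The learning problem

`mplearn` models concept learning over *list functions*: a learner observes
input/output pairs of lists of natural numbers (elements 0–99, lengths
0–15) and must infer the rule that maps inputs to outputs, predicting the
output for each new input before it is revealed. The hypothesis space is a
space of symbolic programs, and the learner is Bayesian: it scores
hypotheses by a posterior that trades data fit against description
complexity, and searches the space with Markov chain Monte Carlo.

The package's central idea is that hypotheses are not plain programs but
**metaprograms**: compositions of *metaprimitives* — operators that
transform programs rather than data — applied to a base program (usually
the empty program ε). Given the observed data, a metaprogram reduces
deterministically to an ordinary program. A short metaprogram can denote a
long program, because metaprimitives can read structure out of the data
(memorize it, align it, generalize it) instead of spelling the structure
out symbol by symbol. This reshapes the inductive bias: rules that are easy
to *infer* from data become easy to *describe*, and therefore easy to find.

# Programs: first-order term rewriting

Programs are first-order term rewriting systems (TRS): ordered lists of
rules `lhs ≈ rhs` where the left-hand side is the target symbol `F` applied
to a pattern and right-hand sides use the object-level primitives of the
language: numerals `0..99` with `nan` for out-of-range results, booleans,
list construction (`[]`, `[x | xs]`), arithmetic (`+`, `-`), comparison
(`>`, `==`), conditionals (`if`), list access (`head`, `tail`,
`is_empty`), and a fixpoint operator `fix`.

The evaluation strategy is fixed for reproducibility: **leftmost-outermost
reduction, with a program's own rules tried in order before the primitive
delta-rules; the first matching rule wins.** This makes
memorized-exception-then-general-rule programs well defined. Choices that
the rewriting literature leaves open are pinned down as follows:

* arithmetic leaving `[0, 99]` rewrites to `nan`, and `nan` propagates
  through arithmetic; comparisons with `nan` are false, `(== nan nan)` is
  true (identity of values);
* `head []` is `nan` and `tail []` is `[]`, so list access is total;
* `(fix x f)` iterates the unary symbol `f` to a fixpoint:
  it expands to `(if (== (f x) x) x (fix (f x) f))`;
* default resource bounds are 10,000 rewrite steps and 10,000 term nodes;
  exceeding either is a *failure value*, not an error. A failed evaluation
  is scored in the likelihood as a prediction sharing a prefix of length 0
  with the observation — the most conservative reading of a diverging
  hypothesis.

A program is only admitted as a hypothesis if it passes a determinism
check: two rules whose left-hand sides unify (after renaming apart) must
agree on the unified right-hand side. Rules with distinct ground patterns
— the memorized exceptions that metaprimitives produce — always pass.

Two evaluation engines compute the same semantics. `normalize()` is the
reference stepwise engine, which rescans for the leftmost redex at each
step. `evaluate_program_fast()` is a compiled engine that reaches the same
normal form by weak-head evaluation with pattern-demanded forcing and
in-place update of forced subterms (graph reduction); a property test
checks that the two agree on deterministic programs whenever both
terminate. The search loop uses the compiled engine with a work budget
(default 3,000 evaluation events per candidate during search) in place of
the step limit.

# Metaprimitives

Eight metaprimitives transform programs. Each one that involves a random
choice ψ enumerates its legal options in a canonical deterministic order
(rule order, then preorder subterm position), so a ψ token is a stable
integer index and reduction is deterministic given the tokens. A
metaprimitive with no legal option — or whose output would break the rule
invariants — makes the whole metaprogram *inapplicable*: it receives zero
posterior rather than silently acting as the identity.

* **MemorizeAll** appends the ground rule `F x ≈ y` for every observed pair
  not already entailed by the program (entailment is checked by
  evaluation), making the data's latent structure available to later
  metaprimitives. **Memorize** appends a single indexed pair.
* **Recurse** implements the minimal elementwise form of recursion
  introduction: ψ selects an unroll arity `k` (0–4) such that every
  memorized pair's output has exactly `k` elements per input element; each
  ground rule is replaced by its one-step unrolled family
  `F [x0 | rest] ≈ [y0, …, y(k−1) | F rest]` chained down to `F [] ≈ []`.
  Richer recursive schemata (folds, accumulators) are deliberately out of
  scope; this variant is exactly what the elementwise duplication function
  needs.
* **AntiUnify** folds similar rules into one by least general
  generalization. Same-head rules are grouped by the root constructor of
  the rule argument — so the `[]` base rule is never folded into the
  `cons` rules — and each group of two or more is folded pairwise,
  left-associated in rule order. A fold whose result would use right-hand
  variables unbound on the left leaves that group unchanged; if no group
  folds, the metaprimitive is inapplicable. This grouping is what lets the
  unrolled duplication family collapse to `F [x | y] ≈ [x, x | (F y)]`
  while keeping `F [] ≈ []`.
* **Variable** generalizes one distinct non-variable subterm of a rule's
  left-hand side into a fresh variable (all its occurrences on both
  sides); **Delete** removes a rule; **Compose** factors a right-hand-side
  subterm into a fresh defined symbol applied to the subterm's free
  variables (behavior-preserving, with the new symbol typed concretely
  from the host rule); **Subproblem** extracts an aligned pair of
  input/output suffixes of a memorized rule into a fresh symbol, so later
  metaprimitives can generalize the subproblem separately. Subproblem's ψ
  ranges over suffix pairs; richer alignments would explode the option
  set without changing what the search can ultimately express.

Metaprograms carry at most 7 steps and at most 50 random choices (grammar
decisions plus ψ tokens), and must reduce to a deterministic TRS.

# Scoring

The posterior over metaprograms is `p(H | D) ∝ p(D | H) p(H)` with a dual
prior

```
p(H) ∝ exp((ln p_M(H) + ln p_P(H̃)) / 2),
```

the geometric mean of a grammar-based prior over the metaprogram `H` and a
similar prior over the program `H̃` it reduces to. Both grammars are
type-constrained with **uniform production probabilities over the
type-legal options at each choice point** (no learned weights). The
metaprogram grammar chooses, at each level, one of the eight
metaprimitives or one of two base productions (ε or an explicit program);
every ψ contributes `log(1/|options|)` with the option set computed during
reduction, which is what makes the grammar context-sensitive. The program
grammar derives rule lists with a geometric continue/stop decision (1/2
each), typed left-hand patterns, and typed right-hand terms; numerals form
a single production family with a uniform 1/100 choice within it, so that
a numeral is one decision, not a hundred sibling productions. The
polymorphic `==` is instantiated at numbers to keep hidden type choices
out of the derivation. Term derivations are capped at depth 18 — enough
for the deepest memorized 15-element list — and deeper structure has zero
prior mass; the priors are proper up to this truncation (checked by
exhaustive enumeration on a reduced grammar).

The likelihood is a prefix noise model: with per-symbol noise rate
η = 10⁻⁶ and append alphabet N = 100 (the numerals), every shared-prefix
length `i` from 0 to the longest common prefix contributes
`η^(|pred|−i) (η/N)^(|obs|−i) (1−η)^(1+min(i,1))`, summed in log space.
Pairs combine as a product (independent generation); a configurable flag
adds them on the natural scale instead, for comparison with the literal
reading of the summation. The alphabet choice N = 100 identifies the
noise-model "characters" with list elements.

# Search

Inference is Metropolis–Hastings over metaprograms with parallel
tempering: two pools of five chains, with temperatures spanning 1.0 to the
current trial number plus one, exponentially spaced. One pool searches the
full language; the other searches base-only hypotheses (plain programs),
emulating object-level-only MCMC. At each search step one pool is chosen
(the full pool with probability α, fixed to 1 except in the ablation), and
its next chain in round-robin order makes one proposal. Wall-clock
schedules in the source procedure are replaced by step-based ones for
determinism: replica-exchange sweeps every 250 steps, and one "search
step" is one proposal-plus-accept decision on one chain.

Full-pool proposals: regenerate a uniformly chosen subtree of the
metaprogram (the base plus an inner prefix of the step chain, resampled
from the grammar with ψs assigned during partial reduction); insert a
metaprimitive step at a uniform position; remove a uniform step;
regenerate a uniform ψ. Object-pool proposals: whole-program resampling
and typed regeneration of a uniformly chosen right-hand-side subtree.
All Hastings corrections are computed exactly from the same option
enumeration that backs sampling, and the toy-space calibration test checks
the T = 1 chain against exhaustively enumerated posterior mass. Proposal
draws abandon terms beyond 120 nodes — the uniform grammar is
supercritical, so unbounded draws have a heavy size tail; states that
large are unreachable under the same truncated proposals, keeping the
truncation consistent.

The online protocol follows the behavioral task: trial *i* trains on the
first *i*−1 pairs, predicts the *i*-th output (using the highest-posterior
hypothesis among the 100 retained, ties broken by fewer steps and then
print order), then reveals it. Chains hotstart from the best known
hypothesis between trials, and the archive is re-scored under the enlarged
dataset. A run is reproducible bit for bit from its seed.

# The enumeration baseline

The comparison model enumerates single-rule programs `F xs = rhs` in
depth-first order within description-length bands of Δ = 1.5 nats,
iteratively deepening across bands. Description length is the negative
log prior under the program grammar, tying the stream's order to
approximately decreasing prior probability; one enumerated candidate
counts as one step so budgets are comparable to search steps. Online, it
uses win-stay/lose-shift: keep the committed program while predictions are
correct; after an error, re-select the first enumerated program consistent
with all observed pairs.

# The benchmark generator

The generator emulates the experimental stimuli. For each registered
function, candidate sets of 11 valid pairs are sampled (input lengths
uniform on 0–15, elements uniform on 0–99, filtered by the function's
validity predicate and the output bounds) and the best set is kept under a
score combining variance in input and output lengths, variance in
elements, the number of distinct outputs, and a penalty on pairs whose
input equals their output — uniform weights by default, plus an optional
per-function hook (e.g. favoring inputs longer than the indexed position
for indexing tasks). A second pass scores random orderings by the subset
scores of the first five and last six pairs, whether the first example's
input differs from its output (weighted at 1000, so such an example leads
whenever one exists), and the closeness of the first input's length to 5.
Desk-scale defaults are 10⁴ candidate sets and 5 × 10³ orderings.

What the generator does **not** emulate: per-function custom scoring
beyond the illustrative hooks, and any property of human-facing stimulus
presentation. Passing tests on generated sets therefore show that the
models behave as specified under the stated sampling conditions, not that
they reproduce behavior on the original experimental stimuli.

# Numerical and design choices

* Degenerate inputs: the empty dataset gives likelihood 0 (log scale), so
  trial 1 is prior-only; empty lists are legal inputs and outputs.
* Ties in prediction are broken deterministically (posterior, then fewer
  metaprimitive steps, then canonical print order).
* `nan` inside a predicted list is a legal output symbol distinct from
  every numeral; it matches `nan` in an observation and nothing else.
* Option sets, priors, proposal densities, and enumeration all share one
  option-enumeration routine, so Metropolis–Hastings corrections and
  description lengths are exact by construction.
* R's copy-on-modify semantics duplicate values assigned into lists, so
  the term machinery builds nodes constructively instead of subassigning;
  the compiled evaluator uses arena-allocated nodes with in-place update,
  where sharing is safe.

# Problem sizes used by the test suite

The suite runs the full pipeline at sizes chosen to exercise every code
path while completing in minutes: the sampler-calibration check uses a
truncated two-metaprimitive space and 10⁵ chain steps; the recovery check
runs the online protocol on the duplication function at 5,000 search steps
per trial for five seeds in each of the two pool configurations; the
generator-bounds check draws 1,000 example sets; oracle comparisons use
exhaustive enumeration at depth 3 (anti-unification) and 1,000 random
pairs (likelihood). Full-scale behavioral comparisons (hundreds of
functions, 5 × 10⁵ steps per trial) are supported by the same interfaces
but are not part of the test suite.

# Known limitations

* The Recurse, Compose, and Subproblem variants are the minimal ones
  consistent with their one-line descriptions; richer variants would
  enlarge the reachable program space.
* The program prior types auxiliary symbols opportunistically; a full
  Hindley–Milner treatment of polymorphic auxiliary definitions is not
  attempted.
* The object-level pool emulates program-only MCMC within this package's
  scoring; it is an in-house baseline, not a reimplementation of any
  external system.
* Likelihood and priors are fixed-form; no parameters are fit to data.
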