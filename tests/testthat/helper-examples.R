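# Shared fixtures: the printed example pairs for the duplication function
# and for the take/cut/replace/swap composition, plus their reference
# programs, built in code.

# duplication: each input element appears twice, in order
f_printed_pairs <- function() {
  list(
    list(input = c(1L, 3L, 9L, 7L), output = c(1L, 1L, 3L, 3L, 9L, 9L, 7L, 7L)),
    list(input = c(6L, 9L, 2L, 8L, 0L, 5L),
         output = c(6L, 6L, 9L, 9L, 2L, 2L, 8L, 8L, 0L, 0L, 5L, 5L)),
    list(input = c(9L, 2L), output = c(9L, 9L, 2L, 2L))
  )
}

# the six-element composition: take 7, cut the 6th, replace the 4th with 4,
# swap 1st and 3rd
g_printed_pairs <- function() {
  list(
    list(input = c(7L, 9L, 0L, 2L, 6L, 8L, 3L, 4L, 6L),
         output = c(0L, 9L, 7L, 4L, 6L, 3L)),
    list(input = c(1L, 7L, 8L, 2L, 5L, 6L, 1L),
         output = c(8L, 7L, 1L, 4L, 5L, 1L)),
    list(input = c(6L, 7L, 1L, 3L, 2L, 0L, 8L, 9L, 4L, 5L),
         output = c(1L, 7L, 6L, 4L, 2L, 8L))
  )
}

# reference rewrite program for the duplication function
f_reference_program <- function() {
  parse_program("F [x | y] = [x, x | (F y)]\nF [] = []")
}

# reference rewrite program for the composition (defined on inputs with at
# least seven elements)
g_reference_program <- function() {
  parse_program("F [a, b, c, d, e, f, g | t] = [c, b, a, 4, e, g]")
}

# an 11-pair online dataset for the duplication function: the three printed
# pairs first, then further pairs consistent with the rule
f_online_pairs <- function() {
  extra <- list(c(4L, 4L, 0L), c(5L), c(2L, 7L, 3L, 1L), integer(0),
                c(8L, 6L), c(3L, 5L, 9L), c(0L, 1L, 2L, 3L, 4L), c(7L, 7L))
  c(f_printed_pairs(),
    lapply(extra, function(x) list(input = x, output = rep(x, each = 2L))))
}

random_valid_input <- function(fn, max_len = 15L) {
  repeat {
    x <- sample(0:99, sample.int(max_len + 1L, 1L) - 1L, replace = TRUE)
    if (is.null(fn$valid) || isTRUE(fn$valid(x))) return(as.integer(x))
  }
}
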