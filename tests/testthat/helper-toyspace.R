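# Exhaustive enumeration of a truncated metaprogram space: every ψ-valid
# step chain of at most `max_steps` metaprimitives from the grammar's name
# set over an ε base. Used for prior-properness and sampler-calibration
# checks.
enumerate_toy_metaprograms <- function(g, d, max_steps = 2L) {
  out <- list(metaprogram(list(), sig = g$sig))
  frontier <- list(list(steps = list(), program = program(sig = g$sig)))
  for (depth in seq_len(max_steps)) {
    nxt <- list()
    for (node in frontier) {
      for (nm in g$mp_names) {
        k <- mplearn:::mp_n_options(nm, node$program, d)
        if (k < 1L) next
        psis <- if (mplearn:::MP_TAKES_PSI[[nm]]) seq_len(k) else list(NULL)
        for (psi in psis) {
          p2 <- mplearn:::mp_apply(nm, node$program, d, psi)
          if (is.null(p2)) next
          steps2 <- c(node$steps, list(list(name = nm, psi = psi)))
          out[[length(out) + 1L]] <- metaprogram(steps2, sig = g$sig)
          nxt[[length(nxt) + 1L]] <- list(steps = steps2, program = p2)
        }
      }
    }
    frontier <- nxt
  }
  out
}
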