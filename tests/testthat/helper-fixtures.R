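# Construct a core/full pair with a deterministic number of significant
# t- and F-tests: "null" traits are balanced 9/11 patterns in both sets
# (t = 0, F = 1), shifted traits move the core mean far away, inflated
# traits widen the core spread around the shared mean.
patterned_pair <- function(m = 19, n_shift = 0, n_inflate = 0,
                           n_core = 40, n_full = 120) {
  base_core <- rep(c(9, 11), length.out = n_core)
  base_full <- rep(c(9, 11), length.out = n_full)
  full <- matrix(rep(base_full, m), n_full, m)
  core <- matrix(rep(base_core, m), n_core, m)
  if (n_shift > 0)
    core[, seq_len(n_shift)] <- core[, seq_len(n_shift)] + 50
  if (n_inflate > 0) {
    cols <- seq.int(m - n_inflate + 1L, m)
    core[, cols] <- 10 + (core[, cols] - 10) * 6   # widen spread, keep mean
  }
  colnames(full) <- colnames(core) <- paste0("t", seq_len(m))
  rownames(full) <- sprintf("f%03d", seq_len(n_full))
  rownames(core) <- sprintf("c%03d", seq_len(n_core))
  list(core = trait_matrix(core), full = trait_matrix(full))
}
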